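#' Walk importance distribution
#'
#' Normalizes absolute walk relevances into a probability distribution,
#' `p_w = |R_W| / sum |R_W'|`, and attaches each walk's spatial extent.
#' Absolute-value normalization is the one choice that guarantees values in
#' `[0, 1]` when relevances are signed.
#'
#' @param map A [walk_relevances()] result (its conformer attribute supplies
#'   atom positions), or any tibble with `atoms` and `relevance` columns if
#'   `conf` is given.
#' @param conf Optional conformer overriding the map's stored conformer.
#' @return A tibble of class `importance_distribution`: the map's columns
#'   plus `p` (summing to 1) and `extent` (Angstrom).
#' @export
walk_importance <- function(map, conf = NULL) {
  conf <- conf %||% attr(map, "conformer")
  if (is.null(conf)) stop("no conformer available for walk extents")
  tot <- sum(abs(map$relevance))
  if (tot == 0) stop("all walk relevances are zero: no importance distribution")
  pos <- conformer_positions(conf)
  out <- tibble::as_tibble(map)
  out$p <- abs(out$relevance) / tot
  out$extent <- vapply(out$atoms, walk_extent, numeric(1), positions = pos)
  class(out) <- c("importance_distribution", class(out))
  attr(out, "y") <- attr(map, "y")
  attr(out, "conformer") <- conf
  out
}

#' Interaction range of an importance distribution
#'
#' Two estimators of how far the model's learned interactions reach:
#' `threshold` returns the maximum walk extent among walks whose importance
#' reaches `p_min` (the learned range in the sense that negligibly probable
#' walks cannot set it; `p_min = 0` is rejected because it would always
#' return the geometric maximum). `power` returns the generalized
#' expectation `(sum p_w d(w)^a)^(1/a)`: `a = 1` is the expected extent and
#' large `a` approaches the maximum extent from below.
#'
#' @param dist A [walk_importance()] result.
#' @param method `"threshold"` or `"power"`.
#' @param p_min Importance threshold (> 0); default 0.001.
#' @param a Generalized-expectation order (> 0); default 4.
#' @return A one-row tibble: `method`, `param`, `lambda` (Angstrom).
#' @export
interaction_range <- function(dist, method = c("threshold", "power"),
                              p_min = 0.001, a = 4) {
  method <- match.arg(method)
  if (method == "threshold") {
    if (p_min <= 0) stop("`p_min` must be > 0")
    keep <- dist$p >= p_min
    lambda <- if (any(keep)) max(dist$extent[keep]) else {
      warning("no walk reaches p_min = ", p_min, "; returning 0")
      0
    }
    tibble::tibble(method = "threshold", param = p_min, lambda = lambda)
  } else {
    if (a <= 0) stop("`a` must be > 0")
    keep <- dist$p > 0 & dist$extent > 0
    lambda <- if (!any(keep)) 0 else {
      # log-space evaluation so large orders do not overflow
      lp <- log(dist$p[keep]) + a * log(dist$extent[keep])
      mx <- max(lp)
      exp((mx + log(sum(exp(lp - mx)))) / a)
    }
    tibble::tibble(method = "power", param = a, lambda = lambda)
  }
}

#' Range summary for one conformer
#'
#' Convenience wrapper returning both range statistics in one row.
#'
#' @param dist A [walk_importance()] result.
#' @param p_min Threshold importance (default 0.001).
#' @param a Generalized-expectation order (default 4).
#' @return One-row tibble: `lambda_thresh`, `p_min`, `lambda_pow`, `a`.
#' @export
range_summary <- function(dist, p_min = 0.001, a = 4) {
  tibble::tibble(
    lambda_thresh = interaction_range(dist, "threshold", p_min = p_min)$lambda,
    p_min = p_min,
    lambda_pow = interaction_range(dist, "power", a = a)$lambda,
    a = a
  )
}

#' Pairwise interaction strength from walk relevances
#'
#' The inclusive strength of a pair is the summed importance of all walks
#' whose visited-atom set contains both atoms (context included); the
#' exclusive strength counts only walks whose visited set is exactly the
#' pair. Inclusive is therefore never smaller than exclusive. Both are
#' symmetric by construction. With `include_self = TRUE`, diagonal rows hold
#' the summed importance of walks visiting only that atom.
#'
#' @param map A [walk_relevances()] result.
#' @param mode `"inclusive"`, `"exclusive"`, or `"both"` (rows for each).
#' @param include_self Include `i == j` rows (self strength).
#' @param conf Optional conformer overriding the map's stored conformer.
#' @return A tibble: `i`, `j`, `element_i`, `element_j`, `distance`
#'   (Angstrom), `mode`, `strength`.
#' @export
pair_interaction_strength <- function(map,
                                      mode = c("inclusive", "exclusive", "both"),
                                      include_self = FALSE,
                                      conf = NULL) {
  mode <- match.arg(mode)
  conf <- conf %||% attr(map, "conformer")
  if (is.null(conf)) stop("no conformer attached to the map")
  dist_tab <- walk_importance(map, conf)
  n <- nrow(conf)
  member <- matrix(FALSE, nrow(dist_tab), n)
  for (w in seq_len(nrow(dist_tab))) {
    member[w, unique(dist_tab$atoms[[w]])] <- TRUE
  }
  n_visited <- rowSums(member)
  pd <- pair_distances(conf)
  one_mode <- function(m) {
    s <- vapply(seq_len(nrow(pd)), function(r) {
      i <- pd$i[r]
      j <- pd$j[r]
      hits <- if (m == "inclusive") {
        member[, i] & member[, j]
      } else {
        member[, i] & member[, j] & n_visited == 2
      }
      sum(dist_tab$p[hits])
    }, numeric(1))
    out <- pd
    out$mode <- m
    out$strength <- s
    if (include_self) {
      self <- tibble::tibble(
        i = seq_len(n), j = seq_len(n),
        element_i = conf$element, element_j = conf$element,
        distance = 0, mode = m,
        strength = vapply(seq_len(n), function(i) {
          sum(dist_tab$p[member[, i] & n_visited == 1])
        }, numeric(1))
      )
      out <- dplyr::bind_rows(out, self)
    }
    out
  }
  if (mode == "both") {
    dplyr::bind_rows(one_mode("inclusive"), one_mode("exclusive"))
  } else {
    one_mode(mode)
  }
}

#' Element-pair mean log strength matrix
#'
#' Aggregates a (multi-conformer) pair-strength table into per-element-pair
#' cells, split into bonded and nonbonded distance classes at `split`
#' (default 1.6 Angstrom). Each cell is the mean of `log10(strength)` over
#' its pairs; zero or negative strengths are excluded from the log and
#' counted in the `excluded_nonpositive` attribute. Cells with no pairs are
#' simply absent (never zero-filled). Element pairs are unordered, so the
#' table is symmetric by construction.
#'
#' @param pairs A pair-strength table (rows from
#'   [pair_interaction_strength()] or [analytic_pair_strengths()], possibly
#'   row-bound over many conformers).
#' @param split Bonded/nonbonded split distance (Angstrom).
#' @return A tibble: `element_a`, `element_b` (sorted within pair), `class`
#'   (`"bonded"` / `"nonbonded"`), `mean_log10_strength`, `n_pairs`.
#' @export
element_pair_matrix <- function(pairs, split = 1.6) {
  excluded <- sum(pairs$strength <= 0)
  pairs <- dplyr::filter(pairs, .data$strength > 0)
  out <- pairs |>
    dplyr::mutate(
      element_a = pmin(.data$element_i, .data$element_j),
      element_b = pmax(.data$element_i, .data$element_j),
      class = ifelse(.data$distance < split, "bonded", "nonbonded")
    ) |>
    dplyr::group_by(.data$element_a, .data$element_b, .data$class) |>
    dplyr::summarise(
      mean_log10_strength = mean(log10(.data$strength)),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "excluded_nonpositive") <- excluded
  out
}

# 100th/10th-percentile log ratio of one strength set (linear interpolation
# between order statistics, R quantile type 7).
strength_gamma <- function(strengths) {
  q <- stats::quantile(strengths, c(0.1, 1), type = 7, names = FALSE)
  log10(q[2] / q[1])
}

#' Many-bodyness profile of pair interaction strengths
#'
#' Bins atom pairs by distance and measures, per bin, by how many orders of
#' magnitude the interaction strength varies among equally distant pairs:
#' `gamma(R) = log10(P100(S_R) / P10(S_R))` with the 100th and 10th
#' percentiles of the bin's strength set (the 10th rather than the 0th to
#' blunt outliers). The scalar summary `gamma_bar` is the unweighted mean
#' over retained bins. A strictly 2-body potential gives gamma = 0 in every
#' bin of exactly repeated distances. Zero or negative strengths are
#' excluded from the log-based statistics and counted; bins with fewer than
#' `min_count` pairs are dropped and reported.
#'
#' @param pairs A pair-strength table with `distance` and `strength`
#'   columns (row-bind tables over conformers for aggregate profiles).
#' @param bin_width Bin width (Angstrom), default 0.5.
#' @param min_count Minimum pairs per retained bin, default 20.
#' @return A tibble of class `many_body_profile`: `bin_center`, `bin_width`,
#'   `n`, `p10`, `p100`, `gamma`, `retained`; attributes `gamma_bar`,
#'   `excluded_nonpositive`, `dropped_bins`.
#' @export
many_bodyness <- function(pairs, bin_width = 0.5, min_count = 20) {
  excluded <- sum(pairs$strength <= 0)
  pairs <- dplyr::filter(pairs, .data$strength > 0)
  if (nrow(pairs) == 0) stop("empty profile: no positive strengths")
  prof <- pairs |>
    dplyr::mutate(bin = floor(.data$distance / bin_width)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      p10 = stats::quantile(.data$strength, 0.1, type = 7, names = FALSE),
      p100 = max(.data$strength),
      gamma = strength_gamma(.data$strength),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_center = (.data$bin + 0.5) * bin_width,
      bin_width = bin_width,
      retained = .data$n >= min_count
    ) |>
    dplyr::select(
      "bin_center", "bin_width", "n", "p10", "p100", "gamma", "retained"
    ) |>
    dplyr::arrange(.data$bin_center)
  if (!any(prof$retained)) {
    stop(
      "empty profile after filtering: no bin reaches min_count = ", min_count
    )
  }
  class(prof) <- c("many_body_profile", class(prof))
  attr(prof, "gamma_bar") <- mean(prof$gamma[prof$retained])
  attr(prof, "excluded_nonpositive") <- excluded
  attr(prof, "dropped_bins") <- sum(!prof$retained)
  prof
}

#' Average many-bodyness of a profile
#'
#' @param profile A [many_bodyness()] result.
#' @return The scalar mean of gamma over retained bins.
#' @export
gamma_bar <- function(profile) {
  attr(profile, "gamma_bar")
}

#' Fit decay laws to strength versus distance
#'
#' Bins the samples by distance, takes per-bin medians, and least-squares
#' fits both an exponential (`log s` linear in `r`) and a power law
#' (`log s` linear in `log r`) to the positive medians. Both responses are
#' `log(median)`, so the residual sums of squares are directly comparable;
#' the model with the smaller residual is preferred. Bins with non-positive
#' medians are excluded and reported. A flat profile sets the `degenerate`
#' flag.
#'
#' @param pairs A table with `distance` and `strength` columns.
#' @param bin_width Bin width (Angstrom), default 0.5.
#' @return A list of class `decay_fit`: `exponential` (`rate`, `prefactor`,
#'   `residual`), `power_law` (`exponent`, `prefactor`, `residual`),
#'   `preferred`, `degenerate`, `bins` (tibble of per-bin medians),
#'   `excluded_bins`.
#' @export
decay_fit <- function(pairs, bin_width = 0.5) {
  bins <- pairs |>
    dplyr::mutate(bin = floor(.data$distance / bin_width)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      center = (.data$bin[1] + 0.5) * bin_width,
      median_strength = stats::median(.data$strength),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$center)
  if (nrow(bins) < 5) {
    stop("need >= 5 occupied distance bins, got ", nrow(bins))
  }
  pos <- bins$median_strength > 0 & bins$center > 0
  excluded <- sum(!pos)
  fit_bins <- bins[pos, ]
  if (nrow(fit_bins) < 3) stop("too few positive medians to fit")
  ls <- log(fit_bins$median_strength)
  fe <- stats::lm(ls ~ fit_bins$center)
  fp <- stats::lm(ls ~ log(fit_bins$center))
  rss <- function(f) sum(stats::residuals(f)^2)
  degenerate <- stats::sd(ls) < 1e-10
  out <- list(
    exponential = list(
      rate = -unname(stats::coef(fe)[2]),
      prefactor = exp(unname(stats::coef(fe)[1])),
      residual = rss(fe)
    ),
    power_law = list(
      exponent = unname(stats::coef(fp)[2]),
      prefactor = exp(unname(stats::coef(fp)[1])),
      residual = rss(fp)
    ),
    degenerate = degenerate,
    bins = fit_bins,
    excluded_bins = excluded
  )
  out$preferred <- if (out$exponential$residual <= out$power_law$residual) {
    "exponential"
  } else {
    "power_law"
  }
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> preferred:", x$preferred,
      if (x$degenerate) "(degenerate: flat profile)" else "", "\n")
  cat(sprintf(
    " exponential: s ~ %.3g exp(-%.3g r), RSS %.3g\n",
    x$exponential$prefactor, x$exponential$rate, x$exponential$residual
  ))
  cat(sprintf(
    " power law:   s ~ %.3g r^%.3g, RSS %.3g\n",
    x$power_law$prefactor, x$power_law$exponent, x$power_law$residual
  ))
  invisible(x)
}
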