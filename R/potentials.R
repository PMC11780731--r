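#' Morse pair-potential parameters
#'
#' The synthetic 2-body potential is a Morse well,
#' `u(r) = D (1 - exp(-a (r - r_e)))^2 - D`, in kcal/mol with distances in
#' Angstrom. Per-element-pair overrides may replace any of the three
#' constants for specific unordered element pairs.
#'
#' @param well_depth Well depth D (kcal/mol), > 0.
#' @param equilibrium_distance Minimum position r_e (Angstrom), > 0.
#' @param width Inverse-width a (1/Angstrom), > 0.
#' @param overrides Optional data frame with columns `element_a`,
#'   `element_b` and any of `well_depth`, `equilibrium_distance`, `width`.
#' @return A list of class `pair_potential_params`.
#' @export
pair_potential_params <- function(well_depth = 5,
                                  equilibrium_distance = 1.5,
                                  width = 1.5,
                                  overrides = NULL) {
  if (well_depth <= 0 || equilibrium_distance <= 0 || width <= 0) {
    stop("`well_depth`, `equilibrium_distance` and `width` must all be > 0")
  }
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    stopifnot(all(c("element_a", "element_b") %in% names(overrides)))
  }
  structure(
    list(
      well_depth = well_depth,
      equilibrium_distance = equilibrium_distance,
      width = width,
      overrides = overrides
    ),
    class = "pair_potential_params"
  )
}

# Resolve (D, r_e, a) for a vector of element pairs.
resolve_pair_constants <- function(el_a, el_b, params) {
  n <- length(el_a)
  out <- tibble::tibble(
    well_depth = rep(params$well_depth, n),
    equilibrium_distance = rep(params$equilibrium_distance, n),
    width = rep(params$width, n)
  )
  ov <- params$overrides
  if (!is.null(ov) && nrow(ov) > 0) {
    key <- paste(pmin(el_a, el_b), pmax(el_a, el_b))
    okey <- paste(pmin(ov$element_a, ov$element_b), pmax(ov$element_a, ov$element_b))
    hit <- match(key, okey)
    for (f in intersect(names(ov), names(out))) {
      idx <- which(!is.na(hit))
      out[[f]][idx] <- ov[[f]][hit[idx]]
    }
  }
  out
}

morse_term <- function(r, D, re, a) {
  D * (1 - exp(-a * (r - re)))^2 - D
}

#' Total 2-body energy of a conformer
#'
#' Sums the Morse term over all unordered atom pairs. The per-pair term
#' depends only on the element pair and the distance, so the potential is
#' strictly 2-body (fully isotropic).
#'
#' @param conf A conformer.
#' @param params A [pair_potential_params()].
#' @return A list with `total` (kcal/mol) and `terms`, a tibble with one row
#'   per pair (`i`, `j`, `element_i`, `element_j`, `distance`, `energy`);
#'   `total` equals `sum(terms$energy)` exactly.
#' @export
pairwise_energy <- function(conf, params = pair_potential_params()) {
  pd <- pair_distances(conf)
  if (nrow(pd) > 0 && any(!is.finite(pd$distance))) {
    stop("non-finite pair distance")
  }
  cst <- resolve_pair_constants(pd$element_i, pd$element_j, params)
  pd$energy <- morse_term(
    pd$distance, cst$well_depth,
    cst$equilibrium_distance, cst$width
  )
  list(total = sum(pd$energy), terms = pd)
}

#' Three-body potential parameters
#'
#' The 3-body term couples each atom triple through the bond angles at every
#' vertex: for center atom c with neighbours p, q the contribution is
#' `A sin^2(theta_pcq) exp(-(r_cp + r_cq) / rho)`, summed over the three
#' vertex choices of the triple. The `sin^2` form vanishes in closed form on
#' exactly collinear triples; the exponential damping (range scale `rho`)
#' keeps the term short-ranged. Amplitude 0 disables the term.
#'
#' @param amplitude A (kcal/mol), >= 0.
#' @param range_scale rho (Angstrom), > 0.
#' @param form Angular form identifier; only `"sin2"` is defined.
#' @return A list of class `three_body_params`.
#' @export
three_body_params <- function(amplitude = 0, range_scale = 3, form = "sin2") {
  if (amplitude < 0) stop("`amplitude` must be >= 0 (0 disables the term)")
  if (range_scale <= 0) stop("`range_scale` must be > 0")
  form <- match.arg(form, "sin2")
  structure(
    list(amplitude = amplitude, range_scale = range_scale, form = form),
    class = "three_body_params"
  )
}

#' Total 3-body energy of a conformer
#'
#' @param conf A conformer.
#' @param params A [three_body_params()].
#' @return A list with `total` (kcal/mol) and `terms`, a tibble with one row
#'   per unordered atom triple (`i`, `j`, `k`, `energy`); `total` equals
#'   `sum(terms$energy)` exactly, and is 0 when `amplitude` is 0.
#' @export
three_body_energy <- function(conf, params = three_body_params()) {
  n <- nrow(conf)
  empty <- tibble::tibble(
    i = integer(), j = integer(), k = integer(), energy = numeric()
  )
  if (n < 3 || params$amplitude == 0) {
    if (n >= 3 && params$amplitude == 0) {
      trip <- utils::combn(n, 3)
      empty <- tibble::tibble(
        i = trip[1, ], j = trip[2, ], k = trip[3, ],
        energy = numeric(ncol(trip))
      )
    }
    return(list(total = 0, terms = empty))
  }
  pos <- conformer_positions(conf)
  trip <- utils::combn(n, 3)
  energy <- vapply(seq_len(ncol(trip)), function(t) {
    triple_term(pos[trip[, t], , drop = FALSE], params)
  }, numeric(1))
  terms <- tibble::tibble(
    i = trip[1, ], j = trip[2, ], k = trip[3, ], energy = energy
  )
  list(total = sum(terms$energy), terms = terms)
}

# One triple's 3-body term: sum over the three vertex (center) choices.
triple_term <- function(p3, params) {
  total <- 0
  for (c_idx in 1:3) {
    others <- setdiff(1:3, c_idx)
    v1 <- p3[others[1], ] - p3[c_idx, ]
    v2 <- p3[others[2], ] - p3[c_idx, ]
    r1 <- sqrt(sum(v1^2))
    r2 <- sqrt(sum(v2^2))
    if (r1 == 0 || r2 == 0) stop("degenerate triple: coincident atoms")
    cosang <- max(-1, min(1, sum(v1 * v2) / (r1 * r2)))
    sin2 <- 1 - cosang^2
    total <- total +
      params$amplitude * sin2 * exp(-(r1 + r2) / params$range_scale)
  }
  total
}

#' Analytic ground-truth pair interaction strengths
#'
#' For the strictly 2-body potential the strength of a pair is the absolute
#' Morse term, a function of the element pair and distance only — identical
#' distances give identical strengths no matter the neighborhood, so the
#' many-bodyness of these strengths is exactly zero. When `three_body` is
#' supplied with positive amplitude, each triple's absolute energy is
#' attributed in equal shares to its three pairs, making the strength depend
#' on the neighborhood and injecting many-bodyness of known origin.
#'
#' @param conf A conformer.
#' @param params A [pair_potential_params()].
#' @param three_body Optional [three_body_params()]; `NULL` or amplitude 0
#'   keeps the strengths strictly 2-body.
#' @return A tibble with one row per unordered pair: `i`, `j`, `element_i`,
#'   `element_j`, `distance`, `strength` (kcal/mol, >= 0).
#' @export
analytic_pair_strengths <- function(conf,
                                    params = pair_potential_params(),
                                    three_body = NULL) {
  pe <- pairwise_energy(conf, params)
  tab <- pe$terms
  tab$strength <- abs(tab$energy)
  tab$energy <- NULL
  if (!is.null(three_body) && three_body$amplitude > 0 && nrow(conf) >= 3) {
    te <- three_body_energy(conf, three_body)$terms
    key <- paste(tab$i, tab$j)
    for (t in seq_len(nrow(te))) {
      trio <- c(te$i[t], te$j[t], te$k[t])
      share <- abs(te$energy[t]) / 3
      pk <- c(
        paste(trio[1], trio[2]),
        paste(trio[1], trio[3]),
        paste(trio[2], trio[3])
      )
      idx <- match(pk, key)
      tab$strength[idx] <- tab$strength[idx] + share
    }
  }
  tab
}

#' Label a conformer set with analytic energies
#'
#' @param conformers A conformer-set tibble (from [generate_conformers()]).
#' @param params A [pair_potential_params()].
#' @param three_body Optional [three_body_params()].
#' @return The input tibble with an `energy` column (kcal/mol).
#' @export
label_conformers <- function(conformers,
                             params = pair_potential_params(),
                             three_body = NULL) {
  conformers <- as_conformer_set(conformers)
  conformers$energy <- vapply(conformers$conformer, function(cf) {
    e <- pairwise_energy(cf, params)$total
    if (!is.null(three_body)) e <- e + three_body_energy(cf, three_body)$total
    e
  }, numeric(1))
  conformers
}
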