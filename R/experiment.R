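#' Classify molecular-dynamics energy series for stability
#'
#' A trajectory is unstable iff any potential-energy sample leaves the
#' allowed band (default -200 to 200 kcal/mol, the bound under which an
#' abrupt energy excursion typically signals a dissociated atom). Non-finite
#' samples mark the trajectory unstable with a flag.
#'
#' @param energies Either a numeric vector (one trajectory, kcal/mol) or a
#'   data frame with columns `trajectory` and `energy`.
#' @param bounds Length-2 numeric `(lower, upper)` in kcal/mol.
#' @return A tibble with one row per trajectory: `trajectory`, `label`
#'   (`"stable"`/`"unstable"`), `first_violation` (index of the first
#'   out-of-bounds sample, `NA` if stable), `non_finite` flag, `lower`,
#'   `upper`.
#' @examples
#' classify_stability(c(-50, -48, -55))
#' classify_stability(c(-50, 500, -55))
#' @export
classify_stability <- function(energies, bounds = c(-200, 200)) {
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("`bounds` must be (lower, upper) with lower < upper")
  }
  if (is.data.frame(energies)) {
    stopifnot(all(c("trajectory", "energy") %in% names(energies)))
    return(
      energies |>
        dplyr::group_by(.data$trajectory) |>
        dplyr::summarise(
          classify_one(.data$energy, bounds),
          .groups = "drop"
        )
    )
  }
  out <- classify_one(energies, bounds)
  out$trajectory <- 1L
  out[, c("trajectory", names(out)[names(out) != "trajectory"])]
}

classify_one <- function(e, bounds) {
  if (length(e) == 0) stop("empty energy series")
  bad <- !is.finite(e) | e < bounds[1] | e > bounds[2]
  tibble::tibble(
    label = if (any(bad)) "unstable" else "stable",
    first_violation = if (any(bad)) which(bad)[1] else NA_integer_,
    non_finite = any(!is.finite(e)),
    lower = bounds[1],
    upper = bounds[2]
  )
}

#' Assemble an experiment configuration
#'
#' Bundles the conformer generator, the model (either one configuration or
#' a depth ladder sharing a fixed depth-times-cutoff product), the training
#' schedule and the metric parameters. Serializable to YAML with
#' [write_experiment_config()].
#'
#' @param generator A [generator_spec()].
#' @param pair_potential A [pair_potential_params()].
#' @param three_body Optional [three_body_params()].
#' @param depths Integer vector of ladder depths; with `ladder_product` set,
#'   each depth L gets cutoff `ladder_product / L` and
#'   `n_rbf = round(4 * cutoff)`.
#' @param ladder_product Depth-times-cutoff product (Angstrom); `NULL` uses
#'   `cutoff` directly for every depth.
#' @param cutoff Cutoff when no ladder product is given.
#' @param embedding,epochs,lr Training/model knobs.
#' @param checkpoint_every Snapshot cadence in epochs (0 snapshots only the
#'   untrained initialization and the final model).
#' @param n_explain Held-out conformers used for relevance extraction.
#' @param p_min,a,bin_width,split Metric parameters (threshold importance,
#'   generalized-expectation order, distance bin width, bonded split).
#' @param stability_bounds Energy band for [classify_stability()].
#' @param seed Experiment seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_spec("random_cluster",
                                n_atoms = 6, n_samples = 80
                              ),
                              pair_potential = pair_potential_params(),
                              three_body = NULL,
                              depths = 2,
                              ladder_product = NULL,
                              cutoff = 5,
                              embedding = 12,
                              epochs = 60,
                              lr = 0.01,
                              checkpoint_every = 0,
                              n_explain = 5,
                              p_min = 0.001,
                              a = 4,
                              bin_width = 0.5,
                              split = 1.6,
                              stability_bounds = c(-200, 200),
                              seed = 1) {
  if (!is.null(ladder_product) && ladder_product <= 0) {
    stop("`ladder_product` must be > 0")
  }
  structure(
    list(
      generator = generator, pair_potential = pair_potential,
      three_body = three_body, depths = as.integer(depths),
      ladder_product = ladder_product, cutoff = cutoff,
      embedding = as.integer(embedding), epochs = as.integer(epochs),
      lr = lr, checkpoint_every = as.integer(checkpoint_every),
      n_explain = as.integer(n_explain), p_min = p_min, a = a,
      bin_width = bin_width, split = split,
      stability_bounds = stability_bounds, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Write / read an experiment configuration (YAML)
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `path` invisibly; the reader returns the config.
#' @export
write_experiment_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML renders NULL fields as empty sequences; normalize them back
  nz <- function(x) if (is.null(x) || length(x) == 0) NULL else x
  gen <- do.call(generator_spec, raw$generator)
  pp <- do.call(pair_potential_params, raw$pair_potential[
    setdiff(names(raw$pair_potential), "overrides")
  ])
  tb <- if (!is.null(nz(raw$three_body))) {
    do.call(three_body_params, raw$three_body)
  }
  experiment_config(
    generator = gen, pair_potential = pp, three_body = tb,
    depths = raw$depths, ladder_product = nz(raw$ladder_product),
    cutoff = raw$cutoff, embedding = raw$embedding, epochs = raw$epochs,
    lr = raw$lr, checkpoint_every = raw$checkpoint_every,
    n_explain = raw$n_explain, p_min = raw$p_min, a = raw$a,
    bin_width = raw$bin_width, split = raw$split,
    stability_bounds = unlist(raw$stability_bounds), seed = raw$seed
  )
}

#' Run a full explanation experiment
#'
#' Generates and labels conformers, trains one model per ladder depth,
#' extracts walk relevances on held-out conformers at every parameter
#' checkpoint (always including the untrained initialization, epoch 0), and
#' computes the metric suite on the final model. Everything is
#' deterministic for a fixed config: two runs write identical reports.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory; created if missing. When `NULL`, no
#'   files are written and the report bundle is only returned.
#' @return A list of class `experiment_report`: `range_tracking` (tibble:
#'   depth, checkpoint epoch, conformer id, lambda_thresh, lambda_pow),
#'   `pair_strengths`, `many_body`, `decay`, `element_matrix`, `history`,
#'   `models`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- "generate"
  report <- list()
  on.exit({
    if (!is.null(out_dir)) {
      try(write_report(report, out_dir, partial = TRUE), silent = TRUE)
    }
  })
  result <- tryCatch({
    data <- generate_conformers(config$generator)
    data <- label_conformers(data, config$pair_potential, config$three_body)
    n <- nrow(data)
    n_explain <- min(config$n_explain, max(1, floor(n / 5)))
    explain_idx <- with_seed(config$seed + 1, sample.int(n, n_explain))
    train_data <- data[setdiff(seq_len(n), explain_idx), ]
    explain_data <- data[explain_idx, ]

    elements <- sort(unique(unlist(
      lapply(data$conformer, function(cf) cf$element)
    )))
    ladder <- lapply(config$depths, function(L) {
      cutoff <- if (!is.null(config$ladder_product)) {
        config$ladder_product / L
      } else {
        config$cutoff
      }
      model_config(
        depth = L, cutoff = cutoff, embedding = config$embedding,
        elements = elements
      )
    })

    stage <- "train"
    ckpts <- if (config$checkpoint_every > 0) {
      seq(config$checkpoint_every, config$epochs, by = config$checkpoint_every)
    } else {
      config$epochs
    }
    models <- lapply(ladder, function(mc) {
      train_model(train_data, mc,
        seed = config$seed, epochs = config$epochs, lr = config$lr,
        checkpoints = ckpts
      )
    })

    stage <- "explain"
    range_tracking <- purrr::map2_dfr(models, config$depths, function(model, L) {
      purrr::map_dfr(names(model$checkpoints), function(ep) {
        snap <- list(params = model$checkpoints[[ep]], config = model$config)
        purrr::map_dfr(seq_len(nrow(explain_data)), function(i) {
          map <- walk_relevances(snap, explain_data$conformer[[i]])
          dist <- walk_importance(map)
          rs <- range_summary(dist, p_min = config$p_min, a = config$a)
          dplyr::bind_cols(
            tibble::tibble(
              depth = L, epoch = as.integer(ep),
              conformer_id = explain_data$id[i]
            ),
            rs
          )
        })
      })
    })

    stage <- "metrics"
    final_strengths <- purrr::map_dfr(seq_along(models), function(mi) {
      purrr::map_dfr(seq_len(nrow(explain_data)), function(i) {
        map <- walk_relevances(models[[mi]], explain_data$conformer[[i]])
        tab <- pair_interaction_strength(map, mode = "inclusive")
        tab$depth <- config$depths[mi]
        tab$conformer_id <- explain_data$id[i]
        tab
      })
    })
    deepest <- final_strengths[
      final_strengths$depth == max(config$depths),
    ]
    many_body <- many_bodyness(deepest,
      bin_width = config$bin_width,
      min_count = max(2, min(10, nrow(deepest) %/% 10))
    )
    decay <- tryCatch(
      decay_fit(deepest, bin_width = config$bin_width),
      error = function(e) NULL
    )
    element_matrix <- element_pair_matrix(deepest, split = config$split)

    history <- purrr::map2_dfr(models, config$depths, function(m, L) {
      dplyr::mutate(m$history, depth = L)
    })

    manifest <- list(
      package = "walklrp",
      version = as.character(utils::packageVersion("walklrp")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      n_conformers = n,
      explain_ids = explain_data$id,
      depths = config$depths,
      metric_params = list(
        p_min = config$p_min, a = config$a,
        bin_width = config$bin_width, split = config$split
      )
    )
    report <- structure(
      list(
        range_tracking = range_tracking,
        pair_strengths = final_strengths,
        many_body = many_body,
        decay = decay,
        element_matrix = element_matrix,
        history = history,
        models = models,
        manifest = manifest
      ),
      class = "experiment_report"
    )
    report
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
      call. = FALSE
    )
  })
  on.exit()
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

write_report <- function(report, out_dir, partial = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wcsv(report$range_tracking, "range_tracking.csv")
  wcsv(report$pair_strengths, "pair_strengths.csv")
  if (!is.null(report$many_body)) {
    mb <- tibble::as_tibble(report$many_body)
    mb$gamma_bar <- gamma_bar(report$many_body)
    wcsv(mb, "many_bodyness.csv")
  }
  wcsv(report$element_matrix, "element_matrix.csv")
  wcsv(report$history, "history.csv")
  if (!is.null(report$decay)) {
    d <- report$decay
    wcsv(
      tibble::tibble(
        model = c("exponential", "power_law"),
        parameter = c(d$exponential$rate, d$power_law$exponent),
        prefactor = c(d$exponential$prefactor, d$power_law$prefactor),
        residual = c(d$exponential$residual, d$power_law$residual),
        preferred = c(d$preferred == "exponential", d$preferred == "power_law")
      ),
      "decay_fit.csv"
    )
  }
  if (!is.null(report$manifest)) {
    manifest <- report$manifest
    manifest$partial <- partial
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out_dir)
}
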