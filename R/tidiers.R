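#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted toy potential
#'
#' One row per parameter block with its shape and magnitude summary.
#'
#' @param x An `ff_model`.
#' @param ... Unused.
#' @return A tibble: `block`, `layer`, `rows`, `cols`, `rms`.
#' @method tidy ff_model
#' @export
tidy.ff_model <- function(x, ...) {
  block_row <- function(name, layer, W) {
    W <- as.matrix(W)
    tibble::tibble(
      block = name, layer = layer,
      rows = nrow(W), cols = ncol(W),
      rms = sqrt(mean(W^2))
    )
  }
  rows <- list(block_row("embedding", NA_integer_, x$params$emb))
  for (t in seq_along(x$params$layers)) {
    for (nm in c("Wf1", "Wf2", "Wm", "Wc1", "Wc2")) {
      rows[[length(rows) + 1]] <- block_row(nm, t, x$params$layers[[t]][[nm]])
    }
  }
  rows[[length(rows) + 1]] <- block_row("Wr1", NA_integer_, x$params$readout$Wr1)
  rows[[length(rows) + 1]] <- block_row(
    "wr2", NA_integer_, matrix(x$params$readout$wr2, nrow = 1)
  )
  dplyr::bind_rows(rows)
}

#' Glance at a fitted toy potential
#'
#' @param x An `ff_model`.
#' @param ... Unused.
#' @return A one-row tibble: `depth`, `cutoff`, `n_rbf`, `embedding`,
#'   `epochs`, `train_rmse`, `val_rmse`, `n_train`, `n_val`.
#' @method glance ff_model
#' @export
glance.ff_model <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(epoch = 0L, train_rmse = NA_real_, val_rmse = NA_real_)
  tibble::tibble(
    depth = x$config$depth, cutoff = x$config$cutoff,
    n_rbf = x$config$n_rbf, embedding = x$config$embedding,
    epochs = last$epoch, train_rmse = last$train_rmse,
    val_rmse = last$val_rmse,
    n_train = x$n_train %||% NA_integer_, n_val = x$n_val %||% NA_integer_
  )
}

#' Tidy a decay fit
#'
#' @param x A [decay_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per candidate model: `model`, `parameter`
#'   (decay rate for the exponential, exponent for the power law),
#'   `prefactor`, `residual`, `preferred`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    model = c("exponential", "power_law"),
    parameter = c(x$exponential$rate, x$power_law$exponent),
    prefactor = c(x$exponential$prefactor, x$power_law$prefactor),
    residual = c(x$exponential$residual, x$power_law$residual),
    preferred = c(x$preferred == "exponential", x$preferred == "power_law")
  )
}

#' Glance at a decay fit
#'
#' @param x A [decay_fit()] result.
#' @param ... Unused.
#' @return One-row tibble: `preferred`, `degenerate`, `n_bins`,
#'   `excluded_bins`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    preferred = x$preferred,
    degenerate = x$degenerate,
    n_bins = nrow(x$bins),
    excluded_bins = x$excluded_bins
  )
}
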