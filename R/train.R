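# Reverse-mode gradients of the mean-squared energy loss.
# `fw` is a forward_batch() result, `dY` the loss gradient per molecule.
backward_batch <- function(params, config, fw, dY) {
  batch <- fw$batch
  actg <- act_grad_fn(config)
  n <- batch$n_atoms
  grads <- list(
    emb = matrix(0, nrow(params$emb), ncol(params$emb)),
    layers = lapply(params$layers, function(W) lapply(W, function(x) x * 0)),
    readout = list(
      Wr1 = params$readout$Wr1 * 0,
      wr2 = params$readout$wr2 * 0
    )
  )
  dAtom <- dY[batch$mol]
  grads$readout$wr2 <- colSums(fw$ZR * dAtom)
  dZR <- outer(dAtom, params$readout$wr2)
  dR1 <- dZR * actg(fw$R1)
  HT <- fw$Hs[[config$depth + 1]]
  grads$readout$Wr1 <- t(dR1) %*% HT
  dH <- dR1 %*% params$readout$Wr1
  for (t in rev(seq_len(config$depth))) {
    W <- params$layers[[t]]
    cache <- fw$caches[[t]]
    Hp <- fw$Hs[[t]]
    dZ1 <- dH %*% W$Wc2
    grads$layers[[t]]$Wc2 <- t(dH) %*% cache$Z1
    dA1 <- dZ1 * actg(cache$A1)
    grads$layers[[t]]$Wc1 <- t(dA1) %*% cache$U
    dU <- dA1 %*% W$Wc1
    dHp <- dU
    if (length(batch$src) > 0) {
      dEM <- dU[batch$dst, , drop = FALSE]
      G <- cache$filt$G
      dMSG <- rowsum_full(dEM * G, batch$src, n)
      grads$layers[[t]]$Wm <- t(dMSG) %*% Hp
      dHp <- dHp + dMSG %*% W$Wm
      if (is.null(params$filter_override)) {
        dG <- dEM * cache$MSG[batch$src, , drop = FALSE]
        dGfc <- dG * batch$fc
        grads$layers[[t]]$Wf2 <- t(dGfc) %*% cache$filt$Fz
        dFa <- (dGfc %*% W$Wf2) * actg(cache$filt$Fa)
        grads$layers[[t]]$Wf1 <- t(dFa) %*% batch$phi
      }
    }
    dH <- dHp
  }
  grads$emb <- rowsum_full(dH, batch$zid, nrow(params$emb))
  grads
}

# Flatten/unflatten parameters for the Adam update.
flatten_params <- function(p) {
  unlist(list(
    emb = p$emb,
    layers = lapply(p$layers, function(W) W[c("Wf1", "Wf2", "Wm", "Wc1", "Wc2")]),
    readout = p$readout
  ), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 1L
  take <- function(x) {
    v <- vec[pos:(pos + length(x) - 1L)]
    pos <<- pos + length(x)
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  out$emb <- take(template$emb)
  for (t in seq_along(template$layers)) {
    for (nm in c("Wf1", "Wf2", "Wm", "Wc1", "Wc2")) {
      out$layers[[t]][[nm]] <- take(template$layers[[t]][[nm]])
    }
  }
  out$readout$Wr1 <- take(template$readout$Wr1)
  out$readout$wr2 <- take(template$readout$wr2)
  out
}

#' Train the toy potential on labeled conformers
#'
#' Full-batch Adam on the mean squared energy error. The train/validation
#' split, parameter initialization and every other source of randomness
#' derive deterministically from `seed`. Parameter snapshots can be kept at
#' selected epochs (epoch 0 — the untrained initialization — is always
#' kept), so quantities such as the interaction range can be tracked over
#' training.
#'
#' @param data A tibble with a `conformer` list-column and an `energy`
#'   column (kcal/mol), e.g. from [label_conformers()].
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param epochs Number of Adam epochs (0 returns the seeded
#'   initialization).
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of conformers held out for validation.
#' @param checkpoints Integer epochs at which to snapshot parameters.
#' @return A list of class `ff_model`: `params`, `config`, `history` (tibble
#'   `epoch`, `train_rmse`, `val_rmse`), `checkpoints` (named list of
#'   parameter snapshots), `seed`.
#' @export
train_model <- function(data, config, seed = 1, epochs = 200, lr = 5e-3,
                        val_fraction = 0.2, checkpoints = integer(0)) {
  data <- as_conformer_set(data)
  if (nrow(data) < 1) stop("`data` must contain at least one conformer")
  if (!"energy" %in% names(data)) stop("`data` must have an `energy` column")
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in [0, 1)")
  }
  n <- nrow(data)
  n_val <- floor(val_fraction * n)
  idx <- with_seed(seed, sample.int(n))
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)
  train_batch <- build_batch(data[train_idx, ], config)
  val_batch <- if (n_val > 0) build_batch(data[val_idx, ], config) else NULL
  y_train <- data$energy[train_idx]
  y_val <- data$energy[val_idx]

  params <- init_params(config, seed)
  theta <- flatten_params(params)
  m1 <- v1 <- numeric(length(theta))
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  history <- vector("list", epochs)
  snaps <- list(`0` = unflatten_params(theta, params))
  rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))
  for (ep in seq_len(epochs)) {
    p <- unflatten_params(theta, params)
    fw <- forward_batch(p, config, train_batch)
    resid <- fw$y - y_train
    loss <- mean(resid^2)
    if (!is.finite(loss)) stop("training diverged at epoch ", ep)
    g <- backward_batch(p, config, fw, 2 * resid / length(resid))
    gv <- flatten_params(g)
    m1 <- b1 * m1 + (1 - b1) * gv
    v1 <- b2 * v1 + (1 - b2) * gv^2
    mhat <- m1 / (1 - b1^ep)
    vhat <- v1 / (1 - b2^ep)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    val_rmse <- NA_real_
    if (!is.null(val_batch)) {
      pv <- unflatten_params(theta, params)
      val_rmse <- rmse(forward_batch(pv, config, val_batch)$y, y_val)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_rmse = sqrt(loss), val_rmse = val_rmse
    )
    if (ep %in% checkpoints) {
      snaps[[as.character(ep)]] <- unflatten_params(theta, params)
    }
  }
  structure(
    list(
      params = unflatten_params(theta, params),
      config = config,
      history = dplyr::bind_rows(history),
      checkpoints = snaps,
      seed = seed,
      n_train = length(train_idx),
      n_val = n_val
    ),
    class = "ff_model"
  )
}

#' @export
print.ff_model <- function(x, ...) {
  cat(
    "<ff_model> depth", x$config$depth, "| cutoff", x$config$cutoff,
    "A | embedding", x$config$embedding, "\n"
  )
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(
      " epochs:", last$epoch,
      "| train RMSE:", signif(last$train_rmse, 4),
      "| val RMSE:", signif(last$val_rmse, 4), "kcal/mol\n"
    )
  } else {
    cat(" untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON container with a format-version tag, the embedded model
#' configuration and all parameters at full double precision.
#'
#' @param model An `ff_model` (or a list with `params` and `config`).
#' @param path File path.
#' @return `path` invisibly for `save_model()`; an `ff_model` for
#'   `load_model()`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "walklrp-checkpoint-1",
    config = unclass(model$config),
    params = params_to_plain(model$params),
    seed = model$seed,
    history = if (!is.null(model$history)) model$history else NULL
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path,
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  if (!identical(payload$format, "walklrp-checkpoint-1")) {
    stop("not a walklrp checkpoint (format tag mismatch)")
  }
  cfg <- payload$config
  cfg$elements <- unlist(cfg$elements)
  config <- model_config(
    depth = cfg$depth, cutoff = cfg$cutoff, n_rbf = cfg$n_rbf,
    embedding = cfg$embedding, elements = cfg$elements,
    activation = cfg$activation, filter_hidden = cfg$filter_hidden,
    combine_hidden = cfg$combine_hidden, readout_hidden = cfg$readout_hidden,
    cosine_cutoff = cfg$cosine_cutoff
  )
  structure(
    list(
      params = params_from_plain(payload$params),
      config = config,
      history = if (!is.null(payload$history)) {
        dplyr::bind_rows(payload$history)
      } else {
        NULL
      },
      checkpoints = NULL,
      seed = payload$seed
    ),
    class = "ff_model"
  )
}

params_to_plain <- function(p) {
  list(
    emb = p$emb,
    layers = lapply(p$layers, function(W) W[c("Wf1", "Wf2", "Wm", "Wc1", "Wc2")]),
    readout = list(Wr1 = p$readout$Wr1, wr2 = p$readout$wr2)
  )
}

params_from_plain <- function(p) {
  structure(
    list(
      emb = as.matrix(p$emb),
      layers = lapply(p$layers, function(W) lapply(W, as.matrix)),
      readout = list(
        Wr1 = as.matrix(p$readout$Wr1),
        wr2 = as.numeric(p$readout$wr2)
      ),
      filter_override = NULL
    ),
    class = "model_params"
  )
}
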