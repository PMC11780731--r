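#' Configure the toy message-passing potential
#'
#' A minimal invariant continuous-filter convolution network: element
#' embeddings of width `m`, `T` message-passing layers (a filter MLP over
#' the radial-basis features of each edge gates a linear transform of the
#' source atom's features; aggregation is a sum over neighbours; the combine
#' step is a two-layer MLP on own state plus aggregated message), an
#' atom-wise readout MLP and sum pooling to the scalar energy. The network
#' is bias-free throughout, which keeps relevance propagation exactly
#' conservative in the zero-stabilizer limit.
#'
#' @param depth Number of message-passing layers T (>= 1).
#' @param cutoff Cutoff distance c (Angstrom), > 0.
#' @param n_rbf Radial basis count; default `round(4 * cutoff)` keeps the
#'   basis spacing at 0.25 Angstrom across model ladders.
#' @param embedding Feature width m (neurons per atom).
#' @param elements Element vocabulary.
#' @param activation `"ssp"` (shifted softplus) or `"linear"` (identity;
#'   used by the algebraic relevance oracle).
#' @param filter_hidden Hidden width of the filter MLP.
#' @param combine_hidden Hidden width of the combine MLP.
#' @param readout_hidden Hidden width of the readout MLP.
#' @param cosine_cutoff Logical; multiply each filter by the cosine cutoff
#'   weight so messages vanish smoothly at the cutoff.
#' @return A list of class `model_config`.
#' @export
model_config <- function(depth = 2,
                         cutoff = 5,
                         n_rbf = round(4 * cutoff),
                         embedding = 12,
                         elements = c("H", "C", "N", "O"),
                         activation = c("ssp", "linear"),
                         filter_hidden = 16,
                         combine_hidden = embedding,
                         readout_hidden = 16,
                         cosine_cutoff = TRUE) {
  activation <- match.arg(activation)
  if (depth < 1) stop("`depth` must be >= 1")
  if (cutoff <= 0) stop("`cutoff` must be > 0")
  if (n_rbf < 2) stop("`n_rbf` must be >= 2")
  if (embedding < 1) stop("`embedding` must be >= 1")
  structure(
    list(
      depth = as.integer(depth), cutoff = cutoff, n_rbf = as.integer(n_rbf),
      embedding = as.integer(embedding), elements = elements,
      activation = activation,
      filter_hidden = as.integer(filter_hidden),
      combine_hidden = as.integer(combine_hidden),
      readout_hidden = as.integer(readout_hidden),
      cosine_cutoff = isTRUE(cosine_cutoff)
    ),
    class = "model_config"
  )
}

# shifted softplus: ssp(0) = 0, ssp'(x) = sigmoid(x)
ssp <- function(x) {
  log1p(exp(-abs(x))) + pmax(x, 0) - log(2)
}
ssp_grad <- function(x) 1 / (1 + exp(-x))

act_fn <- function(config) {
  if (config$activation == "linear") identity else ssp
}
act_grad_fn <- function(config) {
  if (config$activation == "linear") function(x) x * 0 + 1 else ssp_grad
}

#' Initialize model parameters from a seed
#'
#' Weights are drawn N(0, 1/sqrt(fan-in)); embeddings N(0, 1). The scheme is
#' fixed: identical seed and config give identical parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A list of class `model_params`: `emb` (vocabulary x m), `layers`
#'   (per layer: filter weights `Wf1`, `Wf2`, message weights `Wm`, combine
#'   weights `Wc1`, `Wc2`) and `readout` (`Wr1`, `wr2`).
#' @export
init_params <- function(config, seed = 1) {
  with_seed(seed, {
    m <- config$embedding
    rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    layers <- lapply(seq_len(config$depth), function(t) {
      list(
        Wf1 = rmat(config$filter_hidden, config$n_rbf, 1 / sqrt(config$n_rbf)),
        Wf2 = rmat(m, config$filter_hidden, 1 / sqrt(config$filter_hidden)),
        Wm = rmat(m, m, 1 / sqrt(m)),
        Wc1 = rmat(config$combine_hidden, m, 1 / sqrt(m)),
        Wc2 = rmat(m, config$combine_hidden, 1 / sqrt(config$combine_hidden))
      )
    })
    structure(
      list(
        emb = rmat(length(config$elements), m, 1),
        layers = layers,
        readout = list(
          Wr1 = rmat(config$readout_hidden, m, 1 / sqrt(m)),
          wr2 = stats::rnorm(config$readout_hidden,
            sd = 1 / sqrt(config$readout_hidden)
          )
        ),
        filter_override = NULL
      ),
      class = "model_params"
    )
  })
}

# Batched graph over one or more conformers: concatenated atoms, a molecule
# index per atom, and a pooled edge list. All forward/backward passes run on
# this structure.
build_batch <- function(conformers, config) {
  conformers <- as_conformer_set(conformers)
  elements <- character()
  mol <- integer()
  src <- integer()
  dst <- integer()
  dists <- numeric()
  offset <- 0L
  for (i in seq_len(nrow(conformers))) {
    cf <- conformers$conformer[[i]]
    g <- build_neighbor_graph(cf, config$cutoff)
    elements <- c(elements, cf$element)
    mol <- c(mol, rep(i, nrow(cf)))
    src <- c(src, g$edges$src + offset)
    dst <- c(dst, g$edges$dst + offset)
    dists <- c(dists, g$edges$distance)
    offset <- offset + nrow(cf)
  }
  zid <- match(elements, config$elements)
  if (anyNA(zid)) {
    stop(
      "element(s) outside the model vocabulary: ",
      paste(unique(elements[is.na(zid)]), collapse = ", ")
    )
  }
  phi <- rbf_expand(dists, config$cutoff, config$n_rbf)
  fc <- if (config$cosine_cutoff) cosine_cutoff(dists, config$cutoff) else rep(1, length(dists))
  list(
    n_atoms = length(elements), n_mol = nrow(conformers),
    elements = elements, zid = zid, mol = mol,
    src = src, dst = dst, dist = dists, phi = phi, fc = fc
  )
}

# rowsum over groups 1..n, keeping empty groups as zero rows.
rowsum_full <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx) > 0) {
    part <- rowsum(x, idx)
    out[as.integer(rownames(part)), ] <- part
  }
  out
}

# Filter (edge gate) matrix G: n_edges x m, plus caches for backprop.
filter_forward <- function(params, layer, batch, config) {
  if (!is.null(params$filter_override)) {
    G <- params$filter_override(batch$dist)
    if (is.null(dim(G))) G <- matrix(G, ncol = config$embedding)
    return(list(G = G * batch$fc, Fa = NULL, Fz = NULL))
  }
  act <- act_fn(config)
  W <- params$layers[[layer]]
  Fa <- batch$phi %*% t(W$Wf1)
  Fz <- act(Fa)
  G <- (Fz %*% t(W$Wf2)) * batch$fc
  list(G = G, Fa = Fa, Fz = Fz)
}

# Forward pass over a batched graph; returns the full trace needed by both
# backprop (training) and relevance propagation.
forward_batch <- function(params, config, batch) {
  act <- act_fn(config)
  n <- batch$n_atoms
  H <- params$emb[batch$zid, , drop = FALSE]
  Hs <- list(H)
  caches <- vector("list", config$depth)
  for (t in seq_len(config$depth)) {
    W <- params$layers[[t]]
    filt <- filter_forward(params, t, batch, config)
    MSG <- H %*% t(W$Wm)
    if (length(batch$src) > 0) {
      EM <- filt$G * MSG[batch$src, , drop = FALSE]
      AGG <- rowsum_full(EM, batch$dst, n)
    } else {
      AGG <- matrix(0, n, config$embedding)
    }
    U <- H + AGG
    A1 <- U %*% t(W$Wc1)
    Z1 <- act(A1)
    Hn <- Z1 %*% t(W$Wc2)
    caches[[t]] <- list(filt = filt, MSG = MSG, U = U, A1 = A1, Z1 = Z1)
    H <- Hn
    Hs[[t + 1]] <- H
  }
  R1 <- H %*% t(params$readout$Wr1)
  ZR <- act(R1)
  atom_energy <- as.numeric(ZR %*% params$readout$wr2)
  y <- as.numeric(rowsum_full(matrix(atom_energy, ncol = 1), batch$mol, batch$n_mol))
  list(
    Hs = Hs, caches = caches, R1 = R1, ZR = ZR,
    atom_energy = atom_energy, y = y, batch = batch
  )
}

#' Evaluate the model on one conformer, caching the full trace
#'
#' @param params A [init_params()] result (or trained parameters).
#' @param config The matching [model_config()].
#' @param conf A conformer.
#' @return A list of class `forward_trace` with the predicted energy `y`
#'   (kcal/mol), per-atom contributions `atom_energy` (summing exactly to
#'   `y`), and every intermediate activation required by relevance
#'   propagation.
#' @export
forward_energy <- function(params, config, conf) {
  batch <- build_batch(conf, config)
  out <- forward_batch(params, config, batch)
  structure(
    list(
      y = out$y[1], atom_energy = out$atom_energy,
      Hs = out$Hs, caches = out$caches, R1 = out$R1, ZR = out$ZR,
      batch = batch, config = config, params = params,
      conformer = conf
    ),
    class = "forward_trace"
  )
}

#' Predict energies for a set of conformers
#'
#' @param object A fitted model (class `ff_model`) from [train_model()], or
#'   a list with `params` and `config`.
#' @param conformers A conformer-set tibble or single conformer.
#' @param ... Unused.
#' @return A tibble with columns `id` and `energy` (kcal/mol).
#' @export
predict.ff_model <- function(object, conformers, ...) {
  conformers <- as_conformer_set(conformers)
  batch <- build_batch(conformers, object$config)
  out <- forward_batch(object$params, object$config, batch)
  tibble::tibble(id = conformers$id, energy = out$y)
}
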