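#' Configure the relevance propagation rule
#'
#' The epsilon rule divides each contribution by the sign-matched
#' relatively stabilized total, `z / (sum(z) * (1 + eps))` — the stabilizer
#' is dimensionless, so each division attenuates the redistributed
#' relevance by exactly `1/(1+eps)` whatever the activation scale. The
#' gamma rule boosts positive contributions by a factor `1 + gamma` before
#' normalizing.
#' Distance-dependent filter values are treated as constants (edge gates)
#' during propagation: relevance flows through atom features only.
#'
#' @param rule `"epsilon"` or `"gamma"`.
#' @param epsilon Stabilizer (dimensionless, >= 0).
#' @param gamma Positive-contribution boost (dimensionless, >= 0).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(rule = c("epsilon", "gamma"),
                        epsilon = 1e-6, gamma = 0.25) {
  rule <- match.arg(rule)
  if (epsilon < 0) stop("`epsilon` must be >= 0")
  if (gamma < 0) stop("`gamma` must be >= 0")
  structure(
    list(rule = rule, epsilon = epsilon, gamma = gamma,
         filter_as_constant = TRUE),
    class = "rule_config"
  )
}

# Count walks (edges-or-self-transitions, length depth+1) via matrix powers
# of the adjacency-with-self-loops matrix.
count_walks <- function(graph, depth) {
  n <- graph$n
  A <- diag(1, n)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$src, graph$edges$dst)] <- 1
  }
  v <- rep(1, n)
  for (t in seq_len(depth)) v <- A %*% v
  sum(v)
}

#' Enumerate all walks on a neighbor graph
#'
#' A walk is an ordered sequence of `depth + 1` atom indices in which each
#' consecutive pair is either an edge of the graph or a self transition
#' (repeated index). The walk count grows exponentially with depth, so
#' enumeration refuses to materialize more than `cap` walks.
#'
#' @param graph A [build_neighbor_graph()] result.
#' @param depth Network depth T (>= 1); walks have `depth + 1` indices.
#' @param cap Maximum number of walks to enumerate.
#' @return An integer matrix, one row per walk in lexicographic order,
#'   `depth + 1` columns of 1-based atom indices. The count is attached as
#'   attribute `n_walks`.
#' @export
enumerate_walks <- function(graph, depth, cap = 1e7) {
  if (depth < 1) stop("`depth` must be >= 1")
  total <- count_walks(graph, depth)
  if (total > cap) {
    stop(
      "walk enumeration would produce ", format(total, big.mark = ","),
      " walks (> cap ", format(cap, big.mark = ","),
      "); walk counts grow exponentially with network depth"
    )
  }
  succ <- lapply(seq_len(graph$n), function(k) {
    sort(unique(c(k, graph$edges$dst[graph$edges$src == k])))
  })
  walks <- matrix(seq_len(graph$n), ncol = 1)
  for (step in seq_len(depth)) {
    reps <- lengths(succ)[walks[, ncol(walks)]]
    nxt <- unlist(succ[walks[, ncol(walks)]], use.names = FALSE)
    walks <- cbind(
      walks[rep(seq_len(nrow(walks)), reps), , drop = FALSE],
      nxt
    )
  }
  dimnames(walks) <- NULL
  ord <- do.call(order, lapply(seq_len(ncol(walks)), function(j) walks[, j]))
  walks <- walks[ord, , drop = FALSE]
  attr(walks, "n_walks") <- nrow(walks)
  walks
}

# Sign-matched relative stabilizer: the epsilon term carries the sign and
# magnitude of the denominator itself, so every division shrinks the
# redistributed relevance by exactly 1/(1+eps) whatever the activation
# scale. An exactly zero denominator cannot be stabilized; those shares are
# dropped and counted.
stab <- function(d, eps) {
  d * (1 + eps)
}

# Redistribute upper relevance R_up over lower neurons given the
# contribution matrix Z (n_lower x n_upper). Applies the configured rule.
# `state` is an environment counting relevance dropped at exact-zero
# stabilized denominators.
lrp_redistribute <- function(Z, R_up, rule, state = NULL) {
  if (rule$rule == "gamma") {
    Z <- Z + rule$gamma * pmax(Z, 0)
  }
  den <- colSums(Z)
  sden <- stab(den, rule$epsilon)
  dead <- sden == 0
  if (any(dead)) {
    if (!is.null(state)) state$dropped <- state$dropped + sum(abs(R_up[dead]))
    sden[dead] <- 1
    R_up <- R_up * ifelse(dead, 0, 1)
  }
  as.numeric(Z %*% (R_up / sden))
}

# Relevance through a linear map y = W x (no bias): Z[a, i] = W[i, a] x[a].
lrp_linear <- function(W, x, R_up, rule, state = NULL) {
  lrp_redistribute(t(W) * x, R_up, rule, state)
}

# Relevance at the top-layer features of atom k, starting from that atom's
# energy contribution and propagating through the readout MLP.
readout_backward <- function(trace, k, rule, state = NULL) {
  p <- trace$params
  zr <- trace$ZR[k, ]
  e_k <- trace$atom_energy[k]
  r_zr <- lrp_redistribute(
    matrix(p$readout$wr2 * zr, ncol = 1), e_k, rule, state
  )
  # nonlinearity: pass-through
  ht <- trace$Hs[[trace$config$depth + 1]][k, ]
  lrp_linear(p$readout$Wr1, ht, r_zr, rule, state)
}

#' One relevance-propagation step through a message-passing layer
#'
#' Implements the index-retaining layer rule: relevance sitting on the
#' features of atom `node` after layer `layer` is pushed back through the
#' combine MLP, then split — without pooling — across the atoms that
#' contributed (the atom itself via its own state, each neighbor via its
#' gated message), and finally through the message transform onto each
#' contributor's features.
#'
#' @param trace A [forward_energy()] trace.
#' @param layer Layer index (1-based, in 1..depth).
#' @param node Atom index whose post-layer relevance is being propagated.
#' @param relevance Numeric vector of per-neuron relevance on the atom's
#'   features after `layer`.
#' @param rule A [rule_config()].
#' @return A named list, one entry per contributing atom (names are atom
#'   indices; `node` itself is the self transition), each a per-neuron
#'   relevance vector on that atom's features before the layer.
#' @export
lrp_layer_backward <- function(trace, layer, node, relevance,
                               rule = rule_config()) {
  layer_split(trace, layer, node, relevance, rule, NULL)
}

layer_split <- function(trace, layer, node, relevance, rule, state) {
  if (!all(is.finite(relevance))) stop("non-finite upper relevance")
  p <- trace$params
  W <- p$layers[[layer]]
  cache <- trace$caches[[layer]]
  Hp <- trace$Hs[[layer]]
  r_z1 <- lrp_linear(W$Wc2, cache$Z1[node, ], relevance, rule, state)
  r_u <- lrp_linear(W$Wc1, cache$U[node, ], r_z1, rule, state)
  in_edges <- which(trace$batch$dst == node)
  srcs <- trace$batch$src[in_edges]
  # contribution rows: self state first, then one gated message per in-edge
  Zs <- rbind(
    Hp[node, ],
    cache$filt$G[in_edges, , drop = FALSE] *
      cache$MSG[srcs, , drop = FALSE]
  )
  Zr <- if (rule$rule == "gamma") Zs + rule$gamma * pmax(Zs, 0) else Zs
  den <- colSums(Zr)
  sden <- stab(den, rule$epsilon)
  dead <- sden == 0
  if (any(dead)) {
    if (!is.null(state)) state$dropped <- state$dropped + sum(abs(r_u[dead]))
    sden[dead] <- 1
    r_u <- r_u * ifelse(dead, 0, 1)
  }
  shares <- Zr * rep(r_u / sden, each = nrow(Zr))
  out <- list()
  out[[as.character(node)]] <- shares[1, ]
  for (e in seq_along(in_edges)) {
    j <- srcs[e]
    Wm_scaled <- cache$filt$G[in_edges[e], ] * W$Wm
    r_hj <- lrp_linear(Wm_scaled, Hp[j, ], shares[e + 1, ], rule, state)
    key <- as.character(j)
    out[[key]] <- if (is.null(out[[key]])) r_hj else out[[key]] + r_hj
  }
  out
}

#' GNN-LRP walk relevances for one conformer
#'
#' Enumerates all walks of the cutoff graph and assigns each a scalar
#' relevance by masked relevance propagation: starting from every atom's
#' energy contribution, relevance is pushed down layer by layer while
#' retaining the atom index taken at each step. The relevances decompose
#' the predicted energy: their sum equals the prediction `y` up to the
#' stabilizer (see [conservation_residual()]). Propagation is fully
#' deterministic.
#'
#' @param object An `ff_model`, or a list with `params` and `config`.
#' @param conf A conformer.
#' @param rule A [rule_config()].
#' @param cap Walk-enumeration cap, see [enumerate_walks()].
#' @return A tibble of class `walk_relevance_map` with columns `walk`
#'   (dash-separated 1-based atom indices), `atoms` (list of integer
#'   vectors, length `depth + 1`) and `relevance`, one row per walk.
#'   Attributes: `y`, `depth`, `rule`, `conformer`, `dropped` (relevance
#'   lost at exact-zero stabilized denominators).
#' @export
walk_relevances <- function(object, conf, rule = rule_config(), cap = 1e7) {
  params <- object$params
  config <- object$config
  trace <- forward_energy(params, config, conf)
  graph <- build_neighbor_graph(conf, config$cutoff)
  walks <- enumerate_walks(graph, config$depth, cap = cap)
  state <- new.env(parent = emptyenv())
  state$dropped <- 0
  acc <- new.env(parent = emptyenv())
  acc$keys <- character(nrow(walks))
  acc$vals <- numeric(nrow(walks))
  acc$i <- 0L
  recurse <- function(t, node, R, suffix) {
    if (t == 0) {
      acc$i <- acc$i + 1L
      acc$keys[acc$i] <- paste(rev(suffix), collapse = "-")
      acc$vals[acc$i] <- sum(R)
      return(invisible(NULL))
    }
    splits <- layer_split(trace, t, node, R, rule, state)
    for (key in names(splits)) {
      recurse(t - 1L, as.integer(key), splits[[key]], c(suffix, as.integer(key)))
    }
  }
  for (k in seq_len(graph$n)) {
    r_top <- readout_backward(trace, k, rule, state)
    recurse(config$depth, k, r_top, k)
  }
  walk_keys <- apply(walks, 1, paste, collapse = "-")
  rel <- acc$vals[match(walk_keys, acc$keys)]
  if (anyNA(rel)) stop("internal error: enumerated walk missing from propagation")
  out <- tibble::tibble(
    walk = walk_keys,
    atoms = lapply(seq_len(nrow(walks)), function(i) as.integer(walks[i, ])),
    relevance = rel
  )
  class(out) <- c("walk_relevance_map", class(out))
  attr(out, "y") <- trace$y
  attr(out, "depth") <- config$depth
  attr(out, "rule") <- rule
  attr(out, "conformer") <- conf
  attr(out, "dropped") <- state$dropped
  out
}

#' Conservation residual of a walk-relevance map
#'
#' The walk decomposition satisfies the conservation axiom: the relevances
#' sum to the model output. This returns `|sum(R_W) - y| / |y|`; when the
#' prediction is exactly zero the absolute residual is returned instead,
#' flagged by attribute `absolute` and a warning.
#'
#' @param map A [walk_relevances()] result.
#' @return The (relative) residual, a non-negative number.
#' @export
conservation_residual <- function(map) {
  y <- attr(map, "y")
  res <- abs(sum(map$relevance) - y)
  if (y == 0) {
    warning("prediction is exactly zero; returning absolute residual")
    attr(res, "absolute") <- TRUE
    return(res)
  }
  res / abs(y)
}

#' Node-level input relevances (pooled propagation)
#'
#' Propagates relevance to the input layer with the pooling over source
#' atoms kept in place, giving one relevance per atom. Because each walk
#' split is linear in the incoming relevance, these equal the walk
#' relevances marginalized over all indices but the first.
#'
#' @param object An `ff_model` or list with `params` and `config`.
#' @param conf A conformer.
#' @param rule A [rule_config()].
#' @return A tibble with columns `atom`, `element`, `relevance`.
#' @export
atom_relevances <- function(object, conf, rule = rule_config()) {
  trace <- forward_energy(object$params, object$config, conf)
  n <- nrow(conf)
  depth <- object$config$depth
  R <- matrix(0, n, object$config$embedding)
  for (k in seq_len(n)) {
    R[k, ] <- readout_backward(trace, k, rule)
  }
  for (t in rev(seq_len(depth))) {
    Rn <- matrix(0, n, object$config$embedding)
    for (k in seq_len(n)) {
      splits <- layer_split(trace, t, k, R[k, ], rule, NULL)
      for (key in names(splits)) {
        j <- as.integer(key)
        Rn[j, ] <- Rn[j, ] + splits[[key]]
      }
    }
    R <- Rn
  }
  tibble::tibble(
    atom = seq_len(n), element = conf$element, relevance = rowSums(R)
  )
}

#' Algebraic walk-relevance oracle for linear models
#'
#' For a model with identity activations the prediction is a sum of
#' per-walk weight products, which this computes by explicit matrix
#' algebra — independently of the propagation engine. Intended for tests.
#'
#' @param object An `ff_model`-like list with `params` and `config`; the
#'   config's activation must be `"linear"`.
#' @param conf A conformer.
#' @param cap Walk-enumeration cap.
#' @return A `walk_relevance_map` tibble (same shape as
#'   [walk_relevances()]).
#' @export
linear_oracle_relevances <- function(object, conf, cap = 1e7) {
  params <- object$params
  config <- object$config
  if (config$activation != "linear") {
    stop("nonlinear layer present: the algebraic oracle requires activation = \"linear\"")
  }
  trace <- forward_energy(params, config, conf)
  graph <- build_neighbor_graph(conf, config$cutoff)
  walks <- enumerate_walks(graph, config$depth, cap = cap)
  batch <- trace$batch
  readout_row <- params$readout$wr2 %*% params$readout$Wr1
  layer_mats <- lapply(seq_len(config$depth), function(t) {
    W <- params$layers[[t]]
    C <- W$Wc2 %*% W$Wc1
    G <- trace$caches[[t]]$filt$G
    edge_mats <- lapply(seq_len(nrow(G)), function(e) C %*% (G[e, ] * W$Wm))
    names(edge_mats) <- paste(batch$src, batch$dst)
    list(self = C, edges = edge_mats)
  })
  emb <- params$emb[batch$zid, , drop = FALSE]
  rel <- vapply(seq_len(nrow(walks)), function(i) {
    w <- walks[i, ]
    v <- emb[w[1], ]
    for (t in seq_len(config$depth)) {
      M <- if (w[t] == w[t + 1]) {
        layer_mats[[t]]$self
      } else {
        layer_mats[[t]]$edges[[paste(w[t], w[t + 1])]]
      }
      v <- as.numeric(M %*% v)
    }
    as.numeric(readout_row %*% v)
  }, numeric(1))
  out <- tibble::tibble(
    walk = apply(walks, 1, paste, collapse = "-"),
    atoms = lapply(seq_len(nrow(walks)), function(i) as.integer(walks[i, ])),
    relevance = rel
  )
  class(out) <- c("walk_relevance_map", class(out))
  attr(out, "y") <- trace$y
  attr(out, "depth") <- config$depth
  attr(out, "rule") <- list(rule = "algebraic-oracle")
  attr(out, "conformer") <- conf
  attr(out, "dropped") <- 0
  out
}

#' Write / read a walk-relevance map
#'
#' Tabular text format: `#`-prefixed header lines carrying the prediction
#' `y`, depth, rule and stabilizer, then CSV rows `walk,relevance` with the
#' relevance at full double precision.
#'
#' @param map A `walk_relevance_map`.
#' @param path File path.
#' @return `path` invisibly; `read_walk_relevances()` returns the map (the
#'   conformer itself is not stored, only the relevances and header).
#' @export
write_walk_relevances <- function(map, path) {
  rule <- attr(map, "rule")
  header <- c(
    sprintf("# y=%.17g", attr(map, "y")),
    sprintf("# depth=%d", attr(map, "depth")),
    sprintf("# rule=%s", rule$rule),
    sprintf("# epsilon=%.17g", rule$epsilon %||% 0),
    "walk,relevance"
  )
  rows <- sprintf("%s,%.17g", map$walk, map$relevance)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_walk_relevances
#' @export
read_walk_relevances <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_h <- function(key) {
    m <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    if (length(m) == 0) return(NA)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  tab <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    walk = as.character(tab$walk),
    atoms = lapply(strsplit(as.character(tab$walk), "-"), as.integer),
    relevance = as.numeric(tab$relevance)
  )
  class(out) <- c("walk_relevance_map", class(out))
  attr(out, "y") <- as.numeric(get_h("y"))
  attr(out, "depth") <- as.integer(get_h("depth"))
  attr(out, "rule") <- list(
    rule = get_h("rule"), epsilon = as.numeric(get_h("epsilon"))
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
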