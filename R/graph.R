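#' Build the cutoff neighbor graph of a conformer
#'
#' A directed edge (j -> k) is present iff `0 < r_jk < cutoff` (strict at
#' both ends); the edge set is symmetric as undirected pairs. Self edges are
#' never stored — the combine step of the network handles each atom's own
#' state, and relevance propagation treats consecutive repeated walk indices
#' as that self transition.
#'
#' @param conf A conformer.
#' @param cutoff Cutoff distance c (Angstrom), > 0.
#' @return A list of class `neighbor_graph` with `n` (atom count), `edges`
#'   (tibble `src`, `dst`, `distance`) and `neighbors` (list of integer
#'   vectors, `neighbors[[k]]` = sources of edges into k).
#' @export
build_neighbor_graph <- function(conf, cutoff) {
  if (cutoff <= 0) stop("`cutoff` must be > 0")
  n <- nrow(conf)
  pos <- conformer_positions(conf)
  if (n > 1) {
    dm <- as.matrix(stats::dist(pos))
    if (any(dm[upper.tri(dm)] == 0)) {
      stop("coincident atoms: zero interatomic distance")
    }
    idx <- which(dm > 0 & dm < cutoff, arr.ind = TRUE)
    edges <- tibble::tibble(
      src = as.integer(idx[, 1]),
      dst = as.integer(idx[, 2]),
      distance = dm[idx]
    )
  } else {
    edges <- tibble::tibble(
      src = integer(), dst = integer(), distance = numeric()
    )
  }
  neighbors <- lapply(seq_len(n), function(k) edges$src[edges$dst == k])
  structure(
    list(n = n, edges = edges, neighbors = neighbors, cutoff = cutoff),
    class = "neighbor_graph"
  )
}

#' Gaussian radial-basis expansion of a distance
#'
#' Centers sit at `(k - 1) * cutoff / n_rbf`, `k = 1..n_rbf`, so the center
#' spacing is `cutoff / n_rbf` — models whose cutoff and basis count keep
#' that ratio fixed share an identical spacing along the distance axis. The
#' Gaussian width equals the spacing.
#'
#' @param r Distances (Angstrom), vectorized.
#' @param cutoff Cutoff distance (Angstrom).
#' @param n_rbf Number of basis functions (>= 2).
#' @return A `length(r) x n_rbf` matrix of basis activations.
#' @export
rbf_expand <- function(r, cutoff, n_rbf) {
  if (n_rbf < 2) stop("`n_rbf` must be >= 2")
  if (any(r < 0)) stop("distances must be non-negative")
  spacing <- cutoff / n_rbf
  centers <- (seq_len(n_rbf) - 1) * spacing
  exp(-(outer(r, centers, "-"))^2 / (2 * spacing^2))
}

#' Cosine cutoff weight
#'
#' Smooth monotone damping `0.5 (1 + cos(pi r / c))` on `[0, c]`, defined as
#' 0 beyond the cutoff so messages vanish continuously at `r = c`.
#'
#' @param r Distances (Angstrom), vectorized.
#' @param c Cutoff distance (Angstrom).
#' @return Weights in `[0, 1]`.
#' @export
cosine_cutoff <- function(r, c) {
  ifelse(r >= c, 0, 0.5 * (1 + cos(pi * r / c)))
}
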