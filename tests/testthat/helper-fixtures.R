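# Shared fixtures: tiny configurations, hand-built models, and independent
# brute-force oracles used across the suite.

tiny_config <- function(depth = 2, cutoff = 5, embedding = 8,
                        elements = c("C", "O", "H"), ...) {
  model_config(
    depth = depth, cutoff = cutoff, embedding = embedding,
    elements = elements, ...
  )
}

random_cluster <- function(n_atoms = 6, seed = 1, n_samples = 1,
                           elements = c("C", "O", "H")) {
  generate_conformers(generator_spec(
    "random_cluster",
    n_atoms = n_atoms, n_samples = n_samples, seed = seed,
    elements = elements
  ))
}

# One-layer linear pair-sum network: the message j -> k carries half the
# Morse pair energy, embeddings are 1, and every learned map is the
# identity, so y = N + sum over pairs of u(r) and the walk (j, k) carries
# exactly u(r_jk) / 2.
pair_sum_model <- function(pp = pair_potential_params(), cutoff = 100) {
  config <- model_config(
    depth = 1, cutoff = cutoff, n_rbf = 2, embedding = 1,
    elements = c("C", "O", "H"), activation = "linear",
    filter_hidden = 1, combine_hidden = 1, readout_hidden = 1,
    cosine_cutoff = FALSE
  )
  params <- init_params(config, 1)
  params$emb <- matrix(1, 3, 1)
  params$layers[[1]]$Wm <- matrix(1)
  params$layers[[1]]$Wc1 <- matrix(1)
  params$layers[[1]]$Wc2 <- matrix(1)
  params$readout$Wr1 <- matrix(1)
  params$readout$wr2 <- 1
  params$filter_override <- function(r) {
    matrix(morse_u(r, pp) / 2, ncol = 1)
  }
  list(params = params, config = config)
}

morse_u <- function(r, pp = pair_potential_params()) {
  pp$well_depth * (1 - exp(-pp$width * (r - pp$equilibrium_distance)))^2 -
    pp$well_depth
}

# Hand-built walk relevance map (for metric arithmetic tests).
fake_map <- function(walks, relevances, conf, y = sum(relevances)) {
  out <- tibble::tibble(
    walk = vapply(walks, paste, character(1), collapse = "-"),
    atoms = lapply(walks, as.integer),
    relevance = relevances
  )
  class(out) <- c("walk_relevance_map", class(out))
  attr(out, "y") <- y
  attr(out, "depth") <- length(walks[[1]]) - 1L
  attr(out, "rule") <- rule_config()
  attr(out, "conformer") <- conf
  out
}

# Independent brute-force minimum enclosing sphere: smallest sphere among
# all 2-, 3- and 4-point candidate spheres that contains every point.
brute_force_sphere <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  contains_all <- function(ctr, rad) {
    all(sqrt(colSums((t(pts) - ctr)^2)) <= rad + 1e-9)
  }
  best <- Inf
  if (n == 1) return(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ctr <- (pts[i, ] + pts[j, ]) / 2
      rad <- sqrt(sum((pts[i, ] - ctr)^2))
      if (rad < best && contains_all(ctr, rad)) best <- rad
    }
  }
  if (n >= 3) {
    for (trip in utils::combn(n, 3, simplify = FALSE)) {
      p1 <- pts[trip[1], ]
      D <- rbind(pts[trip[2], ] - p1, pts[trip[3], ] - p1)
      G <- D %*% t(D)
      if (abs(det(G)) < 1e-12) next
      ab <- solve(G, rowSums(D^2) / 2)
      ctr <- p1 + as.numeric(t(D) %*% ab)
      rad <- sqrt(sum((p1 - ctr)^2))
      if (rad < best && contains_all(ctr, rad)) best <- rad
    }
  }
  if (n >= 4) {
    for (quad in utils::combn(n, 4, simplify = FALSE)) {
      p1 <- pts[quad[1], ]
      D <- sweep(pts[quad[-1], ], 2, p1)
      if (abs(det(D)) < 1e-12) next
      ctr <- p1 + solve(D, rowSums(D^2) / 2)
      rad <- sqrt(sum((p1 - ctr)^2))
      if (rad < best && contains_all(ctr, rad)) best <- rad
    }
  }
  2 * best
}
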