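test_that("walk enumeration matches direct counting", {
  # complete graph on 3 atoms, depth 2: 3^3 walks
  tri <- conformer(c("C", "C", "C"), rbind(
    c(0, 0, 0), c(1, 0, 0), c(0.5, 0.9, 0)
  ))
  g <- build_neighbor_graph(tri, 5)
  w <- enumerate_walks(g, 2)
  expect_equal(nrow(w), 27)
  # path graph 0-1-2 with self transitions, depth 1: 7 walks
  chain <- conformer(c("C", "C", "C"), rbind(
    c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)
  ))
  gp <- build_neighbor_graph(chain, 1.5)
  wp <- enumerate_walks(gp, 1)
  expect_equal(
    apply(wp, 1, paste, collapse = "-"),
    c("1-1", "1-2", "2-1", "2-2", "2-3", "3-2", "3-3")
  )
  # single atom: one all-self walk for any depth
  lone <- conformer("C", matrix(c(0, 0, 0), 1))
  gl <- build_neighbor_graph(lone, 3)
  expect_equal(nrow(enumerate_walks(gl, 4)), 1)
})

test_that("walk counts equal adjacency-matrix-power counts on random graphs", {
  for (s in 1:5) {
    cf <- random_cluster(n_atoms = 5 + s, seed = 40 + s)$conformer[[1]]
    g <- build_neighbor_graph(cf, 4)
    A <- diag(1, g$n)
    A[cbind(g$edges$src, g$edges$dst)] <- 1
    depth <- 2
    expect_equal(nrow(enumerate_walks(g, depth)), sum(A %*% A %*% rep(1, g$n)))
  }
})

test_that("the enumeration cap aborts with an explicit error", {
  cf <- random_cluster(8, seed = 1)$conformer[[1]]
  g <- build_neighbor_graph(cf, 10)
  expect_error(enumerate_walks(g, 3, cap = 100), "exponentially")
})

test_that("relevance conservation holds and tightens as epsilon shrinks", {
  residuals <- vapply(1:6, function(s) {
    set.seed(s)
    cf <- random_cluster(sample(6:9, 1), seed = 50 + s)$conformer[[1]]
    par <- init_params(tiny_config(), 200 + s)
    map <- walk_relevances(list(params = par, config = tiny_config()), cf)
    conservation_residual(map)
  }, numeric(1))
  expect_true(all(residuals <= 1e-4))
  # residual grows monotonically with epsilon on a fixed model
  cf <- random_cluster(6, seed = 3)$conformer[[1]]
  par <- init_params(tiny_config(), 5)
  sweep_res <- vapply(c(0, 1e-8, 1e-6, 1e-4, 1e-2, 1), function(eps) {
    map <- walk_relevances(
      list(params = par, config = tiny_config()), cf,
      rule = rule_config(epsilon = eps)
    )
    conservation_residual(map)
  }, numeric(1))
  expect_true(all(diff(sweep_res) > 0))
  expect_equal(sweep_res[1], 0, tolerance = 1e-12)
})

test_that("trivial conservation cases hold by construction", {
  cf <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  map <- fake_map(list(c(1, 2)), 0.7, cf, y = 0.7)
  expect_equal(conservation_residual(map), 0)
})

test_that("walk relevances equal the algebraic oracle on linear models", {
  for (s in 1:3) {
    cfg <- tiny_config(embedding = 4, activation = "linear")
    par <- init_params(cfg, 60 + s)
    cf <- random_cluster(5, seed = 70 + s)$conformer[[1]]
    engine <- walk_relevances(
      list(params = par, config = cfg), cf,
      rule = rule_config(epsilon = 0)
    )
    oracle <- linear_oracle_relevances(list(params = par, config = cfg), cf)
    expect_equal(engine$walk, oracle$walk)
    expect_lt(max(abs(engine$relevance - oracle$relevance)), 1e-10)
  }
  # oracle refuses nonlinear models; doubling readout doubles relevances
  cfg_nl <- tiny_config(embedding = 4)
  expect_error(
    linear_oracle_relevances(
      list(params = init_params(cfg_nl, 1), config = cfg_nl),
      random_cluster(4, seed = 2)$conformer[[1]]
    ),
    "linear"
  )
  cfg <- tiny_config(embedding = 4, activation = "linear")
  par <- init_params(cfg, 9)
  cf <- random_cluster(4, seed = 9)$conformer[[1]]
  par2 <- par
  par2$readout$wr2 <- 2 * par$readout$wr2
  o1 <- linear_oracle_relevances(list(params = par, config = cfg), cf)
  o2 <- linear_oracle_relevances(list(params = par2, config = cfg), cf)
  expect_equal(o2$relevance, 2 * o1$relevance, tolerance = 1e-12)
})

test_that("a hand-built pair-sum network attributes each pair walk its half-energy", {
  pp <- pair_potential_params()
  model <- pair_sum_model(pp)
  cf <- conformer(c("C", "O", "H"), rbind(
    c(0, 0, 0), c(1.8, 0, 0), c(0.4, 2.2, 0)
  ))
  map <- walk_relevances(model, cf, rule = rule_config(epsilon = 0))
  oracle <- linear_oracle_relevances(model, cf)
  expect_lt(max(abs(map$relevance - oracle$relevance)), 1e-10)
  pd <- pair_distances(cf)
  for (r in seq_len(nrow(pd))) {
    key <- paste(pd$i[r], pd$j[r], sep = "-")
    expect_equal(
      map$relevance[map$walk == key],
      morse_u(pd$distance[r], pp) / 2,
      tolerance = 1e-10
    )
  }
  # self walks carry the embedding contribution of 1
  expect_equal(map$relevance[map$walk == "1-1"], 1, tolerance = 1e-10)
  expect_equal(sum(map$relevance), attr(map, "y"), tolerance = 1e-10)
})

test_that("zero readout weights give a zero prediction and zero relevances", {
  cfg <- tiny_config()
  par <- init_params(cfg, 8)
  par$readout$wr2 <- par$readout$wr2 * 0
  cf <- random_cluster(5, seed = 21)$conformer[[1]]
  map <- walk_relevances(list(params = par, config = cfg), cf)
  expect_equal(attr(map, "y"), 0)
  expect_true(all(map$relevance == 0))
  expect_warning(res <- conservation_residual(map), "absolute")
  expect_equal(as.numeric(res), 0)
})

test_that("summing walk relevances marginalizes to node-level relevance", {
  cfg <- tiny_config()
  par <- init_params(cfg, 33)
  model <- list(params = par, config = cfg)
  cf <- random_cluster(6, seed = 27)$conformer[[1]]
  map <- walk_relevances(model, cf, rule = rule_config(epsilon = 0))
  # marginal over all but the first index vs pooled propagation
  first <- vapply(map$atoms, `[[`, integer(1), 1L)
  marg <- vapply(
    seq_len(nrow(cf)),
    function(j) sum(map$relevance[first == j]), numeric(1)
  )
  pooled <- atom_relevances(model, cf, rule = rule_config(epsilon = 0))
  expect_equal(marg, pooled$relevance, tolerance = 1e-10)
  # marginal over all but the last index vs per-atom energies
  last <- vapply(map$atoms, function(a) a[[length(a)]], integer(1))
  tr <- forward_energy(par, cfg, cf)
  top_marg <- vapply(
    seq_len(nrow(cf)),
    function(k) sum(map$relevance[last == k]), numeric(1)
  )
  expect_equal(top_marg, tr$atom_energy, tolerance = 1e-10)
})

test_that("relabeling atoms permutes walks but not the relevance multiset", {
  cfg <- tiny_config()
  par <- init_params(cfg, 12)
  cf <- random_cluster(5, seed = 33)$conformer[[1]]
  perm <- c(3, 5, 1, 2, 4)
  cfp <- conformer(cf$element[perm], conformer_positions(cf)[perm, ])
  m1 <- walk_relevances(list(params = par, config = cfg), cf)
  m2 <- walk_relevances(list(params = par, config = cfg), cfp)
  expect_equal(sort(m1$relevance), sort(m2$relevance), tolerance = 1e-9)
  expect_equal(attr(m1, "y"), attr(m2, "y"), tolerance = 1e-12)
})

test_that("propagation is deterministic and maps serialize faithfully", {
  cfg <- tiny_config()
  par <- init_params(cfg, 44)
  cf <- random_cluster(5, seed = 44)$conformer[[1]]
  m1 <- walk_relevances(list(params = par, config = cfg), cf)
  m2 <- walk_relevances(list(params = par, config = cfg), cf)
  expect_identical(m1$relevance, m2$relevance)
  path <- withr::local_tempfile(fileext = ".csv")
  write_walk_relevances(m1, path)
  back <- read_walk_relevances(path)
  expect_equal(back$walk, m1$walk)
  expect_identical(back$relevance, m1$relevance)
  expect_equal(attr(back, "y"), attr(m1, "y"))
})

test_that("single-input layers pass relevance through unchanged", {
  # one upper neuron fed by one lower neuron: identity transport
  r <- walklrp:::lrp_linear(matrix(1), 2.5, 0.8, rule_config(epsilon = 0))
  expect_equal(r, 0.8)
  # epsilon = 0, no zero denominators: exact layer-wise conservation
  W <- matrix(rnorm(12), 3, 4)
  x <- rnorm(4)
  R_up <- rnorm(3)
  r_low <- walklrp:::lrp_linear(W, x, R_up, rule_config(epsilon = 0))
  expect_equal(sum(r_low), sum(R_up), tolerance = 1e-12)
})
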