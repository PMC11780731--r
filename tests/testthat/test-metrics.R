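test_that("walk importance is a normalized probability distribution", {
  cf <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  one <- fake_map(list(c(1, 2)), -0.4, cf)
  d1 <- walk_importance(one)
  expect_equal(d1$p, 1)
  four <- fake_map(
    list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
    c(0.3, -0.3, 0.3, -0.3), cf
  )
  d4 <- walk_importance(four)
  expect_equal(d4$p, rep(0.25, 4))
  # engine maps normalize within 1e-12
  cfg <- tiny_config()
  par <- init_params(cfg, 77)
  map <- walk_relevances(
    list(params = par, config = cfg),
    random_cluster(6, seed = 77)$conformer[[1]]
  )
  d <- walk_importance(map)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_true(all(d$p >= 0 & d$p <= 1))
  zero <- fake_map(list(c(1, 2)), 0, cf)
  expect_error(walk_importance(zero), "zero")
})

test_that("walk extent equals the enclosing-sphere diameter on known shapes", {
  # two atoms: their distance
  pos2 <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(walk_extent(c(1, 2), pos2), 5)
  # repeated visits of one atom: zero
  expect_equal(walk_extent(c(1, 1, 1), pos2), 0)
  # equilateral triangle of side 1: circumdiameter 2/sqrt(3)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(walk_extent(1:3, tri), 2 / sqrt(3), tolerance = 1e-12)
  # unit square (coplanar quadruple): circumdiameter sqrt(2)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(walk_extent(1:4, sq), sqrt(2), tolerance = 1e-12)
})

test_that("the enclosing sphere agrees with brute force on random point sets", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    pts <- matrix(rnorm(3 * n, sd = 2), n, 3)
    expect_equal(
      walk_extent(seq_len(n), pts),
      brute_force_sphere(pts),
      tolerance = 1e-9
    )
  }
})

test_that("threshold range follows the importance cutoff", {
  cf <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
  dist <- tibble::tibble(p = c(0.9995, 0.0005), extent = c(1, 8))
  expect_equal(
    interaction_range(dist, "threshold", p_min = 0.001)$lambda, 1
  )
  expect_equal(
    interaction_range(dist, "threshold", p_min = 0.0001)$lambda, 8
  )
  expect_error(interaction_range(dist, "threshold", p_min = 0), "p_min")
  expect_warning(
    out <- interaction_range(dist, "threshold", p_min = 2), "returning 0"
  )
  expect_equal(out$lambda, 0)
})

test_that("the generalized expectation interpolates mean and maximum", {
  dist <- tibble::tibble(p = c(0.5, 0.5), extent = c(1, 3))
  expect_equal(interaction_range(dist, "power", a = 1)$lambda, 2)
  expect_equal(
    interaction_range(dist, "power", a = 4)$lambda,
    (0.5 * 1 + 0.5 * 81)^(1 / 4),
    tolerance = 1e-12
  )
  l64 <- interaction_range(dist, "power", a = 64)$lambda
  expect_lt(l64, 3)
  expect_gt(l64, 2.96)
  expect_error(interaction_range(dist, "power", a = 0), "`a`")
})

test_that("range statistics obey their monotonicity laws", {
  cfg <- tiny_config()
  par <- init_params(cfg, 55)
  map <- walk_relevances(
    list(params = par, config = cfg),
    random_cluster(7, seed = 55)$conformer[[1]]
  )
  d <- walk_importance(map)
  lam_t <- vapply(
    c(1e-5, 1e-4, 1e-3, 1e-2, 0.1),
    function(p) interaction_range(d, "threshold", p_min = p)$lambda,
    numeric(1)
  )
  expect_true(all(diff(lam_t) <= 0))
  lam_p <- vapply(
    c(0.5, 1, 2, 4, 8, 16, 32),
    function(a) interaction_range(d, "power", a = a)$lambda,
    numeric(1)
  )
  expect_true(all(diff(lam_p) >= -1e-12))
  expect_lte(lam_p[length(lam_p)], max(d$extent))
})

test_that("pair strengths follow their definitional arithmetic", {
  cf <- conformer(c("C", "C", "C"), rbind(
    c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)
  ))
  map <- fake_map(
    list(c(1, 1), c(1, 2), c(2, 2), c(1, 3)),
    c(0.2, 0.3, 0.1, 0.4), cf
  )
  incl <- pair_interaction_strength(map, "inclusive")
  get <- function(tab, i, j) tab$strength[tab$i == i & tab$j == j]
  expect_equal(get(incl, 1, 2), 0.3)
  expect_equal(get(incl, 1, 3), 0.4)
  expect_equal(get(incl, 2, 3), 0)
  # self strength: walks visiting only that atom
  self <- pair_interaction_strength(map, "inclusive", include_self = TRUE)
  expect_equal(get(self, 1, 1), 0.2)
  expect_equal(get(self, 2, 2), 0.1)
})

test_that("inclusive strength dominates exclusive for every pair", {
  cfg <- tiny_config()
  par <- init_params(cfg, 91)
  map <- walk_relevances(
    list(params = par, config = cfg),
    random_cluster(6, seed = 91)$conformer[[1]]
  )
  both <- pair_interaction_strength(map, "both")
  wide <- tidyr::pivot_wider(
    both,
    names_from = "mode", values_from = "strength"
  )
  expect_true(all(wide$inclusive >= wide$exclusive - 1e-12))
  # a two-atom molecule has no context: inclusive equals exclusive
  dimer <- conformer(c("C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  dmap <- walk_relevances(list(params = par, config = cfg), dimer)
  dboth <- pair_interaction_strength(dmap, "both")
  expect_equal(
    dboth$strength[dboth$mode == "inclusive"],
    dboth$strength[dboth$mode == "exclusive"]
  )
})

test_that("element-pair matrices are log-mean, split and symmetric", {
  tab <- tibble::tibble(
    element_i = c("H", "B"), element_j = c("H", "A"),
    distance = c(1.0, 2.5), strength = c(0.01, 1)
  )
  m <- element_pair_matrix(tab, split = 1.6)
  hh <- m[m$element_a == "H" & m$element_b == "H", ]
  expect_equal(hh$mean_log10_strength, -2)
  expect_equal(hh$class, "bonded")
  ab <- m[m$element_a == "A", ]
  expect_equal(ab$element_b, "B") # unordered pair canonicalized
  expect_equal(ab$class, "nonbonded")
  # swapping element labels leaves the canonical table unchanged
  tab_sw <- tab
  tab_sw$element_i <- c("H", "A")
  tab_sw$element_j <- c("H", "B")
  expect_equal(element_pair_matrix(tab_sw, split = 1.6), m)
})

test_that("many-bodyness measures orders of magnitude within a bin", {
  # all strengths equal: gamma 0
  eq <- tibble::tibble(distance = rep(2, 30), strength = rep(0.5, 30))
  p0 <- many_bodyness(eq, min_count = 10)
  expect_equal(p0$gamma, 0)
  expect_equal(gamma_bar(p0), 0)
  # max ten times the 10th percentile: gamma 1
  f10 <- tibble::tibble(distance = rep(2, 10), strength = c(rep(1, 9), 10))
  expect_equal(many_bodyness(f10, min_count = 10)$gamma, 1)
  # factor 100 between P10 and max: gamma 2
  f100 <- tibble::tibble(distance = rep(2, 10), strength = c(rep(0.3, 9), 30))
  expect_equal(many_bodyness(f100, min_count = 10)$gamma, 2)
})

test_that("gamma is scale-invariant and bin filtering is reported", {
  set.seed(5)
  tab <- tibble::tibble(
    distance = rep(c(2, 3), each = 25),
    strength = exp(rnorm(50))
  )
  p1 <- many_bodyness(tab, min_count = 20)
  tab2 <- tab
  tab2$strength <- tab2$strength * 37.5
  p2 <- many_bodyness(tab2, min_count = 20)
  expect_equal(p1$gamma, p2$gamma, tolerance = 1e-12)
  # under-filled bins are dropped from gamma_bar but reported
  tab3 <- dplyr::bind_rows(
    tab,
    tibble::tibble(distance = rep(9, 3), strength = c(1, 2, 3))
  )
  p3 <- many_bodyness(tab3, min_count = 20)
  expect_equal(attr(p3, "dropped_bins"), 1)
  expect_equal(gamma_bar(p3), gamma_bar(p1), tolerance = 1e-12)
  expect_error(
    many_bodyness(
      tibble::tibble(distance = 1, strength = 0),
      min_count = 1
    ),
    "positive"
  )
})

test_that("strict 2-body strengths give exactly zero many-bodyness", {
  pp <- pair_potential_params()
  reps <- generate_repeated_distance_set(30, seed = 19)
  tab <- dplyr::bind_rows(
    lapply(reps$conformer, analytic_pair_strengths, params = pp)
  )
  oo <- dplyr::filter(tab, element_i == "O", element_j == "O")
  prof <- many_bodyness(oo, bin_width = 0.5, min_count = 10)
  expect_equal(prof$gamma, rep(0, nrow(prof)), tolerance = 1e-14)
  expect_equal(gamma_bar(prof), 0, tolerance = 1e-14)
})

test_that("a 3-body term injects many-bodyness that grows with amplitude", {
  pp <- pair_potential_params()
  gbar <- vapply(c(1.5, 3, 6), function(A) {
    mean(vapply(1:3, function(s) {
      reps <- generate_repeated_distance_set(30, seed = s)
      tab <- dplyr::bind_rows(lapply(
        reps$conformer, analytic_pair_strengths,
        params = pp, three_body = three_body_params(amplitude = A)
      ))
      oo <- dplyr::filter(tab, element_i == "O", element_j == "O")
      gamma_bar(many_bodyness(oo, bin_width = 0.5, min_count = 10))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(gbar[1], 0)
  expect_true(all(diff(gbar) > 0))
})

test_that("decay fits recover generated exponential and power laws", {
  set.seed(11)
  r <- runif(400, 0.5, 8)
  s_exp <- 3 * exp(-1.7 * r) * (1 + rnorm(400, sd = 0.01))
  fe <- decay_fit(tibble::tibble(distance = r, strength = s_exp))
  expect_equal(fe$preferred, "exponential")
  expect_equal(fe$exponential$rate, 1.7, tolerance = 0.05)
  s_pow <- r^-6 * (1 + rnorm(400, sd = 0.01))
  fp <- decay_fit(tibble::tibble(distance = r, strength = s_pow))
  expect_equal(fp$preferred, "power_law")
  expect_equal(fp$power_law$exponent, -6, tolerance = 0.3 / 6)
  # constant strengths: degenerate flag, flat fits
  fc <- decay_fit(tibble::tibble(distance = r, strength = rep(2, 400)))
  expect_true(fc$degenerate)
  expect_equal(fc$exponential$rate, 0, tolerance = 1e-8)
  expect_error(
    decay_fit(tibble::tibble(distance = rep(1, 10), strength = 1:10)),
    "bins"
  )
  td <- tidy(fe)
  expect_equal(nrow(td), 2)
  expect_true(glance(fe)$preferred == "exponential")
})
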