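#' Specify a synthetic conformer generator
#'
#' Three topologies are supported: `chain` (atoms along a line at fixed
#' spacing, optionally jittered), `random_cluster` (atoms packed into a cubic
#' box by rejection sampling under a minimum-distance constraint) and
#' `dimer_scan` (a two-atom system whose separation is scanned linearly).
#' All randomness flows from the single integer `seed`.
#'
#' @param topology One of `"chain"`, `"random_cluster"`, `"dimer_scan"`.
#' @param n_atoms Number of atoms per conformer (forced to 2 for
#'   `dimer_scan`).
#' @param elements Element palette; atoms are drawn uniformly from it
#'   (chains use `elements` recycled in order so geometry stays controlled).
#' @param min_distance Smallest allowed interatomic distance (Angstrom).
#' @param spacing Chain spacing (Angstrom).
#' @param jitter Isotropic Gaussian displacement sd applied to chain atoms
#'   (Angstrom); 0 keeps the chain exact.
#' @param density Cluster packing density (atoms per cubic Angstrom) used to
#'   size the cubic box.
#' @param scan_range Length-2 numeric, dimer separations scanned from
#'   `scan_range[1]` to `scan_range[2]` (Angstrom).
#' @param n_samples Number of conformers to generate.
#' @param seed Integer seed.
#' @param max_retries Rejection-sampling retry budget per conformer.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(topology = c("chain", "random_cluster", "dimer_scan"),
                           n_atoms = 6,
                           elements = c("C", "O", "H"),
                           min_distance = 1.1,
                           spacing = 1.5,
                           jitter = 0,
                           density = 0.015,
                           scan_range = c(1.0, 6.0),
                           n_samples = 1,
                           seed = 1,
                           max_retries = 10000) {
  topology <- match.arg(topology)
  if (min_distance <= 0) stop("`min_distance` must be > 0")
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (n_atoms < 1) stop("`n_atoms` must be >= 1")
  if (topology == "dimer_scan") n_atoms <- 2L
  structure(
    list(
      topology = topology, n_atoms = as.integer(n_atoms),
      elements = elements, min_distance = min_distance,
      spacing = spacing, jitter = jitter, density = density,
      scan_range = scan_range, n_samples = as.integer(n_samples),
      seed = as.integer(seed), max_retries = as.integer(max_retries)
    ),
    class = "generator_spec"
  )
}

#' Generate synthetic conformers
#'
#' Deterministic for a fixed spec (including its seed): two calls return
#' bitwise-identical coordinates. Packing failures (the minimum-distance
#' constraint cannot be met within the retry budget) raise an error naming
#' the constraint.
#'
#' @param spec A [generator_spec()].
#' @return A tibble with columns `id` and `conformer` (list-column of
#'   conformers), one row per sample.
#' @examples
#' confs <- generate_conformers(generator_spec("chain", n_atoms = 4))
#' confs$conformer[[1]]
#' @export
generate_conformers <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  confs <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_samples), function(s) generate_one(spec, s))
  })
  tibble::tibble(id = seq_along(confs), conformer = confs)
}

generate_one <- function(spec, sample_index) {
  switch(spec$topology,
    chain = gen_chain(spec),
    random_cluster = gen_cluster(spec),
    dimer_scan = gen_dimer(spec, sample_index)
  )
}

chain_elements <- function(spec) {
  rep_len(spec$elements, spec$n_atoms)
}

gen_chain <- function(spec) {
  base <- cbind((seq_len(spec$n_atoms) - 1) * spec$spacing, 0, 0)
  for (try in seq_len(spec$max_retries)) {
    pos <- base
    if (spec$jitter > 0) {
      pos <- base + matrix(stats::rnorm(3 * spec$n_atoms, sd = spec$jitter),
        ncol = 3
      )
    }
    if (spec$n_atoms == 1 || min(stats::dist(pos)) >= spec$min_distance) {
      return(conformer(chain_elements(spec), pos))
    }
    if (spec$jitter == 0) break
  }
  stop(
    "infeasible packing: chain with spacing ", spec$spacing,
    " A cannot satisfy min_distance ", spec$min_distance, " A"
  )
}

gen_cluster <- function(spec) {
  box <- (spec$n_atoms / spec$density)^(1 / 3)
  elements <- sample(spec$elements, spec$n_atoms, replace = TRUE)
  pos <- matrix(NA_real_, spec$n_atoms, 3)
  pos[1, ] <- stats::runif(3, 0, box)
  placed <- 1L
  tries <- 0L
  while (placed < spec$n_atoms) {
    cand <- stats::runif(3, 0, box)
    d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)
    if (min(d2) >= spec$min_distance^2) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    } else {
      tries <- tries + 1L
      if (tries > spec$max_retries) {
        stop(
          "infeasible packing: cannot place ", spec$n_atoms,
          " atoms with min_distance ", spec$min_distance,
          " A in a box of ", round(box, 2), " A after ",
          spec$max_retries, " retries"
        )
      }
    }
  }
  conformer(elements, pos)
}

gen_dimer <- function(spec, sample_index) {
  r <- if (spec$n_samples == 1) {
    mean(spec$scan_range)
  } else {
    spec$scan_range[1] +
      (sample_index - 1) / (spec$n_samples - 1) * diff(spec$scan_range)
  }
  if (r < spec$min_distance) {
    stop(
      "infeasible packing: dimer separation ", r,
      " A below min_distance ", spec$min_distance, " A"
    )
  }
  conformer(rep_len(spec$elements, 2L), rbind(c(0, 0, 0), c(r, 0, 0)))
}

#' Conformers with element pairs at exactly repeated separations
#'
#' Builds clusters in which one tagged same-element pair (element
#' `pair_element`) sits at one of the given exact separations, embedded in a
#' varying random neighborhood of palette atoms. Because the tagged element
#' appears only in the tagged pair, filtering a pair-strength table to that
#' element pair isolates strengths measured at exactly repeated distances —
#' the construction under which a strictly 2-body potential must give
#' identical strengths (zero many-bodyness).
#'
#' @param n_conformers Number of conformers (the tagged distances are cycled).
#' @param distances Exact pair separations to repeat (Angstrom); the
#'   defaults sit mid-bin for the package's 0.5 Angstrom binning so the
#'   repeated pairs cannot straddle a bin edge through rounding.
#' @param pair_element Element symbol reserved for the tagged pair.
#' @param n_env Number of surrounding environment atoms.
#' @param env_elements Palette for the environment atoms (must not contain
#'   `pair_element`).
#' @param min_distance Minimum distance between any two atoms (Angstrom).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `tag_distance` and `conformer`.
#' @export
generate_repeated_distance_set <- function(n_conformers = 50,
                                           distances = c(2.2, 3.2),
                                           pair_element = "O",
                                           n_env = 5,
                                           env_elements = c("C", "H"),
                                           min_distance = 1.1,
                                           seed = 1) {
  if (pair_element %in% env_elements) {
    stop("`pair_element` must not occur in `env_elements`")
  }
  tag <- rep_len(distances, n_conformers)
  confs <- with_seed(seed, lapply(seq_len(n_conformers), function(k) {
    r <- tag[k]
    # tagged pair along a random direction, environment packed around it
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    pos <- rbind(-r / 2 * u, r / 2 * u)
    el <- rep(pair_element, 2)
    box <- max(2 * r + 4, 8)
    placed <- 2L
    tries <- 0L
    while (placed < n_env + 2L) {
      cand <- stats::runif(3, -box / 2, box / 2)
      d2 <- colSums((t(pos) - cand)^2)
      if (min(d2) >= min_distance^2) {
        pos <- rbind(pos, cand)
        el <- c(el, sample(env_elements, 1))
        placed <- placed + 1L
      } else {
        tries <- tries + 1L
        if (tries > 10000) {
          stop("infeasible packing: repeated-distance environment")
        }
      }
    }
    conformer(el, pos)
  }))
  tibble::tibble(
    id = seq_len(n_conformers),
    tag_distance = tag,
    conformer = confs
  )
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
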