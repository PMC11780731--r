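#' Build a conformer
#'
#' A conformer is one molecular geometry: a tibble with one row per atom and
#' columns `element`, `x`, `y`, `z` (Cartesian coordinates in Angstrom).
#' All user-facing functions in the package accept this shape.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param positions Numeric matrix with `length(elements)` rows and 3 columns
#'   (x, y, z in Angstrom).
#' @return A tibble of class `conformer` with columns `element`, `x`, `y`, `z`.
#' @examples
#' conformer(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
#' @export
conformer <- function(elements, positions) {
  positions <- as.matrix(positions)
  if (!is.character(elements) || length(elements) < 1) {
    stop("`elements` must be a character vector with at least one atom")
  }
  if (nrow(positions) != length(elements) || ncol(positions) != 3) {
    stop("`positions` must be an N x 3 matrix matching `elements`")
  }
  if (!all(is.finite(positions))) stop("coordinates must be finite")
  out <- tibble::tibble(
    element = elements,
    x = as.numeric(positions[, 1]),
    y = as.numeric(positions[, 2]),
    z = as.numeric(positions[, 3])
  )
  class(out) <- c("conformer", class(out))
  validate_conformer(out)
  out
}

validate_conformer <- function(conf) {
  pos <- conformer_positions(conf)
  if (nrow(pos) > 1) {
    d <- stats::dist(pos)
    if (any(d == 0)) stop("conformer has coincident atoms (zero pair distance)")
  }
  invisible(conf)
}

#' Extract the coordinate matrix of a conformer
#'
#' @param conf A conformer (tibble with `x`, `y`, `z` columns).
#' @return Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
conformer_positions <- function(conf) {
  cbind(x = conf$x, y = conf$y, z = conf$z)
}

#' All pairwise distances of a conformer
#'
#' @param conf A conformer.
#' @return A tibble with one row per unordered atom pair `i < j`:
#'   `i`, `j`, `element_i`, `element_j`, `distance` (Angstrom).
#' @export
pair_distances <- function(conf) {
  n <- nrow(conf)
  if (n < 2) {
    return(tibble::tibble(
      i = integer(), j = integer(),
      element_i = character(), element_j = character(),
      distance = numeric()
    ))
  }
  idx <- utils::combn(n, 2)
  pos <- conformer_positions(conf)
  d <- sqrt(rowSums((pos[idx[1, ], , drop = FALSE] - pos[idx[2, ], , drop = FALSE])^2))
  tibble::tibble(
    i = idx[1, ], j = idx[2, ],
    element_i = conf$element[idx[1, ]],
    element_j = conf$element[idx[2, ]],
    distance = d
  )
}

#' Write conformers to an extended-XYZ file
#'
#' One frame per conformer: an atom-count line, a comment line carrying
#' `energy=<float>` when an energy is available, then one
#' `element x y z` line per atom (Angstrom).
#'
#' @param conformers A tibble with a `conformer` list-column (as returned by
#'   [generate_conformers()]) and optionally an `energy` column, or a single
#'   conformer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(conformers, path) {
  conformers <- as_conformer_set(conformers)
  lines <- purrr::pmap(conformers, function(id, conformer, ...) {
    extra <- list(...)
    comment <- if (!is.null(extra$energy) && is.finite(extra$energy)) {
      sprintf("energy=%.17g", extra$energy)
    } else {
      ""
    }
    c(
      as.character(nrow(conformer)),
      comment,
      sprintf(
        "%s %.12f %.12f %.12f",
        conformer$element, conformer$x, conformer$y, conformer$z
      )
    )
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read conformers from an extended-XYZ file
#'
#' @param path File path written by [write_extxyz()] or any plain/extended
#'   XYZ file whose comment line may carry an `energy=<float>` key.
#' @return A tibble with columns `id`, `conformer` (list of conformers) and
#'   `energy` (`NA` where the frame carries no energy).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  energies <- numeric()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) {
      pos <- pos + 1L
      next
    }
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n) || n < 1) stop("malformed XYZ frame at line ", pos)
    comment <- lines[pos + 1L]
    e <- NA_real_
    m <- regmatches(comment, regexpr("energy=[-+0-9.eE]+", comment))
    if (length(m) == 1) e <- as.numeric(sub("energy=", "", m))
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    el <- vapply(fields, `[[`, character(1), 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- conformer(el, xyz)
    energies <- c(energies, e)
    pos <- pos + 2L + n
  }
  tibble::tibble(
    id = seq_along(frames),
    conformer = frames,
    energy = energies
  )
}

# Accept a single conformer, a list of conformers, or a conformer-set tibble
# and return the tibble form (id + conformer list-column).
as_conformer_set <- function(x) {
  if (inherits(x, "conformer")) {
    return(tibble::tibble(id = 1L, conformer = list(x)))
  }
  if (is.data.frame(x) && "conformer" %in% names(x)) {
    if (!"id" %in% names(x)) x$id <- seq_len(nrow(x))
    return(x)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "conformer"))) {
    return(tibble::tibble(id = seq_along(x), conformer = x))
  }
  stop("expected a conformer, a list of conformers, or a conformer-set tibble")
}
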