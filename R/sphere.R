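#' Minimum enclosing sphere of a 3D point set
#'
#' Welzl's recursive algorithm: the smallest sphere is determined by at most
#' four boundary points; points are tested one by one and moved onto the
#' boundary set when they fall outside the current candidate. Degenerate
#' boundary sets (collinear triples, coplanar quadruples) fall back to the
#' smallest sphere over sub-boundaries.
#'
#' @param points Numeric matrix, one row per point, 3 columns.
#' @return A list with `center` (length-3) and `radius`.
#' @export
minimal_enclosing_sphere <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have 3 columns")
  points <- unique(points)
  welzl(points, matrix(numeric(0), 0, 3))
}

welzl <- function(P, B) {
  if (nrow(P) == 0 || nrow(B) == 4) {
    return(sphere_from_boundary(B))
  }
  p <- P[nrow(P), , drop = FALSE]
  s <- welzl(P[-nrow(P), , drop = FALSE], B)
  if (in_sphere(p, s)) {
    return(s)
  }
  welzl(P[-nrow(P), , drop = FALSE], rbind(B, p))
}

in_sphere <- function(p, s, tol = 1e-10) {
  if (s$radius < 0) {
    return(FALSE)
  }
  sqrt(sum((as.numeric(p) - s$center)^2)) <= s$radius * (1 + tol) + tol
}

sphere_from_boundary <- function(B) {
  k <- nrow(B)
  if (k == 0) {
    return(list(center = c(0, 0, 0), radius = -1))
  }
  if (k == 1) {
    return(list(center = as.numeric(B[1, ]), radius = 0))
  }
  if (k == 2) {
    ctr <- (B[1, ] + B[2, ]) / 2
    return(list(center = as.numeric(ctr), radius = sqrt(sum((B[1, ] - ctr)^2))))
  }
  s <- tryCatch(circumsphere(B), error = function(e) NULL)
  if (!is.null(s)) {
    return(s)
  }
  # degenerate boundary: fall back to the smallest sub-boundary sphere
  # that still contains all boundary points
  best <- NULL
  for (m in 2:(k - 1)) {
    subs <- utils::combn(k, m)
    for (c_idx in seq_len(ncol(subs))) {
      cand <- sphere_from_boundary(B[subs[, c_idx], , drop = FALSE])
      if (cand$radius >= 0 &&
        all(apply(B, 1, function(p) in_sphere(p, cand)))) {
        if (is.null(best) || cand$radius < best$radius) best <- cand
      }
    }
  }
  if (is.null(best)) stop("degenerate boundary set")
  best
}

# Circumsphere of 3 (in-plane circle) or 4 affinely independent points.
circumsphere <- function(B) {
  k <- nrow(B)
  p1 <- B[1, ]
  D <- sweep(B[-1, , drop = FALSE], 2, p1)
  rhs <- rowSums(D^2) / 2
  if (k == 4) {
    if (abs(det(D)) < 1e-12 * max(abs(D))^3) stop("coplanar")
    coef <- solve(D, rhs)
    ctr <- p1 + coef
  } else {
    # 3 points: center lies in their plane
    G <- D %*% t(D)
    if (abs(det(G)) < 1e-14 * max(abs(G))^2) stop("collinear")
    ab <- solve(G, rhs)
    ctr <- p1 + as.numeric(t(D) %*% ab)
  }
  list(center = as.numeric(ctr), radius = sqrt(sum((p1 - ctr)^2)))
}

#' Extent of a walk
#'
#' The diameter of the smallest sphere enclosing the (deduplicated) atoms a
#' walk visits. A walk visiting a single atom (all self transitions) has
#' extent 0; a walk visiting two atoms has extent equal to their distance.
#'
#' @param atoms Integer vector of atom indices visited by the walk.
#' @param positions Numeric N x 3 coordinate matrix (Angstrom), or a
#'   conformer.
#' @return The extent in Angstrom (>= 0).
#' @export
walk_extent <- function(atoms, positions) {
  if (is.data.frame(positions)) positions <- conformer_positions(positions)
  pts <- unique(positions[unique(atoms), , drop = FALSE])
  if (nrow(pts) < 2) {
    return(0)
  }
  2 * minimal_enclosing_sphere(pts)$radius
}
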