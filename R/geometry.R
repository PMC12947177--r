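#' @keywords internal
"_PACKAGE"

# ---- low-level vector helpers (3-vectors as numeric length-3) ----

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a sphere
#'
#' A sphere is the locus of points at a fixed distance (radius, in Angstrom)
#' from a center.  Spheres are the carriers of exact distance constraints in
#' the discretizable distance-geometry formulation: a vertex with three known
#' distances to placed predecessors lies on the intersection of three spheres.
#'
#' @param center numeric length-3, center coordinates in Angstrom.
#' @param radius positive scalar radius in Angstrom.
#' @return an object of class `sphere` (a list with `center` and `radius`).
#' @examples
#' sphere(c(0, 0, 0), 1.5)
#' @export
sphere <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("sphere center must be a finite 3-vector")
  if (!is.finite(radius) || radius <= 0)
    stop("sphere radius must be > 0")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "sphere")
}

#' Strict triangle inequality test
#'
#' Checks `d_jk + d_kl > d_jl` strictly.  The strictness is what guarantees
#' that three predecessor centers are non-collinear, so that the intersection
#' of their three spheres is at most two points rather than a degenerate set.
#'
#' @param d_jk,d_kl,d_jl positive distances in Angstrom.
#' @return logical scalar.
#' @examples
#' strict_triangle_ok(1, 1, 2)    # FALSE: collinear
#' strict_triangle_ok(3, 4, 5)    # TRUE
#' @export
strict_triangle_ok <- function(d_jk, d_kl, d_jl) {
  if (any(!is.finite(c(d_jk, d_kl, d_jl))) || any(c(d_jk, d_kl, d_jl) <= 0))
    stop("non-positive-distance: all distances must be finite and > 0")
  (d_jk + d_kl) > d_jl
}

# Orthonormal trilateration frame from three centers.
# Returns NULL when the centers are collinear within eps (scale-invariant
# test: parallelogram area < eps * longest_side^2).
trilat_frame <- function(c1, c2, c3, eps = 1e-9) {
  v21 <- c2 - c1
  v31 <- c3 - c1
  d <- vnorm(v21)
  if (d == 0 || vnorm(v31) == 0 || vnorm(c3 - c2) == 0)
    stop("degenerate-centers: sphere centers must be pairwise distinct")
  cr <- vcross(v21, v31)
  lmax <- max(d, vnorm(v31), vnorm(c3 - c2))
  if (vnorm(cr) < eps * lmax^2) return(NULL)
  ex <- v21 / d
  i <- sum(ex * v31)
  eyv <- v31 - i * ex
  ey <- eyv / vnorm(eyv)
  ez <- vcross(ex, ey)
  list(ex = ex, ey = ey, ez = ez, d = d, i = i, j = sum(ey * v31))
}

#' Intersection of three sphere surfaces
#'
#' Returns the 0, 1 or 2 points common to three sphere surfaces.  Two points
#' are mirror images across the plane of the three centers; when the squared
#' off-plane coordinate falls within `eps` of zero the two merge into a single
#' tangent point, and when it is below `-eps` the intersection is empty.
#'
#' @param s1,s2,s3 `sphere` objects with pairwise distinct, non-collinear
#'   centers.
#' @param eps numerical slack for the collinearity and tangency tests
#'   (default `1e-9`).
#' @return a list of 0, 1 or 2 numeric length-3 points.
#' @examples
#' s <- lapply(list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), sphere, radius = 2)
#' intersect_three_spheres(s[[1]], s[[2]], s[[3]])
#' @export
intersect_three_spheres <- function(s1, s2, s3, eps = 1e-9) {
  fr <- trilat_frame(s1$center, s2$center, s3$center, eps)
  if (is.null(fr))
    stop("degenerate-centers: collinear sphere centers (strict triangle inequality violated)")
  r1 <- s1$radius; r2 <- s2$radius; r3 <- s3$radius
  x <- (r1^2 - r2^2 + fr$d^2) / (2 * fr$d)
  y <- (r1^2 - r3^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) / (2 * fr$j)
  h2 <- r1^2 - x^2 - y^2
  base <- s1$center + x * fr$ex + y * fr$ey
  if (h2 < -eps) return(list())
  if (h2 < eps) return(list(base))
  h <- sqrt(h2)
  list(base + h * fr$ez, base - h * fr$ez)
}

# Vectorized variant used by the interval-discretization step of the BP
# search: the first two radii are fixed, the third sphere's radius varies
# over `r3` (one sampled value per entry).  Returns a matrix of candidate
# points (rows) and, in attributes, the sample index and branch sign of each
# row.  Rows are emitted in ascending-sample order, '+' branch first.
trilaterate_many <- function(c1, r1, c2, r2, c3, r3, eps = 1e-9, tang = eps) {
  fr <- trilat_frame(c1, c2, c3, eps)
  if (is.null(fr))
    stop("degenerate-centers: collinear sphere centers (strict triangle inequality violated)")
  x <- (r1^2 - r2^2 + fr$d^2) / (2 * fr$d)
  y <- (r1^2 - r3^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) / (2 * fr$j)
  h2 <- r1^2 - x^2 - y^2
  nK <- length(r3)
  bx <- c1[1L] + x * fr$ex[1L] + y * fr$ey[1L]
  by <- c1[2L] + x * fr$ex[2L] + y * fr$ey[2L]
  bz <- c1[3L] + x * fr$ex[3L] + y * fr$ey[3L]
  tangent <- h2 >= -tang & h2 < eps
  two <- h2 >= eps
  h <- sqrt(pmax(h2, 0))
  # interleave: for each sample, '+' then '-' (tangent samples emit one row)
  nrep <- ifelse(two, 2L, ifelse(tangent, 1L, 0L))
  idx <- rep.int(seq_len(nK), nrep)
  sgn <- unlist(lapply(seq_len(nK), function(k) {
    if (two[k]) c(1, -1) else if (tangent[k]) 0 else numeric(0)
  }), use.names = FALSE)
  if (length(idx) == 0L)
    return(structure(matrix(numeric(0), 0L, 3L), sample = integer(0), sign = numeric(0)))
  hh <- h[idx] * sgn
  pts <- cbind(bx[idx] + hh * fr$ez[1L],
               by[idx] + hh * fr$ez[2L],
               bz[idx] + hh * fr$ez[3L])
  structure(pts, sample = idx, sign = sgn)
}

#' Filter candidate points against a fourth sphere
#'
#' Keeps exactly the candidates whose distance to the fourth sphere's center
#' matches its radius within `tol`.  An empty result is a valid outcome: it is
#' the signal on which the Branch-and-Prune search backtracks.
#'
#' @param cands list of numeric length-3 points (as returned by
#'   [intersect_three_spheres()]).
#' @param s4 a `sphere`.
#' @param tol acceptance tolerance in Angstrom (default 0.01).
#' @return the surviving candidates, order preserved.
#' @export
refine_with_fourth <- function(cands, s4, tol = 0.01) {
  if (tol <= 0) stop("tol must be > 0")
  keep <- vapply(cands, function(p) abs(vnorm(p - s4$center) - s4$radius) <= tol,
                 logical(1L))
  cands[keep]
}

#' Common point of four sphere surfaces
#'
#' Solves the four sphere equations by differencing the quadratic equations
#' into a 3x3 linear system (exact when the radii are consistent).  The four
#' centers must not be coplanar; the returned point is accepted only if every
#' sphere-equation residual is at most `eps`.
#'
#' @param s1,s2,s3,s4 `sphere` objects with non-coplanar centers.
#' @param eps residual acceptance threshold in Angstrom (default `1e-6`).
#' @return numeric length-3 point with attribute `residuals` (length 4).
#' @export
four_sphere_point <- function(s1, s2, s3, s4, eps = 1e-6) {
  cs <- rbind(s1$center, s2$center, s3$center, s4$center)
  rs <- c(s1$radius, s2$radius, s3$radius, s4$radius)
  A <- 2 * (cs[2:4, , drop = FALSE] - matrix(cs[1L, ], 3L, 3L, byrow = TRUE))
  scale <- max(dist(cs))
  vol <- abs(det(A)) / 8  # 6 * tetrahedron volume
  if (vol < 1e-9 * scale^3)
    stop("coplanar-centers: the four sphere centers are coplanar")
  b <- (rs[1L]^2 - rs[2:4]^2) - sum(cs[1L, ]^2) + rowSums(cs[2:4, , drop = FALSE]^2)
  p <- drop(solve(A, b))
  res <- abs(sqrt(rowSums((cs - matrix(p, 4L, 3L, byrow = TRUE))^2)) - rs)
  if (max(res) > eps)
    stop(sprintf("inconsistent-radii: max residual %.3g exceeds eps %.3g",
                 max(res), eps))
  structure(p, residuals = res)
}
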