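# Branch-and-Prune enumeration over a DDGP instance.
#
# Depth-first over the vertex order: vertices with three exact predecessor
# distances land on the (at most two) intersection points of three spheres;
# a fourth or later exact predecessor acts as a refinement sphere; the one
# interval discretization edge is sampled at K uniformly spaced radii, each
# giving at most two candidates (up to 2K).  Every remaining edge incident
# to the vertex prunes candidates, and the search backtracks on an empty
# candidate set.  Branch order is deterministic: ascending sample radius,
# positive side of the predecessor plane first.

#' Branch-and-Prune configuration
#'
#' @param K number of uniform samples taken inside the interval
#'   discretization edge (endpoints inclusive; default 1000).
#' @param tol constraint tolerance in Angstrom: exact edges must match
#'   within `tol`, interval edges within `[lo - tol, hi + tol]`
#'   (default 0.01).
#' @param max_solutions optional cap on the number of solutions collected.
#' @param enumerate_all explore the full tree (default) or stop at the cap.
#' @param eps geometric degeneracy slack (default 1e-9).
#' @return an object of class `bp_config`.
#' @export
bp_config <- function(K = 1000L, tol = 0.01, max_solutions = Inf,
                      enumerate_all = TRUE, eps = 1e-9) {
  stopifnot(K >= 2L, tol > 0)
  structure(list(K = as.integer(K), tol = tol, max_solutions = max_solutions,
                 enumerate_all = isTRUE(enumerate_all), eps = eps),
            class = "bp_config")
}

# Per-vertex placement plan extracted from the instance edge table.
solver_plan <- function(instance, config) {
  ord <- instance$order
  m <- nrow(ord$vertices)
  ed <- instance$edges
  elo <- matrix(NA_real_, m, m)
  ehi <- matrix(NA_real_, m, m)
  for (k in seq_len(nrow(ed))) {
    elo[ed$i[k], ed$j[k]] <- ed$lo[k]
    ehi[ed$i[k], ed$j[k]] <- ed$hi[k]
  }
  lookup <- function(i, j) c(elo[min(i, j), max(i, j)], ehi[min(i, j), max(i, j)])
  plan <- vector("list", m)
  for (i in seq.int(4L, m)) {
    pr <- ord$preds[[i]]
    js <- pr$j
    vals <- t(vapply(js, function(j) lookup(i, j), numeric(2L)))
    interval_pred <- vals[, 1L] < vals[, 2L]
    if (any(is.na(vals)))
      stop("invalid-instance: predecessor edge of vertex ", i, " missing")
    if (any(interval_pred[1:2]))
      stop("invalid-instance: the first two predecessor edges of vertex ", i,
           " must be exact")
    type <- if (nrow(pr) >= 3L && interval_pred[3L]) "interval" else "exact"
    refine <- if (nrow(pr) > 3L) seq.int(4L, nrow(pr)) else integer(0)
    if (length(refine) > 0L && any(interval_pred[refine]))
      stop("invalid-instance: refinement predecessor edges must be exact")
    # incident pruning edges: everything not consumed above
    inc <- ed[ed$j == i & !(ed$i %in% js), , drop = FALSE]
    plan[[i]] <- list(
      j1 = js[1L], j2 = js[2L], j3 = js[3L],
      r1 = vals[1L, 1L], r2 = vals[2L, 1L],
      lo3 = vals[3L, 1L], hi3 = vals[3L, 2L],
      type = type,
      refine_j = js[refine], refine_d = vals[refine, 1L],
      prune_j = inc$i, prune_lo = inc$lo, prune_hi = inc$hi)
  }
  plan
}

# Candidate positions for one vertex given the partial embedding.
# Returns a matrix of points (rows) with attribute `label` (branch labels).
# A near-tangent intersection (h^2 slightly negative) still emits the
# in-plane point when its sphere residuals stay within the constraint
# tolerance (-h^2 <= 2 * r_min * tol): amide hydrogens are coplanar with
# their three predecessor centers, so their placement is tangent by
# construction and must not be lost to upstream rounding.
vertex_candidates <- function(info, coords, config) {
  c1 <- coords[info$j1, ]; c2 <- coords[info$j2, ]; c3 <- coords[info$j3, ]
  tang <- 2 * config$tol * min(info$r1, info$r2, info$lo3)
  if (info$type == "interval" && info$lo3 < info$hi3) {
    radii <- seq(info$lo3, info$hi3, length.out = config$K)
    pts <- trilaterate_many(c1, info$r1, c2, info$r2, c3, radii,
                            eps = config$eps, tang = tang)
    labels <- sprintf("%d%s", attr(pts, "sample"),
                      c(`-1` = "-", `0` = "o", `1` = "+")[
                        as.character(attr(pts, "sign"))])
  } else {
    pts <- trilaterate_many(c1, info$r1, c2, info$r2, c3, info$lo3,
                            eps = config$eps, tang = tang)
    labels <- c(`-1` = "-", `0` = "o", `1` = "+")[
      as.character(attr(pts, "sign"))]
  }
  if (nrow(pts) == 2L && sum((pts[1L, ] - pts[2L, ])^2) < 1e-12) {
    pts <- pts[1L, , drop = FALSE]   # tangency duplicate
    labels <- labels[1L]
  }
  structure(pts, label = unname(labels))
}

# Vectorized refinement + pruning of a candidate matrix; returns the kept
# row indices and the number pruned.
filter_candidates <- function(pts, info, coords, tol) {
  keep <- rep(TRUE, nrow(pts))
  if (length(info$refine_j) > 0L)
    for (k in seq_along(info$refine_j)) {
      cj <- coords[info$refine_j[k], ]
      d <- sqrt((pts[, 1L] - cj[1L])^2 + (pts[, 2L] - cj[2L])^2 +
                  (pts[, 3L] - cj[3L])^2)
      keep <- keep & abs(d - info$refine_d[k]) <= tol
    }
  if (length(info$prune_j) > 0L)
    for (k in seq_along(info$prune_j)) {
      cj <- coords[info$prune_j[k], ]
      d <- sqrt((pts[, 1L] - cj[1L])^2 + (pts[, 2L] - cj[2L])^2 +
                  (pts[, 3L] - cj[3L])^2)
      keep <- keep & d >= info$prune_lo[k] - tol & d <= info$prune_hi[k] + tol
    }
  keep
}

# Gauss-Newton least-squares fit of a point to a set of sphere constraints
# (min over p of sum_i (|p - c_i| - r_i)^2).  Used to place over-determined
# vertices (>= 4 exact predecessors): balancing the residuals instead of
# trusting the first three spheres stops placement error from compounding
# along the order.
ls_sphere_fit <- function(p, centers, radii, iters = 8L) {
  for (it in seq_len(iters)) {
    dv <- centers - matrix(p, nrow(centers), 3L, byrow = TRUE)
    dn <- sqrt(rowSums(dv * dv))
    f <- dn - radii
    J <- -dv / dn
    g <- crossprod(J, f)
    H <- crossprod(J) + diag(1e-12, 3L)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    p <- p + drop(step)
    if (sum(step^2) < 1e-24) break
  }
  p
}

# Candidate placement for an over-determined vertex: trilateration seeds a
# least-squares fit over all predecessor spheres; candidates far off the
# refinement spheres (residual > max(10 tol, 0.1)) are not seeded, mirror
# seeds converging to the same point are merged, and (unless `reject =
# FALSE`, used by the exhaustive-enumeration oracle, which defers all
# feasibility checks to the leaves) candidates whose worst sphere residual
# exceeds tol are dropped.
refine_candidates <- function(pts, labels, info, coords, tol, reject = TRUE) {
  ctr <- rbind(coords[info$j1, ], coords[info$j2, ], coords[info$j3, ],
               coords[info$refine_j, , drop = FALSE])
  rad <- c(info$r1, info$r2, info$lo3, info$refine_d)
  pre <- filter_candidates(pts, list(refine_j = info$refine_j,
                                     refine_d = info$refine_d,
                                     prune_j = integer(0)),
                           coords, max(10 * tol, 0.1))
  out <- matrix(numeric(0), 0L, 3L)
  lab <- character(0)
  for (r in which(pre)) {
    p <- ls_sphere_fit(pts[r, ], ctr, rad)
    res <- abs(sqrt(rowSums((ctr - matrix(p, nrow(ctr), 3L,
                                          byrow = TRUE))^2)) - rad)
    if (reject && max(res) > tol) next
    if (nrow(out) > 0L &&
        any(rowSums((out - matrix(p, nrow(out), 3L, byrow = TRUE))^2) < 1e-12))
      next
    out <- rbind(out, p)
    lab <- c(lab, labels[r])
  }
  structure(out, label = lab)
}

#' Candidate positions from three exact predecessor spheres
#'
#' The two-candidate branching step of BP: the vertex lands on the
#' intersection of the spheres around its first three predecessors; any
#' further exact predecessor refines the candidates down to at most one.
#'
#' @param vertex vertex order index (>= 4).
#' @param coords partial embedding (matrix, rows = placed vertices).
#' @param instance a `ddgp_instance`.
#' @param config a [bp_config()].
#' @return list of candidate points (numeric length-3), at most two before
#'   refinement.
#' @export
place_exact <- function(vertex, coords, instance, config = bp_config()) {
  plan <- solver_plan(instance, config)
  info <- plan[[vertex]]
  if (info$type != "exact")
    stop("vertex ", vertex, " is the interval-discretization vertex; ",
         "use place_interval()")
  pts <- vertex_candidates(info, coords, config)
  keep <- rep(TRUE, nrow(pts))
  if (length(info$refine_j) > 0L)
    keep <- filter_candidates(pts, list(refine_j = info$refine_j,
                                        refine_d = info$refine_d,
                                        prune_j = integer(0)),
                              coords, config$tol)
  lapply(which(keep), function(r) pts[r, ])
}

#' Candidate positions from two exact spheres and a sampled interval
#'
#' The interval discretization step: K uniformly spaced radii spanning
#' `[lo, hi]` (endpoints included), each intersected with the two exact
#' predecessor spheres, giving up to `2K` candidates in ascending sample
#' order.
#'
#' @inheritParams place_exact
#' @return list of candidate points (up to `2K`).
#' @export
place_interval <- function(vertex, coords, instance, config = bp_config()) {
  plan <- solver_plan(instance, config)
  info <- plan[[vertex]]
  pts <- vertex_candidates(info, coords, config)
  lapply(seq_len(nrow(pts)), function(r) pts[r, ])
}

#' Pruning-edge test for one candidate
#'
#' TRUE (keep) iff every pruning edge joining `vertex` to an already placed
#' vertex is satisfied: exact edges within `tol`, interval edges within
#' `[lo - tol, hi + tol]`.
#'
#' @param candidate numeric length-3 position.
#' @inheritParams place_exact
#' @return logical scalar.
#' @export
prune <- function(candidate, vertex, coords, instance, config = bp_config()) {
  info <- solver_plan(instance, config)[[vertex]]
  sel <- vapply(info$prune_j, function(j)
    j <= nrow(coords) && all(is.finite(coords[j, ])), logical(1L))
  keep <- filter_candidates(matrix(candidate, 1L, 3L),
                            list(refine_j = integer(0),
                                 prune_j = info$prune_j[sel],
                                 prune_lo = info$prune_lo[sel],
                                 prune_hi = info$prune_hi[sel]),
                            coords, config$tol)
  unname(keep)
}

#' Maximum constraint violation of a full embedding
#'
#' For exact edges the absolute residual; for interval edges the distance
#' outside `[lo, hi]` (zero inside).  The maximum over all edges is the
#' standard solution-quality score of the method.
#'
#' @param coords full embedding (matrix with one row per vertex).
#' @param instance a `ddgp_instance`.
#' @return maximum residual in Angstrom.
#' @export
compute_max_err <- function(coords, instance) {
  ed <- instance$edges
  d <- sqrt(rowSums((coords[ed$i, , drop = FALSE] -
                       coords[ed$j, , drop = FALSE])^2))
  max(pmax(ed$lo - d, d - ed$hi, 0))
}

#' Enumerate all embeddings of a DDGP instance by Branch-and-Prune
#'
#' @param instance a `ddgp_instance` (see [assemble_instance()] or
#'   [fabricate_instance()]).
#' @param config a [bp_config()].
#' @return an object of class `bp_solutions`: list with `solutions` (list of
#'   coordinate matrices, rows named by atom key), `signatures`,
#'   `max_err`, `rmsd` (anchored RMSD to the reference, if present),
#'   `nodes` and `pruned` counters, `truncated` flag, `wall_time` seconds.
#' @examples
#' inst <- fabricate_instance(loop_spec(6, seed = 1),
#'                            intervals = interval_spec(delta = 0.5, seed = 1))
#' sols <- bp_solve(inst, bp_config(K = 50))
#' summary(sols)
#' @export
bp_solve <- function(instance, config = bp_config()) {
  stopifnot(inherits(instance, "ddgp_instance"))
  t0 <- proc.time()[["elapsed"]]
  viol <- validate_order(instance)
  if (nrow(viol) > 0L)
    stop("invalid-instance: ", nrow(viol), " order violations (see validate_order)")
  ord <- instance$order
  m <- nrow(ord$vertices)
  plan <- solver_plan(instance, config)
  tol <- config$tol

  coords <- matrix(NA_real_, m, 3L,
                   dimnames = list(ord$vertices$key, NULL))
  coords[1:3, ] <- instance$anchor_coords
  labels <- character(m)

  sols <- list()
  sigs <- character(0)
  nodes <- 0L
  pruned <- 0L
  truncated <- FALSE

  recurse <- function(i) {
    if (truncated) return()
    if (i > m) {
      sols[[length(sols) + 1L]] <<- coords
      sigs <<- c(sigs, paste(labels[4:m], collapse = "/"))
      if (length(sols) >= config$max_solutions) truncated <<- TRUE
      return()
    }
    info <- plan[[i]]
    pts <- tryCatch(vertex_candidates(info, coords, config),
                    error = function(e) {
                      if (grepl("degenerate-centers", conditionMessage(e)))
                        structure(matrix(numeric(0), 0L, 3L),
                                  label = character(0))
                      else stop(e)
                    })
    nodes <<- nodes + nrow(pts)
    if (nrow(pts) == 0L) return()
    if (info$type == "exact" && length(info$refine_j) > 0L) {
      polished <- refine_candidates(pts, attr(pts, "label"), info, coords, tol)
      pruned <<- pruned + nrow(pts) - nrow(polished)
      pts <- polished
      if (nrow(pts) == 0L) return()
      info <- c(info[setdiff(names(info), "refine_j")],
                list(refine_j = integer(0)))
    }
    keep <- filter_candidates(pts, info, coords, tol)
    pruned <<- pruned + sum(!keep)
    for (r in which(keep)) {
      coords[i, ] <<- pts[r, ]
      labels[i] <<- attr(pts, "label")[r]
      recurse(i + 1L)
      if (truncated) break
    }
    coords[i, ] <<- NA_real_
  }
  recurse(4L)

  max_err <- vapply(sols, compute_max_err, numeric(1L), instance = instance)
  rmsd <- rep(NA_real_, length(sols))
  if (!is.null(instance$reference_coords))
    rmsd <- vapply(sols, anchored_rmsd, numeric(1L),
                   reference = instance$reference_coords)
  structure(list(
    solutions = sols,
    signatures = sigs,
    max_err = max_err,
    rmsd = rmsd,
    nodes = nodes,
    pruned = pruned,
    truncated = truncated,
    kind = ord$kind,
    n_residues = ord$n_residues,
    delta = instance$delta,
    K = config$K,
    tol = tol,
    wall_time = proc.time()[["elapsed"]] - t0
  ), class = "bp_solutions")
}

#' @export
print.bp_solutions <- function(x, ...) {
  cat(sprintf("BP solution set (%s-order, %d-residue loop): %d solution%s\n",
              if (x$kind == "H") "H" else "Hbar", x$n_residues,
              length(x$solutions), if (length(x$solutions) == 1L) "" else "s"))
  if (length(x$solutions) > 0L) {
    cat(sprintf("  max_err: max %.4g A (tol %.3g)\n", max(x$max_err), x$tol))
    if (!all(is.na(x$rmsd)))
      cat(sprintf("  anchored RMSD vs reference: min %.4f / mean %.4f / max %.4f A\n",
                  min(x$rmsd), mean(x$rmsd), max(x$rmsd)))
  }
  cat(sprintf("  tree: %d candidates generated, %d pruned, %.2f s%s\n",
              x$nodes, x$pruned, x$wall_time,
              if (x$truncated) " (truncated at cap)" else ""))
  invisible(x)
}

#' @export
summary.bp_solutions <- function(object, ...) {
  out <- data.frame(
    kind = object$kind,
    n_residues = object$n_residues,
    delta = object$delta,
    K = object$K,
    n_solutions = length(object$solutions),
    min_rmsd = if (all(is.na(object$rmsd))) NA_real_ else min(object$rmsd),
    mean_rmsd = if (all(is.na(object$rmsd))) NA_real_ else mean(object$rmsd),
    max_rmsd = if (all(is.na(object$rmsd))) NA_real_ else max(object$rmsd),
    max_err = if (length(object$max_err)) max(object$max_err) else NA_real_,
    nodes = object$nodes,
    pruned = object$pruned,
    tsecs = object$wall_time)
  class(out) <- c("summary.bp_solutions", "data.frame")
  out
}

#' @export
plot.bp_solutions <- function(x, ...) {
  if (length(x$solutions) == 0L) {
    graphics::plot.new()
    graphics::title("no solutions")
    return(invisible(x))
  }
  if (all(is.na(x$rmsd))) {
    graphics::hist(x$max_err, main = "constraint violation per solution",
                   xlab = "max_err (A)", ...)
  } else {
    graphics::plot(x$rmsd, x$max_err,
                   xlab = "anchored RMSD to reference (A)",
                   ylab = "max_err (A)",
                   main = sprintf("%d solutions (%s-order, delta = %.2f A)",
                                  length(x$solutions), x$kind, x$delta), ...)
  }
  invisible(x)
}
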