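# Shared fixtures: the canonical six-residue template (29-vertex order,
# predecessor sets, a priori edge list), random-sphere generators, instance
# truncation, and the exhaustive-tree enumeration oracle.

# The printed 29-vertex template order for the 6-residue loop anchored at
# residues 1/3/5, as loop-local atom keys.
template_order_keys <- c(
  "CA:1", "CA:5", "C:5", "N:1", "C:6", "CA:6", "N:6", "HA:6", "H:6", "HA:5",
  "N:5", "CA:3", "C:3", "C:4", "CA:4", "H:5", "N:4", "HA:4", "H:4", "N:3",
  "HA:3", "C:1", "HA:1", "C:2", "CA:2", "H:3", "N:2", "HA:2", "H:2")

# Predecessor sets of the template, vertex index -> list(keys, classes).
template_pred_sets <- list(
  `4` = list(c("CA:1", "CA:5", "C:5"), c("b", "r", "r")),
  `5` = list(c("CA:1", "CA:5", "C:5", "N:1"), c("r", "r", "r", "r")),
  `6` = list(c("CA:1", "CA:5", "C:5", "N:1", "C:6"), c("r", "r", "b", "r", "b")),
  `7` = list(c("CA:1", "CA:5", "C:5", "N:1", "C:6", "CA:6"),
             c("r", "b", "b", "r", "b", "b")),
  `8` = list(c("C:6", "CA:6", "N:6"), c("b", "b", "b")),
  `9` = list(c("C:5", "CA:6", "N:6"), c("b", "b", "b")),
  `10` = list(c("CA:5", "C:5", "H:6"), c("b", "b", "*")),
  `11` = list(c("CA:5", "C:5", "HA:5"), c("b", "b", "b")),
  `12` = list(c("CA:1", "CA:5", "N:1", "N:5"), c("r", "r", "r", "r")),
  `13` = list(c("CA:5", "N:5", "CA:3"), c("r", "r", "b")),
  `14` = list(c("CA:5", "N:5", "CA:3", "C:3"), c("b", "b", "r", "r")),
  `15` = list(c("CA:5", "N:5", "CA:3", "C:3", "C:4"),
              c("r", "b", "r", "b", "b")),
  `16` = list(c("CA:5", "N:5", "C:4"), c("b", "b", "b")),
  `17` = list(c("CA:5", "N:5", "CA:3", "C:3", "C:4", "CA:4"),
              c("r", "r", "b", "b", "b", "b")),
  `18` = list(c("C:4", "CA:4", "N:4"), c("b", "b", "b")),
  `19` = list(c("C:3", "CA:4", "N:4"), c("b", "b", "b")),
  `20` = list(c("CA:1", "N:1", "CA:3", "C:3"), c("r", "r", "b", "b")),
  `21` = list(c("CA:3", "C:3", "N:3"), c("b", "b", "b")),
  `22` = list(c("CA:1", "N:1", "CA:3", "N:3"), c("b", "b", "r", "r")),
  `23` = list(c("CA:1", "N:1", "C:1"), c("b", "b", "b")),
  `24` = list(c("CA:1", "N:1", "CA:3", "N:3"), c("r", "r", "b", "b")),
  `25` = list(c("CA:1", "N:1", "N:3", "C:2"), c("r", "r", "b", "b")),
  `26` = list(c("CA:3", "N:3", "C:2"), c("b", "b", "b")),
  `27` = list(c("CA:1", "N:1", "N:3", "C:1", "C:2", "CA:2"),
              c("b", "r", "r", "b", "b", "b")),
  `28` = list(c("C:2", "CA:2", "N:2"), c("b", "b", "b")),
  `29` = list(c("C:1", "CA:2", "N:2"), c("b", "b", "b")))

# The a priori edge list of the template as printed (vertex index pairs),
# with the single typographic correction (21,24) -> (20,24): the pair as
# printed joins HA:3 and C:2, which is neither a bonded nor an intra-body
# pair, while the predecessor set of C:2 requires its edge to N:3 = v20.
template_edge_pairs <- rbind(
  c(1,2),c(1,3),c(1,4),c(1,5),c(1,6),c(1,7),c(1,12),c(1,20),c(1,22),c(1,23),
  c(1,24),c(1,25),c(1,27),c(2,3),c(2,4),c(2,5),c(2,6),c(2,7),c(2,10),c(2,11),
  c(2,12),c(2,13),c(2,14),c(2,15),c(2,16),c(2,17),c(3,4),c(3,5),c(3,6),c(3,7),
  c(3,9),c(3,10),c(3,11),c(4,5),c(4,6),c(4,7),c(5,6),c(5,7),c(5,8),c(6,7),
  c(6,8),c(6,9),c(7,8),c(7,9),c(9,10),c(10,11),c(11,12),c(11,13),c(11,14),
  c(11,15),c(11,16),c(11,17),c(12,13),c(12,14),c(12,15),c(12,17),c(12,20),
  c(12,21),c(12,22),c(12,24),c(12,25),c(12,26),c(12,27),c(13,14),c(13,15),
  c(13,17),c(13,19),c(13,20),c(13,21),c(14,15),c(14,16),c(14,17),c(14,18),
  c(15,17),c(15,18),c(15,19),c(17,18),c(17,19),c(20,21),c(20,22),c(20,24),
  c(20,25),c(20,26),c(20,27),c(22,23),c(22,24),c(22,25),c(22,27),c(22,29),
  c(24,25),c(24,26),c(24,27),c(24,28),c(25,27),c(25,28),c(25,29),c(27,28),
  c(27,29))

# Random well-separated sphere triple through a known point; returns
# list(spheres, point).
random_sphere_triple <- function() {
  repeat {
    cs <- matrix(stats::runif(9L, -5, 5), 3L, 3L)
    p <- stats::runif(3L, -5, 5)
    area <- loopBP:::vnorm(loopBP:::vcross(cs[2L, ] - cs[1L, ],
                                           cs[3L, ] - cs[1L, ]))
    rads <- sqrt(rowSums((cs - matrix(p, 3L, 3L, byrow = TRUE))^2))
    if (area > 1 && min(rads) > 0.5 && min(dist(cs)) > 0.5) break
  }
  list(spheres = lapply(1:3, function(i) sphere(cs[i, ], rads[i])),
       point = p, centers = cs)
}

# Count the real intersection points of three spheres by dense angular
# search on the intersection circle of the first two (independent of the
# closed-form kernel).
grid_count_three_spheres <- function(s1, s2, s3, n_grid = 200000L) {
  c1 <- s1$center; c2 <- s2$center
  d <- sqrt(sum((c2 - c1)^2))
  x <- (s1$radius^2 - s2$radius^2 + d^2) / (2 * d)
  rho2 <- s1$radius^2 - x^2
  if (rho2 < 0) return(0L)
  ex <- (c2 - c1) / d
  a <- if (abs(ex[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ey <- a - sum(a * ex) * ex; ey <- ey / sqrt(sum(ey^2))
  ez <- loopBP:::vcross(ex, ey)
  th <- seq(0, 2 * pi, length.out = n_grid)
  cc <- c1 + x * ex
  pts <- matrix(cc, n_grid, 3L, byrow = TRUE) +
    sqrt(rho2) * (outer(cos(th), ey) + outer(sin(th), ez))
  g <- sqrt(rowSums((pts - matrix(s3$center, n_grid, 3L, byrow = TRUE))^2)) -
    s3$radius
  sum(abs(diff(sign(g))) > 0) # sign changes = surface crossings
}

# Restrict an instance to its first nv vertices.
truncate_instance <- function(inst, nv) {
  ord <- inst$order
  keep_keys <- ord$vertices$key[seq_len(nv)]
  ord2 <- ord
  ord2$vertices <- ord$vertices[seq_len(nv), , drop = FALSE]
  ord2$preds <- ord$preds[seq_len(nv)]
  inst2 <- inst
  inst2$order <- ord2
  inst2$edges <- inst$edges[inst$edges$j <= nv, , drop = FALSE]
  inst2$reference_coords <- inst$reference_coords[keep_keys, , drop = FALSE]
  inst2
}

# Exhaustive full-tree enumeration: expands every candidate at every vertex
# (no refinement rejection, no pruning) and filters complete embeddings at
# the leaves by the full edge-residual check.
oracle_count <- function(inst, config) {
  plan <- loopBP:::solver_plan(inst, config)
  m <- nrow(inst$order$vertices)
  coords <- matrix(NA_real_, m, 3L)
  coords[1:3, ] <- inst$anchor_coords
  n_sol <- 0L
  recurse <- function(i) {
    if (i > m) {
      if (compute_max_err(coords, inst) <= config$tol)
        n_sol <<- n_sol + 1L
      return()
    }
    info <- plan[[i]]
    pts <- tryCatch(loopBP:::vertex_candidates(info, coords, config),
                    error = function(e) matrix(numeric(0), 0L, 3L))
    if (info$type == "exact" && length(info$refine_j) > 0L && nrow(pts) > 0L)
      pts <- loopBP:::refine_candidates(pts, attr(pts, "label"), info,
                                        coords, config$tol, reject = FALSE)
    for (r in seq_len(nrow(pts))) {
      coords[i, ] <<- pts[r, ]
      recurse(i + 1L)
    }
    coords[i, ] <<- NA_real_
  }
  recurse(4L)
  n_sol
}
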