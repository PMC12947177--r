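test_that("exact-distance limit recovers the generating conformation", {
  inst <- fabricate_instance(loop_spec(6, seed = 3),
                             intervals = interval_spec(0, seed = 1))
  sols <- bp_solve(inst, bp_config(K = 10))
  expect_gte(length(sols$solutions), 1L)
  expect_lt(min(sols$rmsd), 1e-6)
  expect_lt(max(sols$max_err), 1e-6)
})

test_that("branching candidates respect the two-point and 2K contracts", {
  inst <- fabricate_instance(loop_spec(6, seed = 3),
                             intervals = interval_spec(1.0, seed = 1))
  keys <- inst$order$vertices$key
  ref <- inst$reference_coords[keys, ]
  coords <- ref
  # over-determined vertex C:6 (4+ exact predecessors): at most one point
  got <- place_exact(which(keys == "C:6"), coords, inst, bp_config(K = 10))
  expect_lte(length(got), 1L)
  expect_equal(got[[1L]], unname(ref["C:6", ]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # three-predecessor hydrogen HA:6: at most two mirror candidates
  got <- place_exact(which(keys == "HA:6"), coords, inst, bp_config(K = 10))
  expect_lte(length(got), 2L)
  expect_lt(min(vapply(got, function(p) sqrt(sum((p - ref["HA:6", ])^2)),
                       numeric(1L))), 1e-6)
  # the interval vertex yields at most 2K candidates, all inside [lo, hi]
  K <- 40L
  iv <- place_interval(which(keys == "HA:5"), coords, inst, bp_config(K = K))
  expect_lte(length(iv), 2L * K)
  de <- inst$edges[inst$edges$klass == "*" & inst$edges$role == "discretization", ]
  dH <- vapply(iv, function(p) sqrt(sum((p - ref["H:6", ])^2)), numeric(1L))
  expect_true(all(dH >= de$lo - 1e-9 & dH <= de$hi + 1e-9))
  # K = 2 samples only the interval endpoints (an endpoint outside the
  # radius range realizable on the two-sphere circle yields no candidate)
  iv2 <- place_interval(which(keys == "HA:5"), coords, inst, bp_config(K = 2))
  expect_gte(length(iv2), 1L)
  dH2 <- vapply(iv2, function(p) sqrt(sum((p - ref["H:6", ])^2)), numeric(1L))
  expect_true(all(abs(dH2 - de$lo) < 1e-6 | abs(dH2 - de$hi) < 1e-6))
  # delta = 0 collapses the interval vertex to the exact two-candidate case
  inst0 <- fabricate_instance(loop_spec(6, seed = 3),
                              intervals = interval_spec(0, seed = 1))
  iv0 <- place_interval(which(keys == "HA:5"), coords, inst0, bp_config(K = 10))
  expect_lte(length(iv0), 2L)
})

test_that("prune decisions equal a brute-force scan over incident edges", {
  inst <- fabricate_instance(loop_spec(6, seed = 6),
                             intervals = interval_spec(0.5, seed = 6))
  keys <- inst$order$vertices$key
  ref <- inst$reference_coords[keys, ]
  cfg <- bp_config(K = 10)
  plan <- loopBP:::solver_plan(inst, cfg)
  set.seed(31)
  for (rep in 1:50) {
    i <- sample(seq.int(4L, length(keys)), 1L)
    cand <- ref[i, ] + stats::rnorm(3L, 0, 0.3)
    coords <- ref
    coords[seq.int(i, nrow(coords)), ] <- NA_real_
    got <- prune(cand, i, coords, inst, cfg)
    info <- plan[[i]]
    want <- TRUE
    for (k in seq_along(info$prune_j)) {
      j <- info$prune_j[k]
      if (any(is.na(coords[j, ]))) next
      d <- sqrt(sum((cand - coords[j, ])^2))
      want <- want && d >= info$prune_lo[k] - cfg$tol &&
        d <= info$prune_hi[k] + cfg$tol
    }
    expect_identical(got, want)
  }
})

test_that("constructed infeasibility yields zero solutions and backtracks", {
  inst <- fabricate_instance(loop_spec(6, seed = 3),
                             intervals = interval_spec(0, seed = 1))
  # make one pruning edge unsatisfiable: every branch reaching its later
  # endpoint is rejected, so the search backtracks to exhaustion
  bad <- inst
  k2 <- which(bad$edges$role == "pruning" & bad$edges$klass == "*")[1L]
  bad$edges$lo[k2] <- 50
  bad$edges$hi[k2] <- 50
  sols <- bp_solve(bad, bp_config(K = 10))
  expect_equal(length(sols$solutions), 0L)
  expect_gte(sols$pruned, 1L)
})

test_that("max_err measures the worst residual exactly", {
  inst <- fabricate_instance(loop_spec(6, seed = 3),
                             intervals = interval_spec(0, seed = 1))
  keys <- inst$order$vertices$key
  ref <- inst$reference_coords[keys, ]
  expect_equal(compute_max_err(ref, inst), 0, tolerance = 1e-9)
  # moving one terminal hydrogen by 0.5 A along one of its edge directions
  # forces max_err = 0.5
  pert <- ref
  i <- which(keys == "H:2")
  ed <- inst$edges
  j <- ed$i[ed$j == i][1L]
  dir <- (pert[i, ] - pert[j, ])
  dir <- dir / sqrt(sum(dir^2))
  pert[i, ] <- pert[i, ] + 0.5 * dir
  expect_equal(compute_max_err(pert, inst), 0.5, tolerance = 1e-6)
})

test_that("enumeration is deterministic and signatures are unique", {
  inst <- fabricate_instance(loop_spec(6, seed = 10),
                             intervals = interval_spec(0.5, seed = 10))
  s1 <- bp_solve(inst, bp_config(K = 200))
  s2 <- bp_solve(inst, bp_config(K = 200))
  expect_identical(s1$signatures, s2$signatures)
  expect_identical(s1$solutions, s2$solutions)
  expect_equal(anyDuplicated(s1$signatures), 0L)
  # every solution satisfies every constraint within tolerance
  expect_true(all(s1$max_err <= s1$tol))
})

test_that("a ground-truth-consistent pruning edge never removes the recovery", {
  inst <- fabricate_instance(loop_spec(6, seed = 5),
                             intervals = interval_spec(0.5, seed = 5))
  cfg <- bp_config(K = 200)
  base <- bp_solve(inst, cfg)
  expect_gte(length(base$solutions), 1L)
  keys <- inst$order$vertices$key
  ref <- inst$reference_coords[keys, ]
  # add a true-distance pruning edge between two unconstrained vertices
  aug <- inst
  pick <- c(which(keys == "HA:6"), which(keys == "HA:2"))
  d <- sqrt(sum((ref[pick[1L], ] - ref[pick[2L], ])^2))
  aug$edges <- rbind(aug$edges,
                     data.frame(i = min(pick), j = max(pick), lo = d, hi = d,
                                klass = "*", role = "pruning"))
  withaug <- bp_solve(aug, cfg)
  expect_lte(length(withaug$solutions), length(base$solutions))
  expect_lte(min(withaug$rmsd), min(base$rmsd) + 1e-9)
})

test_that("every H-order solution projects onto an Hbar-order solution", {
  # the reduced order's constraint set restricted to its vertices is a
  # subset of the full order's, so on the same sample grid the backbone
  # (plus retained hydrogens) of every H solution must reappear among the
  # Hbar solutions: hydrogen restraints never admit a backbone the reduced
  # order forbids
  for (seed in c(2L, 5L, 10L)) {
    co <- generate_loop(loop_spec(6, seed = seed))
    cmp <- compare_orders(co, 6, spec = interval_spec(0.5, seed = seed),
                          config = bp_config(K = 200))
    if (cmp$n_H == 0L) next
    hbar_keys <- cmp$Hbar$solutions[[1L]]
    hbar_keys <- rownames(hbar_keys)
    canon <- function(cc) paste(round(cc[hbar_keys, ], 4L), collapse = ",")
    hbar_set <- vapply(cmp$Hbar$solutions, canon, character(1L))
    proj <- unique(vapply(cmp$H$solutions, canon, character(1L)))
    expect_true(all(proj %in% hbar_set))
    expect_lte(length(proj), cmp$n_Hbar)
  }
})

test_that("solution cap truncates the enumeration and says so", {
  inst <- fabricate_instance(loop_spec(6, seed = 10),
                             intervals = interval_spec(1.0, seed = 10))
  s <- bp_solve(inst, bp_config(K = 200, max_solutions = 2L))
  expect_lte(length(s$solutions), 2L)
  expect_true(s$truncated)
})
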