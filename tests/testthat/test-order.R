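test_that("H-order census and validity across loop sizes", {
  for (n in c(4L, 6L, 8L, 12L)) {
    ord <- build_h_order(n)
    expect_equal(nrow(ord$vertices), 5L * n - 1L)
    # one HA per residue, one amide H per residue except the first
    expect_equal(sum(ord$vertices$name == "HA"), n)
    expect_equal(sum(ord$vertices$name == "H"), n - 1L)
    # every vertex from the fourth has >= 3 predecessors, indices increasing
    for (i in seq.int(4L, nrow(ord$vertices))) {
      pr <- ord$preds[[i]]
      expect_gte(nrow(pr), 3L)
      expect_true(all(pr$j < i))
      expect_false(is.unsorted(pr$j, strictly = TRUE))
    }
    # assembled instances pass the order validation (long sampled loops can
    # carry steric-clash warnings; irrelevant to order validity)
    inst <- suppressWarnings(
      fabricate_instance(loop_spec(n, seed = 5),
                         intervals = interval_spec(0.5, seed = 5)))
    expect_equal(nrow(validate_order(inst)), 0L)
  }
})

test_that("exactly one interval edge discretizes; the rest prune", {
  inst <- fabricate_instance(loop_spec(6, seed = 2),
                             intervals = interval_spec(1.0, seed = 2))
  star_disc <- inst$edges[inst$edges$klass == "*" &
                            inst$edges$role == "discretization", ]
  expect_equal(nrow(star_disc), 1L)
  keys <- inst$order$vertices$key
  expect_setequal(keys[c(star_disc$i, star_disc$j)], c("H:6", "HA:5"))
  expect_true(all(inst$edges$klass[inst$edges$role == "pruning" &
                                     inst$edges$klass == "*"] == "*"))
})

test_that("reduced order drops all hydrogens but the discretizing pair", {
  h <- build_h_order(6, c(1L, 3L, 5L))
  hbar <- build_hbar_order(h)
  expect_equal(nrow(hbar$vertices), 20L)
  kept_h <- hbar$vertices$key[loopBP:::is_hydrogen(hbar$vertices$key)]
  expect_setequal(kept_h, c("H:6", "HA:5"))
  # idempotent
  expect_identical(build_hbar_order(hbar), hbar)
  # predecessor sets survive as atom sets
  key_preds <- function(ord, key) {
    i <- ord$vertices$idx[ord$vertices$key == key]
    ord$vertices$key[ord$preds[[i]]$j]
  }
  for (k in c("N:5", "H:6", "HA:5"))
    expect_identical(key_preds(hbar, k), key_preds(h, k))
})

test_that("anchor layouts outside the supported family are rejected", {
  expect_error(build_h_order(6, c(2L, 4L, 5L)), "anchor layout")
  expect_error(build_h_order(6, c(1L, 3L, 6L)), "anchor layout")
  expect_error(build_h_order(3, c(1L, 2L, 3L)), "anchor layout")
  expect_equal(default_anchors(4L), c(1L, 2L, 3L))
  expect_equal(default_anchors(6L), c(1L, 3L, 5L))
  expect_equal(default_anchors(12L), c(1L, 4L, 7L))
})

test_that("rigid-body distances come from the right source and class", {
  geo <- default_geometry()
  bodies <- rigid_bodies(6L, c(1L, 3L, 5L))
  co <- generate_loop(loop_spec(6, seed = 9))
  # 1-bond pair from the table
  d <- rigid_body_distance("N:2", "H:2", geo, bodies)
  expect_equal(as.numeric(d), geo$bonds[["N-H"]])
  expect_equal(attr(d, "class_edge"), "b")
  # HA within two bonds of CA's neighbors
  d <- rigid_body_distance("CA:5", "HA:5", geo, bodies)
  expect_equal(attr(d, "class_edge"), "b")
  # intra-body pair requires reference coordinates, then matches them
  expect_error(rigid_body_distance("CA:1", "CA:3", geo, bodies),
               "missing-geometry-entry")
  d <- rigid_body_distance("CA:1", "CA:3", geo, bodies, ref_coords = co)
  expect_equal(as.numeric(d), sqrt(sum((co["CA:1", ] - co["CA:3", ])^2)))
  expect_equal(attr(d, "class_edge"), "r")
  # no a priori distance across bodies
  expect_null(rigid_body_distance("C:1", "C:4", geo, bodies, ref_coords = co))
})

test_that("deleting a predecessor edge is flagged by validation", {
  inst <- fabricate_instance(loop_spec(6, seed = 2),
                             intervals = interval_spec(0.5, seed = 2))
  expect_equal(nrow(validate_order(inst)), 0L)
  # drop the interval discretization edge {H:6, HA:5} = {9, 10}
  broken <- inst
  broken$edges <- broken$edges[!(broken$edges$i == 9L & broken$edges$j == 10L), ]
  v <- validate_order(broken)
  expect_true(10L %in% v$vertex)
})
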