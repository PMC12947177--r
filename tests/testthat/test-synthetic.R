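test_that("generated loops are deterministic and ideal-geometry exact", {
  geo <- default_geometry()
  co1 <- generate_loop(loop_spec(6, seed = 0), geo)
  co2 <- generate_loop(loop_spec(6, seed = 0), geo)
  expect_identical(unclass(co1), unclass(co2))
  # bond lengths match the table to 1e-6
  for (i in 1:6) {
    expect_equal(sqrt(sum((co1[paste0("N:", i), ] - co1[paste0("CA:", i), ])^2)),
                 geo$bonds[["N-CA"]], tolerance = 1e-6)
    expect_equal(sqrt(sum((co1[paste0("CA:", i), ] - co1[paste0("C:", i), ])^2)),
                 geo$bonds[["CA-C"]], tolerance = 1e-6)
    if (i < 6)
      expect_equal(sqrt(sum((co1[paste0("C:", i), ] - co1[paste0("N:", i + 1L), ])^2)),
                   geo$bonds[["C-N"]], tolerance = 1e-6)
  }
  # trans peptide planes are exactly planar: CA-C-N-CA dihedral = 180
  for (i in 2:6) {
    om <- loopBP:::dihedral_angle(co1[paste0("CA:", i - 1L), ],
                                  co1[paste0("C:", i - 1L), ],
                                  co1[paste0("N:", i), ],
                                  co1[paste0("CA:", i), ])
    expect_equal(abs(om), 180, tolerance = 1e-6)
  }
})

test_that("prescribed torsions are realized exactly", {
  phi <- c(0, -60, -120, 50, -70, -100)
  psi <- c(-40, 130, -30, 60, 140, 0)
  co <- generate_loop(loop_spec(6, phi = phi, psi = psi, seed = 1))
  for (i in 2:6) {
    got_phi <- loopBP:::dihedral_angle(co[paste0("C:", i - 1L), ],
                                       co[paste0("N:", i), ],
                                       co[paste0("CA:", i), ],
                                       co[paste0("C:", i), ])
    expect_equal(got_phi, phi[i], tolerance = 1e-6)
  }
  for (i in 1:5) {
    got_psi <- loopBP:::dihedral_angle(co[paste0("N:", i), ],
                                       co[paste0("CA:", i), ],
                                       co[paste0("C:", i), ],
                                       co[paste0("N:", i + 1L), ])
    expect_equal(got_psi, psi[i], tolerance = 1e-6)
  }
})

test_that("table distances agree with measured coordinates", {
  geo <- default_geometry()
  co <- generate_loop(loop_spec(6, seed = 21), geo)
  bodies <- rigid_bodies(6L, c(1L, 3L, 5L))
  graph <- loopBP:::covalent_graph(6L)
  # every bonded/2-bond backbone pair: table value == measured value
  keys <- rownames(co)
  for (a in keys) for (b in keys) {
    if (a >= b) next
    if (loopBP:::bond_separation(graph, a, b) > 2L) next
    ideal <- loopBP:::ideal_bond_pair_distance(geo, graph, a, b)
    expect_equal(sqrt(sum((co[a, ] - co[b, ])^2)), ideal, tolerance = 1e-6,
                 label = paste(a, b))
  }
})

test_that("fabricated instances are feasible for their own ground truth", {
  for (kind in c("H", "Hbar")) {
    inst <- fabricate_instance(loop_spec(6, seed = 14), order_kind = kind,
                               intervals = interval_spec(1.5, seed = 14))
    keys <- inst$order$vertices$key
    expect_equal(compute_max_err(inst$reference_coords[keys, ], inst), 0,
                 tolerance = 1e-9)
    expect_equal(nrow(validate_order(inst)), 0L)
  }
})

test_that("steric clashes are reported but not fatal", {
  # a torsion set that folds the chain back onto itself
  co <- suppressWarnings(generate_loop(
    loop_spec(6, phi = rep(0, 6), psi = rep(0, 6), seed = 1)))
  expect_warning(generate_loop(loop_spec(6, phi = rep(0, 6), psi = rep(0, 6),
                                         seed = 1)), "clash")
  expect_gte(nrow(attr(co, "clashes")), 1L)
})
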