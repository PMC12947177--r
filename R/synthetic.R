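# Synthetic loop fixtures: geometrically exact backbones built from internal
# coordinates (standard bond lengths/angles, planar trans peptides), with
# hydrogens placed by the same rules the reconstruction module uses.  Every
# module of the package is testable against these loops, with the generating
# coordinates as ground truth.

#' Synthetic loop specification
#'
#' @param n_residues loop length (>= 4).
#' @param phi,psi backbone torsions in degrees: numeric vectors of length
#'   `n_residues` (phi of residue 1 and psi of residue n are unused), or
#'   `"sample"` to draw them from a coarse two-basin Ramachandran-like prior
#'   (alpha basin at (-63, -43), beta basin at (-120, 135), sd 15 degrees,
#'   equal weights) using `seed`.
#' @param omega peptide torsion in degrees (default 180, trans).
#' @param anchors anchor residues (default [default_anchors()]).
#' @param seed integer seed for torsion sampling.
#' @return an object of class `loop_spec`.
#' @export
loop_spec <- function(n_residues, phi = "sample", psi = "sample",
                      omega = 180, anchors = default_anchors(n_residues),
                      seed = 1L) {
  n <- as.integer(n_residues)
  check_anchor_layout(n, anchors)
  if (!identical(phi, "sample"))
    stopifnot(is.numeric(phi), length(phi) == n)
  if (!identical(psi, "sample"))
    stopifnot(is.numeric(psi), length(psi) == n)
  structure(list(n_residues = n, phi = phi, psi = psi, omega = omega,
                 anchors = as.integer(anchors), seed = as.integer(seed)),
            class = "loop_spec")
}

sample_torsions <- function(n, seed) {
  set.seed(seed)
  basin <- sample(c("alpha", "beta"), n, replace = TRUE)
  centers <- list(alpha = c(-63, -43), beta = c(-120, 135))
  phi <- vapply(basin, function(b) stats::rnorm(1L, centers[[b]][1L], 15),
                numeric(1L))
  psi <- vapply(basin, function(b) stats::rnorm(1L, centers[[b]][2L], 15),
                numeric(1L))
  list(phi = unname(phi), psi = unname(psi))
}

#' Generate an ideal-geometry loop backbone with hydrogens
#'
#' Sequential internal-coordinate construction: residue i's N, CA, C are
#' placed from bond lengths, bond angles and the torsions (psi[i-1],
#' omega, phi[i]); amide and alpha hydrogens are then placed by the exact
#' rules of [place_amide_h()] and [place_alpha_h()] (virtual CB), so a
#' strip-and-replace round trip reproduces them to machine precision.
#'
#' @param spec a [loop_spec()].
#' @param geometry a [default_geometry()] table.
#' @return coordinate matrix (rows named by atom key) with attribute
#'   `torsions` (the phi/psi actually used) and `clashes` (data.frame of
#'   nonbonded pairs closer than 1.5 Angstrom, reported with a warning).
#' @export
generate_loop <- function(spec, geometry = default_geometry()) {
  stopifnot(inherits(spec, "loop_spec"))
  n <- spec$n_residues
  if (identical(spec$phi, "sample") || identical(spec$psi, "sample")) {
    tor <- sample_torsions(n, spec$seed)
    phi <- if (identical(spec$phi, "sample")) tor$phi else spec$phi
    psi <- if (identical(spec$psi, "sample")) tor$psi else spec$psi
  } else {
    phi <- spec$phi; psi <- spec$psi
  }
  b <- geometry$bonds; a <- geometry$angles
  coords <- matrix(NA_real_, 0L, 3L)
  put <- function(key, p) coords <<- rbind(coords,
                                           matrix(p, 1L, 3L,
                                                  dimnames = list(key)))
  # residue 1 in a canonical frame
  put("N:1", c(0, 0, 0))
  put("CA:1", c(b[["N-CA"]], 0, 0))
  th <- a[["N-CA-C"]] * pi / 180
  put("C:1", coords["CA:1", ] + b[["CA-C"]] * c(-cos(th), sin(th), 0))
  for (i in seq.int(2L, n)) {
    put(atom_key("N", i),
        place_dihedral(coords[atom_key("N", i - 1L), ],
                       coords[atom_key("CA", i - 1L), ],
                       coords[atom_key("C", i - 1L), ],
                       b[["C-N"]], a[["CA-C-N"]], psi[i - 1L]))
    put(atom_key("CA", i),
        place_dihedral(coords[atom_key("CA", i - 1L), ],
                       coords[atom_key("C", i - 1L), ],
                       coords[atom_key("N", i), ],
                       b[["N-CA"]], a[["C-N-CA"]], spec$omega))
    put(atom_key("C", i),
        place_dihedral(coords[atom_key("C", i - 1L), ],
                       coords[atom_key("N", i), ],
                       coords[atom_key("CA", i), ],
                       b[["CA-C"]], a[["N-CA-C"]], phi[i]))
  }
  coords <- add_missing_hydrogens(coords, geometry, tol = 1e-6)
  placements <- attr(coords, "placements")
  # clash scan over nonbonded pairs
  graph <- covalent_graph(n)
  dd <- as.matrix(stats::dist(coords))
  close <- which(upper.tri(dd) & dd < 1.5, arr.ind = TRUE)
  keys <- rownames(coords)
  clashes <- data.frame(a = character(0), b = character(0), d = numeric(0))
  if (nrow(close) > 0L) {
    for (k in seq_len(nrow(close))) {
      ka <- keys[close[k, 1L]]; kb <- keys[close[k, 2L]]
      if (bond_separation(graph, ka, kb) > 2L)
        clashes <- rbind(clashes, data.frame(a = ka, b = kb,
                                             d = dd[close[k, 1L],
                                                    close[k, 2L]]))
    }
    if (nrow(clashes) > 0L)
      warning("clash: ", nrow(clashes),
              " nonbonded pair(s) closer than 1.5 A")
  }
  structure(coords, torsions = list(phi = phi, psi = psi),
            placements = placements, clashes = clashes)
}

#' Build a complete synthetic DDGP instance with ground truth attached
#'
#' End to end: generate the loop, build the requested vertex order, assemble
#' the weighted graph with randomized intervals.  The generating coordinates
#' are stored as the reference embedding, so the instance always admits at
#' least one solution (its own ground truth) and recovery can be scored.
#'
#' @param spec a [loop_spec()].
#' @param order_kind `"H"` (all backbone hydrogens) or `"Hbar"` (only the
#'   two hydrogens of the discretization edge).
#' @param intervals an [interval_spec()] (its seed drives the tau draws;
#'   `spec$seed` drives the torsion draws).
#' @param geometry a [default_geometry()] table.
#' @return a `ddgp_instance` with `reference_coords` set.
#' @export
fabricate_instance <- function(spec, order_kind = c("H", "Hbar"),
                               intervals = interval_spec(),
                               geometry = default_geometry()) {
  order_kind <- match.arg(order_kind)
  coords <- generate_loop(spec, geometry)
  ord <- build_h_order(spec$n_residues, spec$anchors)
  if (order_kind == "Hbar") ord <- build_hbar_order(ord)
  assemble_instance(coords, ord, intervals, geometry)
}
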