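# Ideal backbone geometry: bond lengths/angles, internal-coordinate atom
# placement (NeRF), and the derived sphere radii used to reconstruct the
# backbone amide (H) and alpha (HA) hydrogens by sphere intersection.

#' Place an atom from internal coordinates
#'
#' Natural extension of reference frame (NeRF) placement: given positions of
#' the chain `a - b - c`, returns the point `d` with `|c - d| = bond`,
#' `angle(b, c, d) = angle` and `dihedral(a, b, c, d) = dihedral`.
#'
#' @param a,b,c numeric length-3 positions.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param dihedral torsion angle in degrees.
#' @return numeric length-3 position.
#' @export
place_dihedral <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  nv <- vcross(ab, bc)
  nv <- nv / vnorm(nv)
  m <- vcross(nv, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * nv
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Standard backbone geometry table
#'
#' Bond lengths and angles for the peptide backbone (standard values used
#' throughout protein model building: N-CA 1.458, CA-C 1.525, C-N 1.329,
#' N-H 1.010, CA-HA 1.090 Angstrom; N-CA-C 111.0, CA-C-N 116.2,
#' C-N-CA 121.7 degrees; trans peptide, omega = 180), plus the derived
#' sphere radii from each backbone hydrogen to its four reconstruction
#' centers.  The amide hydrogen lies in the peptide plane with the two
#' in-plane angles at N split evenly; HA and CB sit at the two remaining
#' tetrahedral directions of CA (L-configuration: CB on the
#' `(N-CA) x (C-CA)` side).
#'
#' All radii are computed from one ideal local frame, so hydrogens placed by
#' the generator are reproduced exactly by the reconstruction routines.
#'
#' @param nca,cac,cn,nh,caha,cacb bond lengths in Angstrom.
#' @param ncac,cacn,cnca backbone bond angles in degrees.
#' @param h_target target angle (degrees) between each of HA/CB and the N and
#'   C substituents of CA (tetrahedral, 109.47).
#' @return an object of class `geometry_table`.
#' @export
default_geometry <- function(nca = 1.458, cac = 1.525, cn = 1.329,
                             nh = 1.010, caha = 1.090, cacb = 1.530,
                             ncac = 111.0, cacn = 116.2, cnca = 121.7,
                             h_target = 109.47) {
  stopifnot(all(c(nca, cac, cn, nh, caha, cacb) > 0.5),
            all(c(nca, cac, cn, nh, caha, cacb) < 4.0),
            all(c(ncac, cacn, cnca, h_target) > 0),
            all(c(ncac, cacn, cnca, h_target) < 180))
  cnh <- (360 - cnca) / 2   # in-plane C-N-H == H-N-CA, planar amide N

  # ideal peptide unit: CA(i-1), C(i-1), N(i), CA(i), H(i) all in one plane
  ca_prev <- c(0, 0, 0)
  c_prev <- c(cac, 0, 0)
  th <- (180 - cacn) * pi / 180
  n_at <- c_prev + cn * c(cos(th), sin(th), 0)
  ca_at <- place_dihedral(ca_prev, c_prev, n_at, nca, cnca, 180)
  h_at <- place_dihedral(ca_prev, c_prev, n_at, nh, cnh, 0)
  amide_radii <- c(CA_prev = vnorm(h_at - ca_prev),
                   C_prev = vnorm(h_at - c_prev),
                   N = nh,
                   CA = vnorm(h_at - ca_at))

  # ideal CA frame: HA/CB at the remaining tetrahedral directions
  # cos(eta) chosen so angle(HA, N) == angle(HA, C) == h_target
  ceta <- -cos(h_target * pi / 180) / cos(ncac / 2 * pi / 180)
  eta <- acos(ceta)
  nloc <- c(nca, 0, 0)
  cloc <- cac * c(cos(ncac * pi / 180), sin(ncac * pi / 180), 0)
  e1 <- (nloc / nca + cloc / cac)
  e1 <- e1 / vnorm(e1)
  e3 <- vcross(nloc / nca, cloc / cac)
  e3 <- e3 / vnorm(e3)
  ha_loc <- caha * (-cos(eta) * e1 - sin(eta) * e3)  # L: HA opposite CB
  cb_loc <- cacb * (-cos(eta) * e1 + sin(eta) * e3)
  alpha_radii <- c(N = vnorm(ha_loc - nloc),
                   CA = caha,
                   C = vnorm(ha_loc - cloc),
                   CB = vnorm(ha_loc - cb_loc))

  structure(list(
    bonds = c(`N-CA` = nca, `CA-C` = cac, `C-N` = cn,
              `N-H` = nh, `CA-HA` = caha, `CA-CB` = cacb),
    angles = c(`N-CA-C` = ncac, `CA-C-N` = cacn, `C-N-CA` = cnca,
               `C-N-H` = cnh, `H-N-CA` = cnh, omega = 180),
    eta = eta * 180 / pi,
    amide_radii = amide_radii,
    alpha_radii = alpha_radii
  ), class = "geometry_table")
}

#' @export
print.geometry_table <- function(x, ...) {
  cat("Backbone geometry table\n")
  cat("  bonds (A): ", paste(names(x$bonds), format(x$bonds), sep = "=",
                             collapse = ", "), "\n")
  cat("  angles (deg):", paste(names(x$angles), format(x$angles), sep = "=",
                               collapse = ", "), "\n")
  cat("  amide H radii:", paste(names(x$amide_radii),
                                format(round(x$amide_radii, 4)),
                                sep = "=", collapse = ", "), "\n")
  cat("  alpha H radii:", paste(names(x$alpha_radii),
                                format(round(x$alpha_radii, 4)),
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Ideal distance between two backbone atoms separated by <= 2 covalent
# bonds, from the geometry table (law of cosines through the shared atom).
# `path` is the covalent path as a character vector of length 2 or 3 of
# generic atom names (N, CA, C, H, HA, CB), consecutive entries bonded.
ideal_path_distance <- function(geometry, path) {
  bond_of <- function(a, b) {
    key <- paste(a, b, sep = "-")
    alt <- paste(b, a, sep = "-")
    bl <- geometry$bonds[key]
    if (is.na(bl)) bl <- geometry$bonds[alt]
    if (is.na(bl)) stop("missing-geometry-entry: no bond ", key)
    unname(bl)
  }
  if (length(path) == 2L) return(bond_of(path[1L], path[2L]))
  if (length(path) != 3L) stop("path must have 2 or 3 atoms")
  b1 <- bond_of(path[1L], path[2L])
  b2 <- bond_of(path[2L], path[3L])
  key <- paste(path, collapse = "-")
  alt <- paste(rev(path), collapse = "-")
  ang <- geometry$angles[key]
  if (is.na(ang)) ang <- geometry$angles[alt]
  if (is.na(ang)) {
    # angles at CA involving HA/CB default to the tetrahedral target used
    # in the table construction
    if (path[2L] == "CA") ang <- 109.47 else
      stop("missing-geometry-entry: no angle ", key)
  }
  unname(sqrt(b1^2 + b2^2 - 2 * b1 * b2 * cos(ang * pi / 180)))
}
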