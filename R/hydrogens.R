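# Reconstruction of backbone hydrogens missing from experimental structures.
#
# The amide hydrogen H(i) lies in the peptide plane spanned by CA(i-1),
# C(i-1), N(i), CA(i); its distances to those four atoms are fixed by ideal
# geometry, so it is recovered by sphere intersection.  Because the four
# centers are themselves coplanar, the four-sphere linear system is rank
# deficient off-plane; the placement is therefore solved in-plane (the only
# place a solution exists) and the four-sphere residuals are kept as a
# check.  The alpha hydrogen HA(i) is the generic four-sphere case with
# centers N, CA, C and CB; without a CB (glycine, or backbone-only input) a
# virtual CB at the ideal tetrahedral direction stands in.

#' Place an amide hydrogen in its peptide plane
#'
#' @param c_alpha_prev,c_prev,n,c_alpha positions (numeric length-3) of
#'   CA(i-1), C(i-1), N(i), CA(i).
#' @param geometry a [default_geometry()] table.
#' @param tol maximum acceptable sphere residual in Angstrom (default 1e-3;
#'   real crystal structures deviate from ideal geometry, so residuals up to
#'   ~tol are expected and reported rather than fatal below `tol`).
#' @return position of H(i) with attribute `residuals` (distances to the
#'   four centers minus the table radii, absolute).
#' @export
place_amide_h <- function(c_alpha_prev, c_prev, n, c_alpha, geometry,
                          tol = 1e-3) {
  r <- geometry$amide_radii
  fr <- tryCatch(trilat_frame(c_alpha_prev, c_prev, n),
                 error = function(e) NULL)
  if (is.null(fr))
    stop("degenerate-plane: peptide-plane centers are collinear or collapsed")
  x <- (r[["CA_prev"]]^2 - r[["C_prev"]]^2 + fr$d^2) / (2 * fr$d)
  y <- (r[["CA_prev"]]^2 - r[["N"]]^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) /
    (2 * fr$j)
  h <- c_alpha_prev + x * fr$ex + y * fr$ey   # in-plane by construction
  centers <- rbind(c_alpha_prev, c_prev, n, c_alpha)
  res <- abs(sqrt(rowSums((centers - matrix(h, 4L, 3L, byrow = TRUE))^2)) -
               c(r[["CA_prev"]], r[["C_prev"]], r[["N"]], r[["CA"]]))
  if (max(res) > tol)
    stop(sprintf("inconsistent-radii: amide H residual %.2g exceeds tol %.2g",
                 max(res), tol))
  structure(h, residuals = unname(res))
}

#' Place an alpha hydrogen by four-sphere intersection
#'
#' @param n,c_alpha,c positions of the residue's N, CA and C.
#' @param c_beta position of CB, or `NULL` to use a virtual CB at the ideal
#'   tetrahedral direction (glycine / backbone-only input).
#' @param geometry a [default_geometry()] table.
#' @param tol maximum acceptable sphere residual in Angstrom.
#' @return position of HA with attributes `residuals` and `virtual_cb`.
#' @export
place_alpha_h <- function(n, c_alpha, c, c_beta = NULL, geometry,
                          tol = 1e-3) {
  r <- geometry$alpha_radii
  virtual <- is.null(c_beta)
  if (virtual) c_beta <- virtual_cbeta(n, c_alpha, c, geometry)
  p <- four_sphere_point(sphere(n, r[["N"]]), sphere(c_alpha, r[["CA"]]),
                         sphere(c, r[["C"]]), sphere(c_beta, r[["CB"]]),
                         eps = tol)
  structure(as.numeric(p), residuals = attr(p, "residuals"),
            virtual_cb = virtual)
}

# Ideal CB direction for an L-residue (CB on the (N-CA) x (C-CA) side).
virtual_cbeta <- function(n, c_alpha, c, geometry) {
  un <- (n - c_alpha); un <- un / vnorm(un)
  uc <- (c - c_alpha); uc <- uc / vnorm(uc)
  e1 <- un + uc; e1 <- e1 / vnorm(e1)
  e3 <- vcross(un, uc); e3 <- e3 / vnorm(e3)
  eta <- geometry$eta * pi / 180
  c_alpha + geometry$bonds[["CA-CB"]] * (-cos(eta) * e1 + sin(eta) * e3)
}

#' Add missing backbone hydrogens to a loop coordinate set
#'
#' Walks the loop residues, reconstructing every amide hydrogen H (residues
#' 2..n) and alpha hydrogen HA (all residues) that is absent.  Atoms already
#' present are left untouched.
#'
#' @param coords coordinate matrix with rows named by atom key (`"N:1"`,
#'   `"CA:2"`, ...); backbone N/CA/C required for every residue.
#' @param geometry a [default_geometry()] table.
#' @param tol residual tolerance passed to the placement routines.
#' @return `coords` with hydrogens added, plus attribute `placements`: a
#'   data.frame with one row per placed atom (key, max residual, whether a
#'   virtual CB was used).
#' @export
add_missing_hydrogens <- function(coords, geometry = default_geometry(),
                                  tol = 1e-3) {
  res_ids <- sort(unique(key_res(rownames(coords))))
  n <- max(res_ids)
  for (i in seq_len(n))
    for (nm in c("N", "CA", "C"))
      if (!(atom_key(nm, i) %in% rownames(coords)))
        stop("missing-atom: backbone atom ", atom_key(nm, i),
             " required to place hydrogens")
  placed <- data.frame(key = character(0), residual = numeric(0),
                       virtual_cb = logical(0))
  at <- function(key) coords[key, ]
  for (i in seq_len(n)) {
    hk <- atom_key("H", i)
    if (i >= 2L && !(hk %in% rownames(coords))) {
      h <- place_amide_h(at(atom_key("CA", i - 1L)), at(atom_key("C", i - 1L)),
                         at(atom_key("N", i)), at(atom_key("CA", i)),
                         geometry, tol)
      coords <- rbind(coords, matrix(h, 1L, 3L, dimnames = list(hk)))
      placed <- rbind(placed, data.frame(key = hk,
                                         residual = max(attr(h, "residuals")),
                                         virtual_cb = FALSE))
    }
    hak <- atom_key("HA", i)
    if (!(hak %in% rownames(coords))) {
      cbk <- atom_key("CB", i)
      cb <- if (cbk %in% rownames(coords)) at(cbk) else NULL
      ha <- place_alpha_h(at(atom_key("N", i)), at(atom_key("CA", i)),
                          at(atom_key("C", i)), cb, geometry, tol)
      coords <- rbind(coords, matrix(ha, 1L, 3L, dimnames = list(hak)))
      placed <- rbind(placed, data.frame(key = hak,
                                         residual = max(attr(ha, "residuals")),
                                         virtual_cb = attr(ha, "virtual_cb")))
    }
  }
  structure(coords, placements = placed)
}
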