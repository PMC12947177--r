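# PDB input/output: extract an anchored loop from a coordinate file, and
# write solution ensembles as multi-model PDB.

#' Read a loop's atoms from a PDB file
#'
#' Extracts backbone atoms (N, CA, C, plus CB and any backbone hydrogens
#' already present) for `n_residues` consecutive residues starting at
#' `start_res` of one chain, and maps them to loop-local atom keys
#' (`"N:1"` ... ).  Alternate locations beyond the first are ignored.
#'
#' @param path PDB file path.
#' @param chain chain identifier (one letter).
#' @param start_res author residue number of the loop's first residue.
#' @param n_residues loop length.
#' @return coordinate matrix (rows named by loop-local atom key) with
#'   attributes `resno_map` (loop-local index -> author residue number) and
#'   `missing_h` (keys of amide/alpha hydrogens not present in the file).
#' @export
read_pdb_loop <- function(path, chain, start_res, n_residues) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("missing-residue: chain ", chain, " not found in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  wanted <- c(N = "N", CA = "CA", C = "C", CB = "CB", H = "H", HA = "HA")
  coords <- matrix(NA_real_, 0L, 3L)
  resnos <- seq.int(start_res, start_res + n_residues - 1L)
  for (i in seq_len(n_residues)) {
    rows <- at[at$resno == resnos[i], , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("missing-residue: residue ", resnos[i], " chain ", chain,
           " absent from ", path)
    for (nm in names(wanted)) {
      hit <- rows[rows$elety == wanted[[nm]], , drop = FALSE]
      if (nrow(hit) >= 1L)
        coords <- rbind(coords, matrix(
          as.numeric(hit[1L, c("x", "y", "z")]), 1L, 3L,
          dimnames = list(atom_key(nm, i))))
    }
    for (nm in c("N", "CA", "C"))
      if (!(atom_key(nm, i) %in% rownames(coords)))
        stop("missing-residue: backbone atom ", wanted[[nm]], " of residue ",
             resnos[i], " absent from ", path)
  }
  need_h <- c(atom_key("HA", seq_len(n_residues)),
              atom_key("H", seq.int(2L, n_residues)))
  structure(coords,
            resno_map = stats::setNames(resnos, seq_len(n_residues)),
            missing_h = setdiff(need_h, rownames(coords)))
}

#' Write loop coordinates (or a solution ensemble) as PDB
#'
#' One MODEL/ENDMDL block per coordinate set, numbered in branch-signature
#' order so solution identity is stable across runs.  Atom keys map back to
#' standard PDB atom names; all residues are written as GLY placeholders
#' (the model carries no side chains beyond CB).
#'
#' @param coord_list a coordinate matrix or list of matrices (rows named by
#'   atom key).
#' @param path output file path.
#' @param chain chain identifier to write.
#' @param start_res author residue number of loop residue 1.
#' @param header optional character vector of REMARK lines.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(coord_list, path, chain = "A", start_res = 1L,
                             header = NULL) {
  if (is.matrix(coord_list)) coord_list <- list(coord_list)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("REMARK   6 %s", header), con)
  multi <- length(coord_list) > 1L
  for (mi in seq_along(coord_list)) {
    cc <- coord_list[[mi]]
    keys <- rownames(cc)
    keys <- keys[order(key_res(keys),
                       match(key_name(keys), c("N", "CA", "C", "CB",
                                               "H", "HA")))]
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (k in keys) {
      serial <- serial + 1L
      nm <- key_name(k)
      elem <- substr(nm, 1L, 1L)
      ename <- if (nchar(nm) < 4L) paste0(" ", formatC(nm, width = -3L))
               else nm
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, ename, "GLY", chain, start_res + key_res(k) - 1L,
        cc[k, 1L], cc[k, 2L], cc[k, 3L], 1, 0, elem), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
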