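# Atom identity and connectivity for an n-residue loop.
#
# Atoms are addressed by keys "NAME:RES" with NAME one of N, CA, C, H, HA,
# CB and RES the 1-based residue index within the loop.  The backbone model
# carries N/CA/C for every residue, an alpha hydrogen HA for every residue
# and an amide hydrogen H for residues 2..n (the loop-entry amide hydrogen
# is not part of the model).

ALLOWED_ATOMS <- c("N", "CA", "C", "H", "HA", "CB")

atom_key <- function(name, res) paste0(name, ":", res)

key_name <- function(key) sub(":.*$", "", key)

key_res <- function(key) as.integer(sub("^.*:", "", key))

is_hydrogen <- function(key) key_name(key) %in% c("H", "HA")

#' Atom roster of an n-residue loop
#'
#' @param n_residues number of residues (>= 4).
#' @return character vector of atom keys: backbone N/CA/C for all residues,
#'   HA for all residues, H for residues 2..n.
#' @keywords internal
loop_atoms <- function(n_residues) {
  c(as.vector(t(outer(c("N", "CA", "C"), seq_len(n_residues), atom_key))),
    atom_key("HA", seq_len(n_residues)),
    atom_key("H", seq.int(2L, n_residues)))
}

# Covalent adjacency (list key -> character vector of bonded keys) for the
# loop backbone with hydrogens.
covalent_graph <- function(n_residues) {
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (i in seq_len(n_residues)) {
    add(atom_key("N", i), atom_key("CA", i))
    add(atom_key("CA", i), atom_key("C", i))
    add(atom_key("CA", i), atom_key("HA", i))
    if (i >= 2L) add(atom_key("N", i), atom_key("H", i))
    if (i < n_residues) add(atom_key("C", i), atom_key("N", i + 1L))
  }
  adj
}

# Number of covalent bonds separating two atoms, capped at 3 ("far").
bond_separation <- function(graph, a, b, cap = 2L) {
  if (a == b) return(0L)
  frontier <- a
  seen <- a
  for (depth in seq_len(cap)) {
    frontier <- setdiff(unique(unlist(graph[frontier], use.names = FALSE)), seen)
    if (b %in% frontier) return(depth)
    seen <- c(seen, frontier)
    if (length(frontier) == 0L) break
  }
  cap + 1L
}

#' Rigid bodies of an anchored loop
#'
#' The loop is anchored at three fixed C-alpha atoms (residues
#' `anchors[1] < anchors[2] < anchors[3]`, with `anchors[1] == 1` and
#' `anchors[3] < n`).  Three rigid bodies result: anchor 1 to anchor 2,
#' anchor 2 to anchor 3, and the closing body running from anchor 3 through
#' the loop's last residue back to the N and C-alpha of residue 1.  Bodies
#' are heavy-atom sets; consecutive bodies share exactly one anchor C-alpha.
#'
#' @param n_residues loop length.
#' @param anchors integer length-3, loop-local anchor residue indices.
#' @return list of three character vectors of atom keys.
#' @export
rigid_bodies <- function(n_residues, anchors) {
  check_anchor_layout(n_residues, anchors)
  a <- as.integer(anchors)
  span <- function(from, to) {
    ks <- c(atom_key("CA", from), atom_key("C", from))
    if (to - from >= 2L)
      for (i in seq.int(from + 1L, to - 1L))
        ks <- c(ks, atom_key("N", i), atom_key("CA", i), atom_key("C", i))
    c(ks, atom_key("N", to), atom_key("CA", to))
  }
  body1 <- span(a[1L], a[2L])
  body2 <- span(a[2L], a[3L])
  body3 <- c(atom_key("CA", a[3L]), atom_key("C", a[3L]))
  for (i in seq.int(a[3L] + 1L, n_residues))
    body3 <- c(body3, atom_key("N", i), atom_key("CA", i), atom_key("C", i))
  body3 <- c(body3, atom_key("N", a[1L]), atom_key("CA", a[1L]))
  list(body1, body2, body3)
}

check_anchor_layout <- function(n_residues, anchors) {
  a <- as.integer(anchors)
  if (length(a) != 3L || any(diff(a) < 1L) || a[1L] != 1L ||
      a[3L] >= n_residues || n_residues < 4L)
    stop("unsupported anchor layout: need 1 == a1 < a2 < a3 < n_residues ",
         "(three contiguous bodies with a closing segment)")
  invisible(TRUE)
}

# Classify a pair of atoms by distance provenance:
#   "b"  within two covalent bonds (bond lengths/angles fix the distance),
#   "r"  both heavy atoms of a common rigid body, or the loop-entry amide N
#        paired with a heavy atom of body 1 (closure convention: that N is
#        rigidly attached to the first body's anchor frame),
#   NA   otherwise (hydrogen-hydrogen pairs are handled as contacts).
classify_pair <- function(a, b, bodies, graph, n_a1_key) {
  sep <- bond_separation(graph, a, b)
  if (sep <= 2L) return("b")
  ah <- is_hydrogen(a); bh <- is_hydrogen(b)
  if (!ah && !bh) {
    for (body in bodies)
      if (a %in% body && b %in% body) return("r")
    if ((a == n_a1_key && b %in% bodies[[1L]]) ||
        (b == n_a1_key && a %in% bodies[[1L]])) return("r")
  }
  NA_character_
}
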