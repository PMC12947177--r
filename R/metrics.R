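# Scoring: anchored-frame RMSD against a reference embedding, ensemble
# summaries, and the solution-count ratio comparing the hydrogen-rich and
# hydrogen-reduced orders.

#' Anchored root-mean-square deviation
#'
#' RMSD between two embeddings that share the anchor frame: the first three
#' vertices are pinned to identical coordinates by construction, so the
#' deviation is computed directly in that common frame, with no additional
#' superposition.
#'
#' @param coords coordinate matrix, rows named by atom key.
#' @param reference reference coordinate matrix, rows named by atom key.
#' @param subset atom keys to score (default: all atoms of `coords`; atoms
#'   must exist in both).
#' @return RMSD in Angstrom.
#' @export
anchored_rmsd <- function(coords, reference, subset = rownames(coords)) {
  missing <- setdiff(subset, intersect(rownames(coords), rownames(reference)))
  if (length(missing) > 0L)
    stop("atom-mismatch: not present in both embeddings: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  a <- coords[subset, , drop = FALSE]
  b <- reference[subset, , drop = FALSE]
  sqrt(mean(rowSums((a - b)^2)))
}

#' Minimum anchored RMSD over a solution set
#'
#' The reported score of an enumeration run is the smallest RMSD among all
#' solutions; the mean and max are attached to describe the rest of the
#' ensemble.
#'
#' @param solutions a `bp_solutions` object.
#' @param reference reference coordinate matrix (defaults to the RMSDs
#'   already computed against the instance reference).
#' @param subset atom keys to score.
#' @return minimum RMSD with attributes `mean` and `max`.
#' @export
min_rmsd <- function(solutions, reference = NULL, subset = NULL) {
  stopifnot(inherits(solutions, "bp_solutions"))
  if (length(solutions$solutions) == 0L)
    stop("empty-set: no solutions to score")
  if (is.null(reference) && is.null(subset)) {
    r <- solutions$rmsd
    if (all(is.na(r))) stop("no reference embedding available")
  } else {
    r <- vapply(solutions$solutions, function(cc)
      anchored_rmsd(cc, reference,
                    subset %||% rownames(cc)), numeric(1L))
  }
  structure(min(r), mean = mean(r), max = max(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solution-count ratio of the H and Hbar orders
#'
#' `n_H / (n_H + n_Hbar)`: 0.5 means the hydrogen-rich order returned as
#' many solutions as the reduced order; values below 0.5 quantify the
#' pruning effect of the hydrogen-hydrogen restraints.
#'
#' @param n_H,n_Hbar solution counts from the two orders.
#' @return the ratio in `[0, 1]`.
#' @export
pruning_ratio <- function(n_H, n_Hbar) {
  stopifnot(n_H >= 0, n_Hbar >= 0)
  if (n_H + n_Hbar == 0) stop("zero-denominator: both solution counts are 0")
  n_H / (n_H + n_Hbar)
}

#' Run both vertex orders on one loop and compare solution counts
#'
#' Builds the H-order and Hbar-order instances from the same coordinates,
#' the same interval specification and the same seed (so the shared
#' discretization interval is identical), solves both with the same
#' configuration, and reports the counts and their ratio.
#'
#' @param coords loop coordinates including hydrogens.
#' @param n_residues,anchors loop layout (see [build_h_order()]).
#' @param spec an [interval_spec()].
#' @param config a [bp_config()].
#' @return list with `H` and `Hbar` (`bp_solutions`), `n_H`, `n_Hbar`,
#'   `ratio`, class `order_comparison`.
#' @export
compare_orders <- function(coords, n_residues,
                           anchors = default_anchors(n_residues),
                           spec = interval_spec(), config = bp_config()) {
  h <- build_h_order(n_residues, anchors)
  hbar <- build_hbar_order(h)
  sol_h <- bp_solve(assemble_instance(coords, h, spec), config)
  sol_hbar <- bp_solve(assemble_instance(coords, hbar, spec), config)
  structure(list(H = sol_h, Hbar = sol_hbar,
                 n_H = length(sol_h$solutions),
                 n_Hbar = length(sol_hbar$solutions),
                 ratio = pruning_ratio(length(sol_h$solutions),
                                       length(sol_hbar$solutions))),
            class = "order_comparison")
}

#' @export
print.order_comparison <- function(x, ...) {
  cat(sprintf("H vs Hbar comparison: n_H = %d, n_Hbar = %d, ratio = %.3f\n",
              x$n_H, x$n_Hbar, x$ratio))
  invisible(x)
}
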