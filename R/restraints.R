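# Simulated NMR-style hydrogen-hydrogen distance restraints.
#
# Every hydrogen pair closer than a cutoff (5 Angstrom by default, the range
# within which NOE contacts are typically measurable) contributes an interval
# restraint: the true distance d is wrapped in [d - tau, d + delta - tau]
# with tau drawn uniformly from [0, delta], so the interval has width exactly
# delta and always contains d, at a uniformly random offset.

#' Interval restraint specification
#'
#' @param delta interval width in Angstrom (the study grid is
#'   0.2 / 0.5 / 1.0 / 1.5; any value >= 0 is accepted, 0 meaning exact).
#' @param cutoff detection cutoff in Angstrom (strict `<`; default 5).
#' @param seed integer seed driving every tau draw of one instance build.
#' @return an object of class `interval_spec`.
#' @export
interval_spec <- function(delta = 1.5, cutoff = 5.0, seed = 1L) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0,
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(delta = delta, cutoff = cutoff, seed = as.integer(seed)),
            class = "interval_spec")
}

#' Detect short-range hydrogen-hydrogen contacts
#'
#' @param coords coordinate matrix with rows named by atom key.
#' @param cutoff strict upper bound on the distance, in Angstrom.
#' @return data.frame `a`, `b` (atom keys, `a` before `b` in row order of
#'   `coords`), `d` (true distance), one row per unordered pair, ordered by
#'   (`a`, `b`).
#' @export
detect_hh_contacts <- function(coords, cutoff = 5.0) {
  hk <- rownames(coords)[is_hydrogen(rownames(coords))]
  hk <- hk[order(key_res(hk), key_name(hk))]
  if (length(hk) < 2L)
    return(data.frame(a = character(0), b = character(0), d = numeric(0)))
  xyz <- coords[hk, , drop = FALSE]
  dd <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dd) & dd < cutoff, arr.ind = TRUE)
  out <- data.frame(a = hk[pairs[, 1L]], b = hk[pairs[, 2L]],
                    d = dd[pairs])
  out[order(out$a, out$b), , drop = FALSE]
}

#' Wrap a true distance in a randomized interval
#'
#' Returns `[d - tau, d + delta - tau]` with `tau ~ U[0, delta]` drawn from
#' the current RNG stream.  The interval has width exactly `delta` and always
#' contains `d`.  If the lower bound would be non-positive (possible only
#' for `d < delta`), it is clamped to a small positive floor with a warning.
#'
#' @param d true distance in Angstrom (`0 < d`).
#' @param spec an [interval_spec()]; only `delta` is used here.
#' @return numeric length-2 `c(lo, hi)`.
#' @export
make_interval <- function(d, spec) {
  stopifnot(d > 0)
  delta <- spec$delta
  if (delta == 0) return(c(d, d))
  tau <- stats::runif(1L, 0, delta)
  lo <- d - tau
  hi <- d + delta - tau
  if (lo <= 0) {
    warning("negative-lo: interval lower bound clamped to 0.01 A")
    lo <- 0.01
  }
  c(lo, hi)
}
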