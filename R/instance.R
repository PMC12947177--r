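# A DDGP instance: the weighted graph over an ordered atom set, with the
# anchor frame pinned and (optionally) the full reference embedding kept for
# scoring.  Exact edges (classes r and b) carry lo == hi; hydrogen-hydrogen
# edges (class *) carry an interval.  Each edge is either a discretization
# edge (consumed by a predecessor set, i.e. used to place an atom) or a
# pruning edge (used only to reject candidate positions).

#' Assemble a DDGP instance from coordinates and a vertex order
#'
#' Emits exact edges for every class r/b pair of the order; wraps the
#' designated hydrogen-hydrogen discretization distance, and every other
#' hydrogen pair closer than `spec$cutoff`, in randomized intervals of width
#' `spec$delta` (see [make_interval()]).  Edges consumed by predecessor sets
#' get role `discretization`; every other edge prunes.  The tau draws are
#' driven by `spec$seed`, in edge order, so an instance is fully reproducible
#' from (coordinates, order, delta, seed).
#'
#' @param coords coordinate matrix, rows named by atom key; must contain
#'   every atom of the order (add hydrogens first if needed, see
#'   [add_missing_hydrogens()]).
#' @param order a [build_h_order()] / [build_hbar_order()] vertex order.
#' @param spec an [interval_spec()].
#' @param geometry geometry table used for bonded-pair consistency checks.
#' @return an object of class `ddgp_instance`.
#' @export
assemble_instance <- function(coords, order, spec = interval_spec(),
                              geometry = default_geometry()) {
  stopifnot(inherits(order, "ddgp_order"), inherits(spec, "interval_spec"))
  keys <- order$vertices$key
  missing <- setdiff(keys, rownames(coords))
  if (length(missing) > 0L)
    stop("missing-atom: coordinates absent for ",
         paste(missing, collapse = ", "))
  xyz <- coords[keys, , drop = FALSE]
  m <- length(keys)
  graph <- covalent_graph(order$n_residues)
  n_a1 <- atom_key("N", order$anchors[1L])
  pos <- stats::setNames(seq_len(m), keys)
  dpair <- sort(unname(pos[order$disc_pair]))

  dist_of <- function(i, j) vnorm(xyz[i, ] - xyz[j, ])

  set.seed(spec$seed)
  ei <- integer(0); ej <- integer(0); lo <- numeric(0); hi <- numeric(0)
  kl <- character(0); role <- character(0)
  in_pred <- matrix(FALSE, m, m)

  # the designated interval discretization edge first, then the remaining
  # predecessor-set edges, then structural and contact pruning edges
  d_true <- dist_of(dpair[1L], dpair[2L])
  iv <- make_interval(d_true, spec)
  ei <- dpair[1L]; ej <- dpair[2L]; lo <- iv[1L]; hi <- iv[2L]
  kl <- "*"; role <- "discretization"
  in_pred[dpair[1L], dpair[2L]] <- TRUE

  for (i in seq_len(m)) {
    pr <- order$preds[[i]]
    for (k in seq_len(nrow(pr))) {
      j <- pr$j[k]
      if (in_pred[min(i, j), max(i, j)]) next
      in_pred[min(i, j), max(i, j)] <- TRUE
      d <- dist_of(i, j)
      if (pr$class[k] == "b") {
        ideal <- ideal_bond_pair_distance(geometry, graph, keys[i], keys[j])
        if (!is.null(ideal) && abs(d - ideal) > 0.05)
          warning(sprintf("bonded pair %s-%s deviates from ideal by %.3f A",
                          keys[i], keys[j], abs(d - ideal)))
      }
      ei <- c(ei, min(i, j)); ej <- c(ej, max(i, j))
      lo <- c(lo, d); hi <- c(hi, d)
      kl <- c(kl, pr$class[k]); role <- c(role, "discretization")
    }
  }
  # structural (r/b) pairs not consumed by predecessor sets
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (in_pred[i, j]) next
      kc <- classify_pair(keys[i], keys[j], order$bodies, graph, n_a1)
      if (is.na(kc)) next
      d <- dist_of(i, j)
      ei <- c(ei, i); ej <- c(ej, j); lo <- c(lo, d); hi <- c(hi, d)
      kl <- c(kl, kc); role <- c(role, "pruning")
      in_pred[i, j] <- TRUE
    }
  }
  # hydrogen-hydrogen contacts below the cutoff
  contacts <- detect_hh_contacts(xyz, spec$cutoff)
  if (nrow(contacts) > 0L) {
    for (k in seq_len(nrow(contacts))) {
      i <- unname(pos[contacts$a[k]]); j <- unname(pos[contacts$b[k]])
      ii <- min(i, j); jj <- max(i, j)
      if (in_pred[ii, jj]) next
      iv <- make_interval(contacts$d[k], spec)
      ei <- c(ei, ii); ej <- c(ej, jj); lo <- c(lo, iv[1L]); hi <- c(hi, iv[2L])
      kl <- c(kl, "*"); role <- c(role, "pruning")
      in_pred[ii, jj] <- TRUE
    }
  }
  edges <- data.frame(i = ei, j = ej, lo = lo, hi = hi, klass = kl,
                      role = role)
  ordix <- order(edges$j, edges$i)
  edges <- edges[ordix, , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(
    order = order,
    edges = edges,
    anchor_coords = xyz[1:3, , drop = FALSE],
    reference_coords = xyz,
    delta = spec$delta,
    cutoff = spec$cutoff,
    seed = spec$seed
  ), class = "ddgp_instance")
}

#' Validate the discretizability of an instance
#'
#' Report-only check of the two order requirements: the first three vertices
#' carry mutually consistent fixed positions, and every later vertex has at
#' least three predecessors at known distance whose positions are not
#' collinear (strict triangle inequality).
#'
#' @param instance a `ddgp_instance`.
#' @return data.frame of violations (columns `vertex`, `issue`); zero rows
#'   when the instance is a valid DDGP.
#' @export
validate_order <- function(instance) {
  stopifnot(inherits(instance, "ddgp_instance"))
  v <- instance$order$vertices
  ed <- instance$edges
  viol <- data.frame(vertex = integer(0), issue = character(0))
  flag <- function(i, msg) viol <<- rbind(viol, data.frame(vertex = i, issue = msg))
  # condition 1: the anchor triangle is realized by the anchor coordinates
  ac <- instance$anchor_coords
  for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    e <- ed[ed$i == p[1L] & ed$j == p[2L], ]
    if (nrow(e) == 0L) { flag(p[2L], "missing anchor edge"); next }
    d <- vnorm(ac[p[1L], ] - ac[p[2L], ])
    if (abs(d - e$lo[1L]) > 1e-6)
      flag(p[2L], sprintf("anchor coordinates violate edge %d-%d", p[1L], p[2L]))
  }
  # condition 2: >= 3 predecessors, non-collinear
  for (i in seq.int(4L, nrow(v))) {
    pr <- instance$order$preds[[i]]
    if (nrow(pr) < 3L) { flag(i, "fewer than 3 predecessors"); next }
    has_edge <- vapply(pr$j, function(j)
      any(ed$i == min(i, j) & ed$j == max(i, j)), logical(1L))
    if (!all(has_edge)) { flag(i, "predecessor edge missing"); next }
    ref <- instance$reference_coords
    if (is.null(ref)) next  # geometric check needs an embedding to measure
    p3 <- ref[v$key[pr$j[1:3]], , drop = FALSE]
    d12 <- vnorm(p3[1L, ] - p3[2L, ]); d23 <- vnorm(p3[2L, ] - p3[3L, ])
    d13 <- vnorm(p3[1L, ] - p3[3L, ])
    tri <- sort(c(d12, d23, d13))
    if (!(tri[1L] + tri[2L] > tri[3L] + 1e-9))
      flag(i, "strict triangle inequality violated among predecessors")
  }
  rownames(viol) <- NULL
  viol
}

#' @export
print.ddgp_instance <- function(x, ...) {
  ed <- x$edges
  cat(sprintf("DDGP instance (%s-order): %d vertices, %d edges\n",
              if (x$order$kind == "H") "H" else "Hbar",
              nrow(x$order$vertices), nrow(ed)))
  cat(sprintf("  exact: %d (r %d, b %d)   interval: %d (width %.2f A)\n",
              sum(ed$klass != "*"), sum(ed$klass == "r"),
              sum(ed$klass == "b"), sum(ed$klass == "*"), x$delta))
  cat(sprintf("  discretization edges: %d, pruning edges: %d\n",
              sum(ed$role == "discretization"), sum(ed$role == "pruning")))
  invisible(x)
}

#' Write an instance to JSON
#'
#' Self-contained schema: vertices with order index, atom and classified
#' predecessor list; edges with `(i, j, lo, hi, klass, role)`; anchor
#' coordinates; optional reference coordinates (kept for scoring, never read
#' by the solver).  Distances are serialized at 6 decimals.
#'
#' @param instance a `ddgp_instance`.
#' @param path output file path.
#' @export
write_instance <- function(instance, path) {
  v <- instance$order$vertices
  obj <- list(
    kind = instance$order$kind,
    n_residues = instance$order$n_residues,
    anchors = instance$order$anchors,
    delta = instance$delta,
    cutoff = instance$cutoff,
    seed = instance$seed,
    disc_pair = instance$order$disc_pair,
    vertices = lapply(seq_len(nrow(v)), function(i) list(
      order_index = v$idx[i],
      atom = list(name = v$name[i], residue = v$res[i]),
      predecessors = if (nrow(instance$order$preds[[i]]) == 0L) list() else
        lapply(seq_len(nrow(instance$order$preds[[i]])), function(k) list(
          j = instance$order$preds[[i]]$j[k],
          class = instance$order$preds[[i]]$class[k]))
    )),
    edges = lapply(seq_len(nrow(instance$edges)), function(k) list(
      i = instance$edges$i[k], j = instance$edges$j[k],
      lo = round(instance$edges$lo[k], 6L),
      hi = round(instance$edges$hi[k], 6L),
      klass = instance$edges$klass[k], role = instance$edges$role[k])),
    anchor_coords = unname(lapply(1:3, function(i)
      as.numeric(instance$anchor_coords[i, ]))),
    reference_coords = if (is.null(instance$reference_coords)) NULL else
      stats::setNames(lapply(rownames(instance$reference_coords), function(k)
        as.numeric(instance$reference_coords[k, ])),
        rownames(instance$reference_coords))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an instance from JSON
#'
#' @param path file written by [write_instance()].
#' @return a `ddgp_instance`.
#' @export
read_instance <- function(path) {
  obj <- jsonlite::read_json(path)
  n <- obj$n_residues
  a <- as.integer(unlist(obj$anchors))
  keys <- vapply(obj$vertices, function(vv)
    atom_key(vv$atom$name, vv$atom$residue), character(1L))
  preds <- lapply(obj$vertices, function(vv) {
    if (length(vv$predecessors) == 0L)
      return(data.frame(j = integer(0), class = character(0)))
    data.frame(j = vapply(vv$predecessors, function(p) as.integer(p$j),
                          integer(1L)),
               class = vapply(vv$predecessors, function(p) p$class,
                              character(1L)))
  })
  ord <- structure(list(
    vertices = data.frame(idx = seq_along(keys), key = keys,
                          name = key_name(keys), res = key_res(keys)),
    preds = preds,
    disc_pair = as.character(unlist(obj$disc_pair)),
    kind = obj$kind,
    n_residues = n,
    anchors = a,
    bodies = rigid_bodies(n, a)
  ), class = "ddgp_order")
  edges <- data.frame(
    i = vapply(obj$edges, function(e) as.integer(e$i), integer(1L)),
    j = vapply(obj$edges, function(e) as.integer(e$j), integer(1L)),
    lo = vapply(obj$edges, function(e) as.numeric(e$lo), numeric(1L)),
    hi = vapply(obj$edges, function(e) as.numeric(e$hi), numeric(1L)),
    klass = vapply(obj$edges, function(e) e$klass, character(1L)),
    role = vapply(obj$edges, function(e) e$role, character(1L)))
  anchor <- do.call(rbind, lapply(obj$anchor_coords, as.numeric))
  rownames(anchor) <- keys[1:3]
  ref <- NULL
  if (!is.null(obj$reference_coords)) {
    ref <- do.call(rbind, lapply(obj$reference_coords, as.numeric))
    rownames(ref) <- names(obj$reference_coords)
  }
  structure(list(order = ord, edges = edges, anchor_coords = anchor,
                 reference_coords = ref, delta = obj$delta,
                 cutoff = obj$cutoff, seed = obj$seed),
            class = "ddgp_instance")
}
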