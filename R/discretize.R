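#' Discretize a dated species tree
#'
#' Builds the time-sliced grid on which all DLT-process probabilities are
#' computed.  The vertex times of the species tree (plus the stem tip) cut the
#' tree into *time slices*; within each slice, every contemporaneous edge
#' receives `resolution` grid points at the midpoints of `resolution` equal
#' sub-intervals — the same time points across all edges crossing the slice.
#' Each midpoint carries a quadrature weight `delta` equal to the sub-interval
#' length, so per-edge weights sum exactly to the edge's time duration.
#' Points at species-vertex times (the out-degree-1 points inserted where an
#' edge crosses a speciation elsewhere in the tree, and the edge endpoints)
#' carry weight 0: duplication and transfer events are never placed exactly at
#' speciation times.
#'
#' @param st a [dated_species_tree].
#' @param resolution integer >= 1: number of equal sub-intervals per slice per
#'   edge.  Default 10.
#' @return an object of class `dltrs_grid`.
#' @examples
#' S <- dated_species_tree("((A:1,B:1):1,C:2);", stem = 0.2)
#' g <- discretize(S, resolution = 4)
#' g$npoints
#' @export
discretize <- function(st, resolution = 10) {
  stopifnot(inherits(st, "dated_species_tree"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 1) stop("resolution must be an integer >= 1")

  top_time <- st$time[st$root] + st$stem
  bounds <- sort(unique(c(st$time, top_time)))
  nslice <- length(bounds) - 1L
  slice_lo <- bounds[seq_len(nslice)]
  slice_hi <- bounds[-1L]

  ptime <- ifelse(is.na(st$parent), top_time, st$time[st$parent])

  # slice membership: edge e (child vertex e) spans [time[e], ptime[e])
  slice_edges <- lapply(seq_len(nslice), function(s)
    which(st$time <= slice_lo[s] & ptime >= slice_hi[s]))

  # build points edge by edge, bottom to top
  pt_edge <- integer(0); pt_time <- numeric(0); pt_delta <- numeric(0)
  pt_kind <- integer(0); pt_slice <- integer(0); pt_sub <- integer(0)
  edge_pts <- vector("list", st$nvert)
  add_pt <- function(edge, time, delta, kind, slice, sub) {
    pt_edge[length(pt_edge) + 1L] <<- edge
    pt_time[length(pt_time) + 1L] <<- time
    pt_delta[length(pt_delta) + 1L] <<- delta
    pt_kind[length(pt_kind) + 1L] <<- kind
    pt_slice[length(pt_slice) + 1L] <<- slice
    pt_sub[length(pt_sub) + 1L] <<- sub
    length(pt_edge)
  }
  # kinds: 1 leaf, 2 speciation, 3 interior (delta>0), 4 sliceline, 5 top, 6 stemtip
  for (e in seq_len(st$nvert)) {
    ids <- integer(0)
    bk <- if (e <= st$ntip) 1L else 2L
    ids <- c(ids, add_pt(e, st$time[e], 0, bk, NA_integer_, 0L))
    for (s in which(slice_lo >= st$time[e] - 1e-12 & slice_hi <= ptime[e] + 1e-12)) {
      h <- (slice_hi[s] - slice_lo[s]) / resolution
      for (j in seq_len(resolution))
        ids <- c(ids, add_pt(e, slice_lo[s] + (j - 0.5) * h, h, 3L, s, j))
      tk <- if (abs(slice_hi[s] - ptime[e]) < 1e-12) {
        if (is.na(st$parent[e])) 6L else 5L
      } else 4L
      ids <- c(ids, add_pt(e, slice_hi[s], 0, tk, NA_integer_, 0L))
    }
    edge_pts[[e]] <- ids
  }
  npt <- length(pt_edge)

  # partners: same (slice, sub-index) interior points on other edges; k = edge
  # count of the slice
  partners <- vector("list", npt)
  ptk <- integer(npt)
  int_idx <- which(pt_kind == 3L)
  grp <- split(int_idx, list(pt_slice[int_idx], pt_sub[int_idx]), drop = TRUE)
  for (g in grp) for (x in g) partners[[x]] <- setdiff(g, x)
  ptk[int_idx] <- lengths(slice_edges)[pt_slice[int_idx]]

  vertex_pt <- vapply(seq_len(st$nvert), function(v) edge_pts[[v]][1L], 1L)
  top_pt <- vapply(seq_len(st$nvert), function(e) {
    ids <- edge_pts[[e]]; ids[length(ids)]
  }, 1L)

  # child-edge top anchors for speciation points
  spec_top <- matrix(0L, npt, 2)
  for (v in seq_len(st$nvert)) if (v > st$ntip) {
    spec_top[vertex_pt[v], ] <- top_pt[st$children[v, ]]
  }

  # strict descendant edges of each edge
  subtree_edges <- vector("list", st$nvert)
  for (v in order(st$time)) {
    if (v <= st$ntip) subtree_edges[[v]] <- integer(0)
    else {
      ch <- st$children[v, ]
      subtree_edges[[v]] <- c(ch, subtree_edges[[ch[1]]], subtree_edges[[ch[2]]])
    }
  }

  is_place <- pt_kind %in% c(1L, 2L, 3L)
  place_by_edge <- lapply(seq_len(st$nvert), function(e) {
    ids <- edge_pts[[e]]; ids[is_place[ids]]
  })
  below <- vector("list", npt)
  for (x in seq_len(npt)) {
    e <- pt_edge[x]
    own <- place_by_edge[[e]]
    own <- own[pt_time[own] < pt_time[x] - 1e-15]
    below[[x]] <- c(own, unlist(place_by_edge[subtree_edges[[e]]], use.names = FALSE))
  }

  # time levels (shared identical times across edges); cache the (lower,
  # upper) level pairs that can actually occur as gene-edge durations — the
  # edge-length density tables are only filled there
  lv <- sort(unique(pt_time))
  pt_level <- match(pt_time, lv)
  L <- length(lv)
  xs <- rep.int(seq_len(npt), lengths(below))
  ys <- unlist(below, use.names = FALSE)
  lf_idx <- sort(unique((pt_level[xs] - 1L) * L + pt_level[ys]))
  lf_dt <- lv[(lf_idx - 1L) %/% L + 1L] - lv[(lf_idx - 1L) %% L + 1L]
  ok <- lf_dt > 1e-14
  lf_idx <- lf_idx[ok]; lf_dt <- lf_dt[ok]

  structure(list(
    tree = st, resolution = resolution,
    slice_lo = slice_lo, slice_hi = slice_hi, slice_edges = slice_edges,
    npoints = npt, pt_edge = pt_edge, pt_time = pt_time, pt_delta = pt_delta,
    pt_kind = pt_kind, pt_slice = pt_slice, pt_k = ptk, pt_level = pt_level,
    levels = lv, lf_idx = lf_idx, lf_dt = lf_dt,
    edge_pts = edge_pts, vertex_pt = vertex_pt, top_pt = top_pt,
    spec_top = spec_top, subtree_edges = subtree_edges, partners = partners,
    below = below, is_place = is_place,
    edge_lo = st$time, edge_hi = ptime,
    edge_keys = if (st$nvert > 1L) species_edge_keys(st) else st$label[1]),
    class = "dltrs_grid")
}

#' @export
print.dltrs_grid <- function(x, ...) {
  cat("Discretized species tree: ", x$npoints, " grid points on ",
      x$tree$nvert, " edges (incl. stem), ", length(x$slice_lo),
      " time slices, resolution ", x$resolution, "\n", sep = "")
  invisible(x)
}

# payload handed to the C++ engine: list ids stay 1-based, ragged structures
# are flattened with 0-based offset vectors; 0 encodes "none"
grid_cpp <- function(g) {
  st <- g$tree
  flat <- function(lst) {
    lens <- lengths(lst)
    list(flat = as.integer(unlist(lst, use.names = FALSE)),
         off = c(0L, cumsum(lens)))
  }
  bl <- flat(g$below); pr <- flat(g$partners)
  ep <- flat(g$edge_pts); se <- flat(g$slice_edges)
  list(npt = g$npoints, nE = st$nvert, ntip = st$ntip, root_edge = st$root,
       nlevel = length(g$levels), nslice = length(g$slice_lo),
       resolution = g$resolution,
       pt_edge = g$pt_edge, pt_kind = g$pt_kind, pt_level = g$pt_level,
       pt_k = g$pt_k, pt_time = g$pt_time, pt_delta = g$pt_delta,
       epts = ep$flat, epts_off = ep$off,
       below_flat = bl$flat, below_off = bl$off,
       part_flat = pr$flat, part_off = pr$off,
       sedge_flat = se$flat, sedge_off = se$off,
       slice_lo = g$slice_lo, slice_hi = g$slice_hi,
       edge_child1 = ifelse(is.na(st$children[, 1]), 0L, st$children[, 1]),
       edge_child2 = ifelse(is.na(st$children[, 2]), 0L, st$children[, 2]),
       top_pt = g$top_pt,
       spec_top1 = g$spec_top[, 1], spec_top2 = g$spec_top[, 2],
       is_int = as.integer(g$pt_kind == 3L),
       is_spec = as.integer(g$pt_kind == 2L),
       is_leaf = as.integer(g$pt_kind == 1L))
}
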