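#' Dated species trees
#'
#' A dated species tree is a rooted binary tree whose vertices carry absolute
#' times: all leaves sit at time 0 and time increases towards the root, so the
#' root time equals the tree height.  The tree carries a *stem* — a pre-root
#' edge of positive duration above the root — on which the gene-family process
#' originates with a single lineage at the stem tip.  Every edge is identified
#' by its child vertex; the stem edge is identified by the root vertex.
#'
#' `dated_species_tree()` builds the object from an [ape::phylo] tree (branch
#' lengths in absolute time) or from a newick string; `read_species_tree()`
#' reads a newick file.  Input must be ultrametric to relative tolerance
#' `tol`; leaf times are then snapped to exactly 0.
#'
#' A degenerate single-leaf "tree" (one species, the host consisting only of
#' the stem edge) can be built with `single_edge_tree()`; it is useful for
#' closed-form checks of the birth--death process.
#'
#' @param x an [ape::phylo] object or a newick string.
#' @param stem stem duration (time units).  Default 10\% of the root height.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an object of class `dated_species_tree` with fields
#'   `ntip`, `nvert`, `parent`, `children`, `time`, `label`, `root`,
#'   `stem`, `height`.
#' @examples
#' S <- dated_species_tree("((A:1,B:1):1,C:2);", stem = 0.2)
#' S$time[S$root]          # root height: 2
#' contemporaneous_edges(S, 0.5)
#' @export
dated_species_tree <- function(x, stem = NULL, tol = 1e-6) {
  if (is.character(x)) {
    phy <- tryCatch(ape::read.tree(text = x),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy)) stop("malformed newick string")
  } else if (inherits(x, "phylo")) {
    phy <- x
  } else stop("'x' must be a phylo object or a newick string")
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("species tree must be rooted and binary")

  n <- length(phy$tip.label)
  nv <- n + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)   # distance from root
  height <- max(depth[seq_len(n)])
  if (height <= 0) stop("species tree has zero height")
  if (any(abs(depth[seq_len(n)] - height) > tol * height))
    stop("species tree is not ultrametric (leaf depths differ beyond tolerance)")
  time <- height - depth
  time[seq_len(n)] <- 0

  parent <- rep(NA_integer_, nv)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- n + 1L
  children <- matrix(NA_integer_, nv, 2)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[p, if (is.na(children[p, 1])) 1 else 2] <- phy$edge[i, 2]
  }
  lab <- character(nv)
  lab[seq_len(n)] <- phy$tip.label
  lab[(n + 1):nv] <- paste0("s", (n + 1):nv)
  if (anyDuplicated(phy$tip.label)) stop("duplicate species leaf labels")
  if (is.null(stem)) stem <- 0.1 * height
  if (!is.numeric(stem) || stem <= 0) stop("stem duration must be > 0")

  st <- structure(list(ntip = n, nvert = nv, parent = parent,
                       children = children, time = time, label = lab,
                       root = root, stem = as.numeric(stem), height = height),
                  class = "dated_species_tree")
  validate_dated_species_tree(st)
  st
}

#' @rdname dated_species_tree
#' @param file path to a newick file.
#' @export
read_species_tree <- function(file, stem = NULL, tol = 1e-6) {
  dated_species_tree(paste(readLines(file, warn = FALSE), collapse = ""),
                     stem = stem, tol = tol)
}

#' @rdname dated_species_tree
#' @param duration duration of the single edge (time units).
#' @param label leaf label.
#' @export
single_edge_tree <- function(duration, label = "A") {
  stopifnot(duration > 0)
  structure(list(ntip = 1L, nvert = 1L, parent = NA_integer_,
                 children = matrix(NA_integer_, 1, 2), time = 0,
                 label = label, root = 1L, stem = as.numeric(duration),
                 height = 0),
            class = "dated_species_tree")
}

validate_dated_species_tree <- function(st) {
  if (st$nvert == 1L) return(invisible(st))
  for (v in seq_len(st$nvert)) {
    ch <- st$children[v, ]
    if (v <= st$ntip) {
      if (!all(is.na(ch))) stop("leaf with children")
      if (st$time[v] != 0) stop("leaf not at time 0")
    } else {
      if (any(is.na(ch))) stop("non-binary internal vertex")
      if (any(st$time[ch] >= st$time[v]))
        stop("vertex times must strictly decrease from root to leaves")
    }
  }
  invisible(st)
}

#' @export
print.dated_species_tree <- function(x, ...) {
  cat("Dated species tree:", x$ntip, "leaves, height", format(x$height),
      "+ stem", format(x$stem), "\n")
  cat("Leaves:", paste(x$label[seq_len(x$ntip)], collapse = ", "), "\n")
  invisible(x)
}

#' Convert a dated species tree to an ape phylo object
#'
#' Branch lengths are time durations; the stem is not represented (phylo has
#' no root edge semantics used here).
#' @param st a `dated_species_tree`.
#' @return an [ape::phylo] object.
#' @export
species_tree_phylo <- function(st) {
  if (st$nvert == 1L) stop("single-edge tree has no phylo representation")
  kids <- which(!is.na(st$parent))
  edge <- cbind(st$parent[kids], kids)
  phy <- list(edge = edge,
              edge.length = st$time[edge[, 1]] - st$time[edge[, 2]],
              tip.label = st$label[seq_len(st$ntip)],
              Nnode = st$nvert - st$ntip)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname dated_species_tree
#' @param st a `dated_species_tree`.
#' @param file output path.
#' @export
write_species_tree <- function(st, file) {
  ape::write.tree(species_tree_phylo(st), file = file)
  invisible(file)
}

#' Species edges contemporaneous with a time point
#'
#' Returns the edges of the species tree whose time span contains `t`.  Edges
#' use the half-open convention `[child time, parent time)`, so an interior
#' time belongs to exactly one edge on any root-to-leaf path; the stem edge
#' spans `[root time, root time + stem]` (closed at the stem tip).
#'
#' @param st a `dated_species_tree` (or a `dltrs_grid`, whose tree is used).
#' @param t a time in `[0, root time + stem]`.
#' @return integer vector of edge ids (an edge is identified by its child
#'   vertex; the stem edge by the root), named by the child vertex label.
#' @export
contemporaneous_edges <- function(st, t) {
  if (inherits(st, "dltrs_grid")) st <- st$tree
  top <- st$time[st$root] + st$stem
  if (t < 0 || t > top) stop("time outside [0, root time + stem]")
  if (t >= st$time[st$root]) {
    e <- st$root
  } else {
    pt <- ifelse(is.na(st$parent), Inf, st$time[st$parent])
    e <- which(st$time <= t & t < pt)
  }
  names(e) <- st$label[e]
  e
}

# leaf-set key identifying a species edge independently of vertex numbering
species_edge_keys <- function(st) {
  keys <- character(st$nvert)
  tips_under <- vector("list", st$nvert)
  ord <- order(st$time)                       # leaves first, root last
  for (v in ord) {
    if (v <= st$ntip) tips_under[[v]] <- st$label[v]
    else tips_under[[v]] <- sort(c(tips_under[[st$children[v, 1]]],
                                   tips_under[[st$children[v, 2]]]))
    keys[v] <- paste(tips_under[[v]], collapse = "+")
  }
  keys
}

#' Read or write a gene-to-species leaf map
#'
#' Two-column tab-separated format: `gene_leaf<TAB>species_leaf`, one pair per
#' line, `#` starting a comment line.  Many gene leaves may map to one species
#' leaf.
#'
#' @param file path.
#' @return a named character vector: names are gene leaf labels, values are
#'   species leaf labels.
#' @export
read_leaf_map <- function(file) {
  ln <- readLines(file, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("leaf map lines must have two tab-separated fields")
  m <- vapply(parts, `[`, "", 2)
  names(m) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(m))) stop("duplicate gene leaf in leaf map")
  m
}

#' @rdname read_leaf_map
#' @param map named character vector (gene leaf -> species leaf).
#' @export
write_leaf_map <- function(map, file) {
  writeLines(paste(names(map), map, sep = "\t"), file)
  invisible(file)
}

check_leaf_map <- function(map, gene_labels, st) {
  miss <- setdiff(gene_labels, names(map))
  if (length(miss)) stop("leaf map missing gene leaf: ", paste(miss, collapse = ", "))
  bad <- setdiff(map[gene_labels], st$label[seq_len(st$ntip)])
  if (length(bad)) stop("leaf map targets unknown species leaf: ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}
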