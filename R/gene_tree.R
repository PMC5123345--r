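# Internal rooted-tree representation used by the MCMC and the DP engine.
# A "vtree" stores a rooted binary tree as flat vectors indexed by vertex id
# (ape numbering: tips 1..n, internals n+1..2n-1, root n+1 initially; ids are
# stable under topology moves).  `len[v]` is the substitution length of the
# edge above v (NA at the root).

as_vtree <- function(phy) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("gene tree must be rooted and binary")
  n <- length(phy$tip.label)
  nv <- n + phy$Nnode
  parent <- rep(NA_integer_, nv)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- matrix(NA_integer_, nv, 2)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[p, if (is.na(children[p, 1])) 1 else 2] <- phy$edge[i, 2]
  }
  len <- rep(NA_real_, nv)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  if (anyDuplicated(phy$tip.label)) stop("duplicate gene leaf labels")
  list(ntip = n, nvert = nv, parent = parent, children = children,
       len = len, label = phy$tip.label, root = which(is.na(parent)))
}

vtree_postorder <- function(vt) {
  # returns all vertices, children before parents
  ord <- integer(vt$nvert)
  i <- 0L
  stack <- vt$root
  out <- integer(vt$nvert)   # reverse preorder = postorder reversed
  j <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    j <- j + 1L
    out[j] <- v
    if (v > vt$ntip) stack <- c(stack, vt$children[v, ])
  }
  rev(out)
}

vtree_to_phylo <- function(vt) {
  kids <- which(!is.na(vt$parent))
  edge <- cbind(vt$parent[kids], kids)
  # ape requires tips 1..n, internals n+1.., root n+1: re-index internals
  n <- vt$ntip
  internal <- unique(c(vt$root, setdiff(which(seq_len(vt$nvert) > n), vt$root)))
  newid <- integer(vt$nvert)
  newid[seq_len(n)] <- seq_len(n)
  newid[internal] <- n + seq_along(internal)
  phy <- list(edge = cbind(newid[edge[, 1]], newid[edge[, 2]]),
              edge.length = vt$len[kids],
              tip.label = vt$label, Nnode = vt$nvert - n)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

vtree_newick <- function(vt, digits = 10) {
  ape::write.tree(vtree_to_phylo(vt), digits = digits)
}

# canonical topology string (lengths dropped, children sorted by leaf sets)
vtree_topology_key <- function(vt) {
  rec <- function(v) {
    if (v <= vt$ntip) return(vt$label[v])
    a <- rec(vt$children[v, 1]); b <- rec(vt$children[v, 2])
    if (a < b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
  }
  rec(vt$root)
}

# clade key of every vertex: sorted leaf labels joined by "+"
vtree_clade_keys <- function(vt) {
  keys <- character(vt$nvert)
  for (v in vtree_postorder(vt)) {
    if (v <= vt$ntip) keys[v] <- vt$label[v]
    else {
      a <- strsplit(keys[vt$children[v, 1]], "+", fixed = TRUE)[[1]]
      b <- strsplit(keys[vt$children[v, 2]], "+", fixed = TRUE)[[1]]
      keys[v] <- paste(sort(c(a, b)), collapse = "+")
    }
  }
  keys
}

# undirected path length (in edges) between two vertices
vtree_path_length <- function(vt, a, b) {
  da <- integer(0); v <- a
  anc_a <- v; while (!is.na(vt$parent[v])) { v <- vt$parent[v]; anc_a <- c(anc_a, v) }
  v <- b; db <- 0L
  while (TRUE) {
    hit <- match(v, anc_a)
    if (!is.na(hit)) return(db + hit - 1L)
    db <- db + 1L; v <- vt$parent[v]
  }
}

vtree_diameter <- function(vt) {
  tips <- seq_len(vt$ntip)
  if (length(tips) < 2) return(0L)
  m <- 0L
  for (i in tips) for (j in tips) if (j > i)
    m <- max(m, vtree_path_length(vt, i, j))
  m
}

#' Read a gene tree from newick
#'
#' Gene trees are rooted binary trees whose branch lengths are expected
#' substitutions per site.
#' @param x newick string or file path.
#' @return an [ape::phylo] object (validated: rooted, binary, non-negative
#'   lengths, unique leaf labels).
#' @export
read_gene_tree <- function(x) {
  phy <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(phy)) stop("malformed newick")
  vt <- as_vtree(phy)   # validates
  if (any(vt$len[-vt$root] < 0, na.rm = TRUE)) stop("negative gene tree edge length")
  phy
}
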