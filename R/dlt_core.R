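#' Extinction and propagation tables of the DLT process
#'
#' `solve_extinction()` computes, for every grid point `x` of the discretized
#' species tree, the probability that a single gene lineage at `x` leaves no
#' descendant at any species-tree leaf.  Within each time slice the coupled
#' Kolmogorov equations
#' \deqn{dE_e/dt = \mu - (\delta+\mu+\tau) E_e + \delta E_e^2 +
#'       \frac{\tau}{k-1} E_e \sum_{f \ne e} E_f}
#' are integrated bottom-up (the transfer terms are dropped when the edge is
#' the only contemporaneous one); at a speciation the extinction probability
#' is the product over the two child edges, and at the species leaves it is 0.
#'
#' `solve_propagation()` computes the matrix `p11(x, y)` over ordered grid
#' point pairs: the probability that a lineage at `x` has exactly one
#' descendant at the ancestor-to-descendant point `y` and that every side
#' lineage spawned in between (the losing copy of a duplication, the emigrant
#' of a transfer, the sibling copy at a bypassed speciation) goes extinct.
#' Propagation follows a single species path; entries are 0 for pairs not on
#' such a path.
#'
#' @param grid a [discretize]d species tree.
#' @param theta a [dltrs_params] object (only `delta`, `mu`, `tau` are used).
#' @param tol per-slice ODE tolerance.
#' @return `solve_extinction()`: numeric vector over grid points, in `[0,1]`.
#'   `solve_propagation()`: list with `p11` (npoints x npoints matrix) and
#'   `cum` (per-point log propagation to the bottom of its edge).
#' @export
solve_extinction <- function(grid, theta, tol = 1e-6) {
  dlt_tables(grid, theta, tol)$ext
}

#' @rdname solve_extinction
#' @export
solve_propagation <- function(grid, theta, tol = 1e-6) {
  tb <- dlt_tables(grid, theta, tol)
  list(p11 = tb$p11, cum = tb$cum)
}

#' @rdname solve_extinction
#' @export
dlt_tables <- function(grid, theta, tol = 1e-6) {
  stopifnot(inherits(grid, "dltrs_grid"), tol > 0)
  th <- as_params(theta)
  gc <- attr(grid, "cpp")
  if (is.null(gc)) gc <- grid_cpp(grid)
  tb <- cpp_dlt_tables(gc, th[["delta"]], th[["mu"]], th[["tau"]], tol)
  tb$grid <- grid
  class(tb) <- "dlt_tables"
  tb
}

#' Density of a gene-edge substitution length under the relaxed clock
#'
#' Edge substitution rates are iid gamma with mean `m` and coefficient of
#' variation `cv` (shape `1/cv^2`, scale `m*cv^2`).  An edge of time duration
#' `t` with observed length `l` therefore has density
#' `dgamma(l/t, shape, scale)/t`.
#'
#' @param l observed length(s), substitutions/site, `>= 0`.
#' @param t edge time duration(s), `> 0`.
#' @param m mean edge rate.
#' @param cv coefficient of variation of the edge rate.
#' @return numeric density values.
#' @examples
#' edge_length_density(0, 1, m = 1, cv = 1)   # exponential(1) at 0: 1
#' @export
edge_length_density <- function(l, t, m, cv) {
  if (any(t <= 0)) stop("edge duration t must be > 0")
  shape <- 1 / cv^2
  scale <- m * cv^2
  stats::dgamma(l / t, shape = shape, scale = scale) / t
}

# gene tree payload for the C++ kernels; leafpt anchors gene leaves on the
# grid via the leaf map
gene_cpp <- function(vt, leaf_map, grid) {
  st <- grid$tree
  leafpt <- integer(vt$nvert)
  sp_leaf <- match(leaf_map[vt$label], st$label[seq_len(st$ntip)])
  leafpt[seq_len(vt$ntip)] <- grid$vertex_pt[sp_leaf]
  post <- vtree_postorder(vt)
  list(M = vt$nvert,
       children1 = ifelse(is.na(vt$children[, 1]), 0L, vt$children[, 1]),
       children2 = ifelse(is.na(vt$children[, 2]), 0L, vt$children[, 2]),
       postorder = post[post > vt$ntip],
       root = vt$root,
       leafpt = leafpt,
       tiprow = c(seq_len(vt$ntip), integer(vt$nvert - vt$ntip)))
}

# grid-cached variant: duration pairs precomputed at discretization time
lenfac_fast <- function(l, grid, m, cv) {
  L <- length(grid$levels)
  out <- matrix(0, L, L)
  shape <- 1 / cv^2
  out[grid$lf_idx] <- stats::dgamma(l / grid$lf_dt, shape = shape,
                                    scale = m * cv^2) / grid$lf_dt
  out
}

lenfac_list <- function(vt, grid, m, cv) {
  lapply(seq_len(vt$nvert), function(v) {
    if (v == vt$root) return(matrix(0, 1, 1))
    lenfac_fast(vt$len[v], grid, m, cv)
  })
}

#' Gene-tree density p(G, l | theta, S)
#'
#' Computes the joint density of a gene-tree topology and its edge lengths
#' under the DLT process with the gamma relaxed clock, by dynamic programming
#' over the grid points of the discretized species tree: the sum over all
#' realizations of the per-realization density times the product of the
#' quadrature interval lengths its duplication/transfer placements use.
#'
#' @param gene a rooted binary [ape::phylo] gene tree with edge lengths in
#'   substitutions/site.
#' @param leaf_map named character vector mapping gene leaf labels to species
#'   leaf labels.
#' @param grid a [discretize]d species tree.
#' @param theta a [dltrs_params] object.
#' @param tol ODE tolerance for the underlying tables.
#' @param tables optional precomputed [dlt_tables] for the same grid/theta.
#' @param mode `"sum"` for the density, `"max"` for the max-product variant
#'   backing MAP realization estimation.
#' @return an object of class `dlt_dp`: list with `log_density`, the DP
#'   tables (`A`, `D`, `cs`), and the inputs needed for realization sampling.
#' @export
gene_tree_density <- function(gene, leaf_map, grid, theta, tol = 1e-6,
                              tables = NULL, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  th <- as_params(theta)
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  check_leaf_map(leaf_map, vt$label, grid$tree)
  if (is.null(tables)) tables <- dlt_tables(grid, th, tol)
  gc <- attr(grid, "cpp")
  if (is.null(gc)) gc <- grid_cpp(grid)
  gcpp <- gene_cpp(vt, leaf_map, grid)
  lf <- lenfac_list(vt, grid, th[["m"]], th[["cv"]])
  stemtip <- grid$top_pt[grid$tree$root]
  res <- cpp_dlt_density(gc, tables$p11, gcpp, th[["delta"]], th[["tau"]],
                         lf, if (mode == "sum") 0L else 1L, stemtip, TRUE)
  structure(list(log_density = res$logdens, A = res$A, D = res$D, cs = res$cs,
                 mode = mode, vt = vt, leaf_map = leaf_map, grid = grid,
                 theta = th, tables = tables, lenfacs = lf, gcpp = gcpp,
                 stemtip = stemtip),
            class = "dlt_dp")
}

#' @export
print.dlt_dp <- function(x, ...) {
  cat("DLT dynamic-programming table (", x$mode, " mode): log density ",
      format(x$log_density), "\n", sep = "")
  invisible(x)
}
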