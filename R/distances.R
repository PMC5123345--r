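#' Topological and temporal distances between realizations
#'
#' Compares the transfer events of two realizations of the same gene tree.
#' Transfers are paired by the minimum-total-cost matching (exhaustive over
#' permutations up to 7 transfers, greedy beyond).  The *topological*
#' distance of a matched pair is the path length (in edges) between the two
#' transfer vertices in the gene tree; each unmatched transfer (unequal
#' counts) contributes the gene-tree diameter.  The *temporal* distance of a
#' matched pair is 0 when the two placement time intervals overlap and the
#' gap between the nearer interval endpoints otherwise; unmatched transfers
#' contribute the species-tree root height.  A grid placement at time `t`
#' with quadrature weight `delta` occupies `[t - delta/2, t + delta/2]`;
#' continuous (simulated truth) placements occupy the degenerate interval
#' `[t, t]`.
#'
#' Both functions return the average and the maximum over matched pairs plus
#' penalties; two realizations without transfers are at distance (0, 0).
#'
#' @param d,d2 `dlt_realization` objects over the same gene-tree topology.
#' @param gene the shared gene tree ([ape::phylo] or internal form); vertices
#'   are matched between realizations by their leaf clades.
#' @return a named numeric vector `c(average = , maximum = )`.
#' @export
topological_distance <- function(d, d2, gene) {
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  check_same_topology(d, d2)
  keys <- vtree_clade_keys(vt)
  t1 <- match(d$clade[d$type == "transfer"], keys)
  t2 <- match(d2$clade[d2$type == "transfer"], keys)
  if (!length(t1) && !length(t2)) return(c(average = 0, maximum = 0))
  cost <- outer(t1, t2, Vectorize(function(a, b) vtree_path_length(vt, a, b)))
  pair_distances(cost, vtree_diameter(vt))
}

#' @rdname topological_distance
#' @param grid the discretized species tree the placements live on (used for
#'   the root-height penalty).
#' @export
temporal_distance <- function(d, d2, gene, grid) {
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  check_same_topology(d, d2)
  i1 <- which(d$type == "transfer"); i2 <- which(d2$type == "transfer")
  if (!length(i1) && !length(i2)) return(c(average = 0, maximum = 0))
  gap <- function(lo1, hi1, lo2, hi2) max(0, lo2 - hi1, lo1 - hi2)
  cost <- matrix(0, length(i1), length(i2))
  for (a in seq_along(i1)) for (b in seq_along(i2))
    cost[a, b] <- gap(d$time[i1[a]] - d$delta[i1[a]] / 2,
                      d$time[i1[a]] + d$delta[i1[a]] / 2,
                      d2$time[i2[b]] - d2$delta[i2[b]] / 2,
                      d2$time[i2[b]] + d2$delta[i2[b]] / 2)
  pair_distances(cost, grid$tree$time[grid$tree$root])
}

check_same_topology <- function(d, d2) {
  k1 <- attr(d, "topology"); k2 <- attr(d2, "topology")
  if (!is.null(k1) && !is.null(k2) && k1 != k2)
    stop("realizations are over different gene trees")
  invisible(TRUE)
}

# minimum-total-cost matching; unmatched entries cost `penalty` each
pair_distances <- function(cost, penalty) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0) {
    k <- max(n1, n2)
    return(c(average = penalty, maximum = penalty) * (k > 0))
  }
  swap <- n1 > n2
  if (swap) { cost <- t(cost); tmp <- n1; n1 <- n2; n2 <- tmp }
  # assign each row to a distinct column, n1 <= n2
  best <- NULL; bestsum <- Inf
  if (n2 <= 7) {
    perms <- all_perms(n2)
    for (p in perms) {
      s <- sum(cost[cbind(seq_len(n1), p[seq_len(n1)])])
      if (s < bestsum) { bestsum <- s; best <- p[seq_len(n1)] }
    }
  } else {
    best <- integer(n1); used <- logical(n2)
    for (i in seq_len(n1)) {
      j <- order(replace(cost[i, ], used, Inf))[1]
      best[i] <- j; used[j] <- TRUE
    }
    bestsum <- sum(cost[cbind(seq_len(n1), best)])
  }
  dists <- c(cost[cbind(seq_len(n1), best)], rep(penalty, n2 - n1))
  c(average = mean(dists), maximum = max(dists))
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Expected distances between a reference realization and a posterior
#'
#' Averages the four distance variants (average/maximum topological,
#' average/maximum temporal) over a posterior sample of realizations with
#' uniform weights: `E = sum_d' dist(d_true, d') q(d')`.
#'
#' @param d_true the reference realization (e.g. simulated truth).
#' @param post a `dlt_realizations` posterior over the same gene tree.
#' @param grid the discretized species tree.
#' @return object of class `dlt_distance_summary`: expectations `E_DGa`,
#'   `E_DGm`, `E_DTa`, `E_DTm` and the per-sample raw distances.
#' @export
expected_distances <- function(d_true, post, grid) {
  stopifnot(inherits(post, "dlt_realizations"))
  if (!length(post$samples)) stop("empty posterior")
  vt <- post$vt
  raw <- t(vapply(post$samples, function(d2) {
    c(topological_distance(d_true, d2, vt),
      temporal_distance(d_true, d2, vt, grid))
  }, numeric(4)))
  colnames(raw) <- c("DGa", "DGm", "DTa", "DTm")
  structure(list(E_DGa = mean(raw[, 1]), E_DGm = mean(raw[, 2]),
                 E_DTa = mean(raw[, 3]), E_DTm = mean(raw[, 4]),
                 raw = raw, n = nrow(raw)),
            class = "dlt_distance_summary")
}

#' @export
print.dlt_distance_summary <- function(x, ...) {
  cat("Expected realization distances over", x$n, "posterior samples:\n")
  cat("  topological: average", format(x$E_DGa), " maximum", format(x$E_DGm),
      "(gene-tree edges)\n")
  cat("  temporal:    average", format(x$E_DTa), " maximum", format(x$E_DTm),
      "(time units)\n")
  invisible(x)
}
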