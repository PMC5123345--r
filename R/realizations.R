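#' Realizations of a gene tree inside the species tree
#'
#' A realization maps every internal gene-tree vertex to a grid point of the
#' discretized species tree together with an event type — `"speciation"`
#' (mapped to a species vertex), `"duplication"` or `"transfer"` (mapped to a
#' weighted interior point of a species edge).  A transfer additionally
#' carries the donor species edge (`from`, the edge the vertex itself sits
#' on) and the recipient edge (`to`, where the emigrant child lineage
#' starts), both contemporaneous at the event time.  Species edges are
#' reported by their leaf-set key (sorted descendant species labels joined
#' by `+`).
#'
#' `sample_realization()` draws realizations from the exact conditional
#' distribution given `(G, l, theta)` by preorder stochastic backtracking
#' through the retained dynamic-programming tables; `map_realization()`
#' back-traces the max-product tables instead and returns the maximum a
#' posteriori realization; `enumerate_realizations()` exhaustively lists all
#' realizations with their probability weights (a test oracle, guarded to
#' small instances).
#'
#' @param dp a `dlt_dp` object from [gene_tree_density()] (`mode = "sum"` for
#'   sampling, `mode = "max"` for MAP).
#' @param n number of draws.
#' @return `sample_realization()`: a `dlt_realizations` object (list of
#'   `dlt_realization` data frames with uniform weights);
#'   `map_realization()`: list with `realization` and `log_score`.
#' @export
sample_realization <- function(dp, n = 1) {
  stopifnot(inherits(dp, "dlt_dp"))
  if (dp$mode != "sum") stop("sampling needs a 'sum'-mode DP table")
  samples <- replicate(n, backtrace_one(dp, sample = TRUE)$real,
                       simplify = FALSE)
  new_realizations(samples, dp)
}

#' @rdname sample_realization
#' @export
map_realization <- function(dp) {
  stopifnot(inherits(dp, "dlt_dp"))
  if (dp$mode != "max") stop("MAP needs a 'max'-mode DP table")
  bt <- backtrace_one(dp, sample = FALSE)
  list(realization = bt$real, log_score = dp$log_density)
}

new_realizations <- function(samples, dp) {
  structure(list(samples = samples, vt = dp$vt, grid = dp$grid,
                 topology = vtree_topology_key(dp$vt)),
            class = "dlt_realizations")
}

#' @export
print.dlt_realizations <- function(x, ...) {
  nt <- vapply(x$samples, function(r) sum(r$type == "transfer"), 0)
  cat("Posterior of", length(x$samples), "realizations;",
      "mean transfers:", format(mean(nt)), "\n")
  invisible(x)
}

# weight of a point when used as a child placement: quadrature Delta at
# interior points, 1 at speciation vertices, 0 elsewhere
place_weight <- function(g, pts) {
  ifelse(g$pt_kind[pts] == 3L, g$pt_delta[pts],
         ifelse(g$pt_kind[pts] == 2L, 1, 0))
}

pick <- function(idx, w, sample) {
  if (sample) {
    s <- sum(w)
    if (!(s > 0)) stop("degenerate sampling weights (zero mass)")
    idx[sample.int(length(idx), 1L, prob = w)]
  } else idx[which.max(w)]
}

backtrace_one <- function(dp, sample = TRUE) {
  g <- dp$grid; vt <- dp$vt
  A <- dp$A; D <- dp$D
  p11 <- dp$tables$p11
  del <- dp$theta[["delta"]]; tau <- dp$theta[["tau"]]
  keys <- vtree_clade_keys(vt)
  ekeys <- g$edge_keys
  rows <- vector("list", vt$nvert)

  place_child <- function(c, s) {
    # choose the grid point of internal child c given its lineage starts at s
    cand <- g$below[[s]]
    lf <- dp$lenfacs[[c]][cbind(g$pt_level[cand], rep(g$pt_level[s], length(cand)))]
    w <- p11[s, cand] * lf * place_weight(g, cand) * A[c, cand]
    pick(cand, w, sample)
  }

  visit <- function(u, x) {
    c1 <- vt$children[u, 1]; c2 <- vt$children[u, 2]
    kind <- g$pt_kind[x]
    if (kind == 2L) {
      tg <- g$spec_top[x, 1]; th <- g$spec_top[x, 2]
      w <- c(D[c1, tg] * D[c2, th], D[c2, tg] * D[c1, th])
      ord <- pick(1:2, w, sample)
      starts <- if (ord == 1) c(tg, th) else c(th, tg)
      type <- "speciation"; from <- NA_character_; to <- NA_character_
    } else {
      wdup <- 2 * del * D[c1, x] * D[c2, x]
      prt <- g$partners[[x]]; k <- g$pt_k[x]
      cand_w <- wdup; cand_x2 <- 0L; cand_em <- 0L
      if (k > 1 && length(prt) && tau > 0) {
        mix <- tau / (k - 1)
        w2 <- mix * D[c1, x] * D[c2, prt]   # c2 emigrates
        w1 <- mix * D[c2, x] * D[c1, prt]   # c1 emigrates
        cand_w <- c(wdup, w2, w1)
        cand_x2 <- c(0L, prt, prt)
        cand_em <- c(0L, rep(2L, length(prt)), rep(1L, length(prt)))
      }
      j <- pick(seq_along(cand_w), cand_w, sample)
      if (cand_em[j] == 0L) {
        type <- "duplication"; from <- NA_character_; to <- NA_character_
        starts <- c(x, x)
      } else {
        x2 <- cand_x2[j]
        type <- "transfer"
        from <- ekeys[g$pt_edge[x]]; to <- ekeys[g$pt_edge[x2]]
        starts <- if (cand_em[j] == 2L) c(x, x2) else c(x2, x)
      }
    }
    rows[[u]] <<- data.frame(vertex = u, clade = keys[u], point = x,
                             time = g$pt_time[x], delta = g$pt_delta[x],
                             type = type, from = from, to = to,
                             s1 = starts[1], s2 = starts[2],
                             stringsAsFactors = FALSE)
    for (i in 1:2) {
      cc <- vt$children[u, i]
      if (cc > vt$ntip) visit(cc, place_child(cc, starts[i]))
    }
  }

  st <- dp$stemtip
  cand <- g$below[[st]]
  w <- p11[st, cand] * place_weight(g, cand) * A[vt$root, cand]
  visit(vt$root, pick(cand, w, sample))
  real <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  real <- structure(real, class = c("dlt_realization", "data.frame"),
                    topology = vtree_topology_key(vt))
  list(real = real)
}

#' @export
print.dlt_realization <- function(x, ...) {
  cols <- c("clade", "time", "type", "from", "to")
  if (!all(cols %in% names(x))) {       # column subset: plain frame printing
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat("Realization:", nrow(x), "internal vertices (",
      sum(x$type == "speciation"), "speciation,",
      sum(x$type == "duplication"), "duplication,",
      sum(x$type == "transfer"), "transfer )\n")
  print.data.frame(x[, cols])
  invisible(x)
}

# canonical identity of a realization (placement + typing + recipients)
realization_key <- function(real) {
  o <- order(real$clade)
  paste(real$clade[o], real$point[o], real$type[o],
        ifelse(is.na(real$to[o]), "", real$to[o]),
        sep = ":", collapse = "|")
}

#' Log probability weight of one realization
#'
#' The per-realization factor of the discretized density: event factors,
#' propagation and edge-length factors for every gene edge, and the
#' quadrature interval lengths of its duplication/transfer placements.
#' @param dp a `"sum"`-mode `dlt_dp`.
#' @param real a `dlt_realization` with child start points (as produced by
#'   the samplers or the enumerator).
#' @return log weight (log of the density contribution times Delta(d)).
#' @export
realization_log_score <- function(dp, real) {
  g <- dp$grid; vt <- dp$vt
  p11 <- dp$tables$p11
  del <- dp$theta[["delta"]]; tau <- dp$theta[["tau"]]
  lw <- 0
  byv <- split(real, real$vertex)
  xof <- function(u) byv[[as.character(u)]]$point[1]
  st <- dp$stemtip
  xr <- xof(vt$root)
  lw <- lw + log(p11[st, xr]) + log(place_weight(g, xr))
  for (u in real$vertex) {
    r <- byv[[as.character(u)]]
    x <- r$point
    fac <- switch(r$type, speciation = 1, duplication = 2 * del,
                  transfer = tau / (g$pt_k[x] - 1))
    lw <- lw + log(fac)
    starts <- c(r$s1, r$s2)
    for (i in 1:2) {
      cc <- vt$children[u, i]; s <- starts[i]
      y <- if (cc <= vt$ntip) dp$gcpp$leafpt[cc] else xof(cc)
      lf <- dp$lenfacs[[cc]][g$pt_level[y], g$pt_level[s]]
      lw <- lw + log(p11[s, y]) + log(lf)
      if (cc > vt$ntip) lw <- lw + log(place_weight(g, y))
    }
  }
  lw
}

#' @rdname sample_realization
#' @param gene,leaf_map,grid,theta as in [gene_tree_density()] (the
#'   enumerator recomputes nothing from DP tables beyond the shared
#'   extinction/propagation inputs).
#' @param max_points,max_vertices guards on instance size.
#' @export
enumerate_realizations <- function(gene, leaf_map, grid, theta,
                                   max_points = 60, max_vertices = 9) {
  th <- as_params(theta)
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  if (vt$nvert > max_vertices) stop("gene tree too large to enumerate")
  if (grid$npoints > max_points) stop("grid too large to enumerate")
  tb <- dlt_tables(grid, th)
  p11 <- tb$p11
  g <- grid
  del <- th[["delta"]]; tau <- th[["tau"]]
  m <- th[["m"]]; cv <- th[["cv"]]
  keys <- vtree_clade_keys(vt)
  ekeys <- g$edge_keys
  st_leaf <- match(leaf_map[vt$label], g$tree$label[seq_len(g$tree$ntip)])
  leafpt <- integer(vt$nvert)
  leafpt[seq_len(vt$ntip)] <- g$vertex_pt[st_leaf]

  lenfac <- function(c, y, s) {
    dtm <- g$pt_time[s] - g$pt_time[y]
    if (dtm <= 0) return(0)
    edge_length_density(vt$len[c], dtm, m, cv)
  }
  # returns list of list(rows = data.frame fragment, w = linear weight)
  enum_down <- function(c, s) {
    if (c <= vt$ntip) {
      w <- p11[s, leafpt[c]] * lenfac(c, leafpt[c], s)
      if (w <= 0) return(list())
      return(list(list(rows = NULL, w = w)))
    }
    out <- list()
    for (y in g$below[[s]]) {
      base <- p11[s, y] * lenfac(c, y, s) * place_weight(g, y)
      if (base <= 0) next
      for (ev in enum_event(c, y))
        out[[length(out) + 1L]] <- list(rows = ev$rows, w = base * ev$w)
    }
    out
  }
  cross <- function(u, x, type, from, to, s1, s2, f1, f2, fac) {
    out <- list()
    for (a in f1) for (b in f2) {
      row <- data.frame(vertex = u, clade = keys[u], point = x,
                        time = g$pt_time[x], delta = g$pt_delta[x],
                        type = type, from = from, to = to,
                        s1 = s1, s2 = s2, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <-
        list(rows = rbind(row, a$rows, b$rows), w = fac * a$w * b$w)
    }
    out
  }
  enum_event <- function(u, x) {
    c1 <- vt$children[u, 1]; c2 <- vt$children[u, 2]
    out <- list()
    if (g$pt_kind[x] == 2L) {
      tg <- g$spec_top[x, 1]; th2 <- g$spec_top[x, 2]
      out <- c(out,
        cross(u, x, "speciation", NA, NA, tg, th2,
              enum_down(c1, tg), enum_down(c2, th2), 1),
        cross(u, x, "speciation", NA, NA, th2, tg,
              enum_down(c1, th2), enum_down(c2, tg), 1))
    } else if (g$pt_kind[x] == 3L) {
      out <- c(out, cross(u, x, "duplication", NA, NA, x, x,
                          enum_down(c1, x), enum_down(c2, x), 2 * del))
      k <- g$pt_k[x]
      if (k > 1 && tau > 0) {
        mix <- tau / (k - 1)
        for (x2 in g$partners[[x]]) {
          fr <- ekeys[g$pt_edge[x]]; to <- ekeys[g$pt_edge[x2]]
          out <- c(out,
            cross(u, x, "transfer", fr, to, x, x2,
                  enum_down(c1, x), enum_down(c2, x2), mix),
            cross(u, x, "transfer", fr, to, x2, x,
                  enum_down(c1, x2), enum_down(c2, x), mix))
        }
      }
    }
    out
  }
  stp <- g$top_pt[g$tree$root]
  res <- list()
  for (y in g$below[[stp]]) {
    base <- p11[stp, y] * place_weight(g, y)
    if (base <= 0) next
    for (ev in enum_event(vt$root, y))
      res[[length(res) + 1L]] <- list(rows = ev$rows, w = base * ev$w)
  }
  reals <- lapply(res, function(r)
    structure(r$rows, class = c("dlt_realization", "data.frame"),
              topology = vtree_topology_key(vt)))
  w <- vapply(res, `[[`, 1.0, "w")
  list(realizations = reals, weights = w, total = sum(w),
       keys = vapply(reals, realization_key, ""))
}

#' Summarize a posterior sample of realizations
#'
#' Reports the expected number of transfer events, the posterior probability
#' that each gene vertex (identified by its leaf clade) is a transfer, the
#' posterior probability of each ordered donor/recipient species-edge pair,
#' and the list of pairs at or above `threshold`.
#'
#' @param post a `dlt_realizations` object.
#' @param threshold posterior probability cutoff (inclusive), default 0.5.
#' @return a list of class `dlt_realization_summary`.
#' @export
posterior_summary <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "dlt_realizations"))
  n <- length(post$samples)
  if (n < 1) stop("empty posterior")
  ntr <- vapply(post$samples, function(r) sum(r$type == "transfer"), 0)
  vertex_tab <- list()
  pair_tab <- list()
  for (r in post$samples) {
    tr <- r[r$type == "transfer", , drop = FALSE]
    for (cl in tr$clade) vertex_tab[[cl]] <- (vertex_tab[[cl]] %||% 0) + 1
    if (nrow(tr)) {
      pairs <- unique(paste(tr$from, tr$to, sep = " -> "))
      for (p in pairs) pair_tab[[p]] <- (pair_tab[[p]] %||% 0) + 1
    }
  }
  vertex_prob <- vapply(vertex_tab, function(x) x / n, 0)
  pair_prob <- vapply(pair_tab, function(x) x / n, 0)
  events <- if (length(pair_prob)) {
    sp <- strsplit(names(pair_prob), " -> ", fixed = TRUE)
    data.frame(from = vapply(sp, `[`, "", 1), to = vapply(sp, `[`, "", 2),
               probability = unname(pair_prob), stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(),
                    probability = numeric())
  structure(list(n_samples = n,
                 expected_transfers = mean(ntr),
                 transfer_count_dist = table(ntr) / n,
                 vertex_transfer_prob = vertex_prob,
                 pair_prob = events,
                 threshold = threshold,
                 events = events[events$probability >= threshold, ,
                                 drop = FALSE]),
            class = "dlt_realization_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dlt_realization_summary <- function(x, ...) {
  cat("Realization posterior (", x$n_samples, " samples)\n", sep = "")
  cat("Expected transfer events:", format(x$expected_transfers), "\n")
  if (nrow(x$events)) {
    cat("Transfers with posterior probability >= ", x$threshold, ":\n", sep = "")
    print.data.frame(x$events, row.names = FALSE)
  } else cat("No transfer at posterior probability >=", x$threshold, "\n")
  invisible(x)
}
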