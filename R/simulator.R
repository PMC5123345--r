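#' Simulate a gene family under the DLT process
#'
#' Runs the generative duplication--loss--transfer process over a dated
#' species tree, starting from a single gene lineage at the stem tip and
#' recording the complete ground truth: every event (speciation, duplication,
#' transfer, loss) with its exact continuous time and species edge, and for
#' each transfer the donor (`from`) and recipient (`to`) species edges, the
#' recipient drawn uniformly among the other contemporaneous edges.  When an
#' edge is the only one alive (e.g. the stem), transfers are suppressed.
#'
#' `prune_extinct()` removes extinct subtrees and suppresses the resulting
#' out-degree-1 vertices, yielding the observable gene tree and its true
#' (continuous-time) realization restricted to surviving divergence vertices.
#' A transfer whose within-donor copy dies leaves no vertex in the pruned
#' tree and is therefore not part of the observable truth.
#'
#' @param st a [dated_species_tree].
#' @param theta a [dltrs_params] (only `delta`, `mu`, `tau` are used here).
#' @param lineage_cap abort guard on the number of concurrently alive
#'   lineages.
#' @return `dlt_simulate()`: an object of class `dlt_history` with the full
#'   event table (`full`), the species tree, `theta`, and the pruned
#'   observable side (`pruned`, see `prune_extinct`).
#' @export
dlt_simulate <- function(st, theta, lineage_cap = 10000) {
  th <- as_params(theta)
  delta <- th[["delta"]]; mu <- th[["mu"]]; tau <- th[["tau"]]
  H <- st$time[st$root] + st$stem
  breaks <- sort(unique(c(st$time, H)))
  ptime <- ifelse(is.na(st$parent), H, st$time[st$parent])
  # number of species edges alive strictly inside each inter-break interval
  kmid <- vapply(seq_len(length(breaks) - 1), function(i) {
    tm <- (breaks[i] + breaks[i + 1]) / 2
    sum(st$time <= tm & ptime > tm)
  }, 0L)

  cap <- 256L
  node_parent <- integer(cap); node_type <- character(cap)
  node_edge <- integer(cap); node_time <- numeric(cap)
  node_to <- integer(cap); nn <- 0L
  new_node <- function(parent, type, edge, time, to = NA_integer_) {
    nn <<- nn + 1L
    if (nn > length(node_parent)) {
      node_parent <<- c(node_parent, integer(nn)); node_type <<- c(node_type, character(nn))
      node_edge <<- c(node_edge, integer(nn)); node_time <<- c(node_time, numeric(nn))
      node_to <<- c(node_to, integer(nn))
    }
    node_parent[nn] <<- parent; node_type[nn] <<- type
    node_edge[nn] <<- edge; node_time[nn] <<- time; node_to[nn] <<- to
    nn
  }

  # pending lineages: parent node id, current edge, current time
  sp <- 1L
  pn <- integer(64); pe <- integer(64); pt <- numeric(64)
  pn[1] <- 0L; pe[1] <- st$root; pt[1] <- H
  while (sp > 0L) {
    if (sp > lineage_cap) stop("lineage cap exceeded (runaway growth)")
    par <- pn[sp]; e <- pe[sp]; t <- pt[sp]; sp <- sp - 1L
    repeat {
      iv <- findInterval(t, breaks, left.open = TRUE)  # interval (breaks[iv], breaks[iv+1]]
      tb <- if (iv >= 1) breaks[iv] else 0
      tb <- max(tb, st$time[e])
      k <- if (iv >= 1) kmid[iv] else 1L
      taueff <- if (k > 1L) tau else 0
      rate <- delta + mu + taueff
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (sp + 2L > length(pn)) {
        pn <- c(pn, integer(length(pn))); pe <- c(pe, integer(length(pe)))
        pt <- c(pt, numeric(length(pt)))
      }
      if (t - w <= tb) {
        t <- tb
        if (t > st$time[e] + 1e-15) next   # crossed a k-change boundary only
        # reached the bottom vertex of edge e
        if (e <= st$ntip) { new_node(par, "leaf", e, 0); break }
        nd <- new_node(par, "speciation", e, t)
        ch <- st$children[e, ]
        sp <- sp + 1L; pn[sp] <- nd; pe[sp] <- ch[1]; pt[sp] <- t
        sp <- sp + 1L; pn[sp] <- nd; pe[sp] <- ch[2]; pt[sp] <- t
        break
      }
      t <- t - w
      u <- stats::runif(1) * rate
      if (u < delta) {
        nd <- new_node(par, "duplication", e, t)
        sp <- sp + 1L; pn[sp] <- nd; pe[sp] <- e; pt[sp] <- t
        par <- nd   # continue this loop as the second copy
      } else if (u < delta + mu) {
        new_node(par, "loss", e, t); break
      } else {
        elig <- which(st$time <= t & ptime > t)
        elig <- elig[elig != e]
        f <- elig[sample.int(length(elig), 1L)]
        nd <- new_node(par, "transfer", e, t, to = f)
        sp <- sp + 1L; pn[sp] <- nd; pe[sp] <- f; pt[sp] <- t  # emigrant
        par <- nd   # stay copy continues on e
      }
    }
  }
  full <- data.frame(node = seq_len(nn), parent = node_parent[seq_len(nn)],
                     type = node_type[seq_len(nn)], edge = node_edge[seq_len(nn)],
                     time = node_time[seq_len(nn)], to = node_to[seq_len(nn)],
                     stringsAsFactors = FALSE)
  h <- structure(list(full = full, tree = st, theta = th), class = "dlt_history")
  prune_extinct(h)
}

#' @rdname dlt_simulate
#' @param h a `dlt_history`.
#' @export
prune_extinct <- function(h) {
  full <- h$full; st <- h$tree
  nn <- nrow(full)
  surv <- full$type == "leaf"
  kids <- split(full$node, factor(full$parent, levels = seq_len(nn)))
  for (i in rev(seq_len(nn)))   # children always have larger ids than parents
    if (!surv[i] && full$type[i] != "leaf" && full$type[i] != "loss")
      surv[i] <- any(surv[kids[[i]]])
  nsurv_kids <- vapply(seq_len(nn), function(i) sum(surv[kids[[i]]]), 0L)
  keep <- surv & (full$type == "leaf" | nsurv_kids == 2L)

  ids <- full$node[keep]
  if (!length(ids)) {
    h$pruned <- NULL; h$usable <- FALSE
    return(h)
  }
  # nearest kept ancestor
  kept_anc <- integer(nn)
  ord <- order(full$node)
  for (i in ord) {
    p <- full$parent[i]
    kept_anc[i] <- if (p == 0L) 0L else if (keep[p]) p else kept_anc[p]
  }
  leaves <- ids[full$type[ids] == "leaf"]
  internals <- setdiff(ids, leaves)
  ntipP <- length(leaves)
  if (ntipP < 2L || length(internals) == 0L) {
    h$pruned <- NULL; h$usable <- FALSE
    return(h)
  }
  # vertex ids: tips first, then internals by decreasing time (root first)
  internals <- internals[order(full$time[internals], decreasing = TRUE)]
  vid <- integer(nn)
  vid[leaves] <- seq_len(ntipP)
  vid[internals] <- ntipP + seq_along(internals)
  nv <- ntipP + length(internals)
  parent <- rep(NA_integer_, nv); children <- matrix(NA_integer_, nv, 2)
  for (i in ids) {
    pa <- kept_anc[i]
    if (pa != 0L && !(pa %in% ids)) pa <- 0L
    if (pa != 0L) {
      parent[vid[i]] <- vid[pa]
      slot <- if (is.na(children[vid[pa], 1])) 1L else 2L
      children[vid[pa], slot] <- vid[i]
    }
  }
  rootv <- which(is.na(parent))
  # the kept set has a unique top node (all others have a kept ancestor)
  sp_label <- st$label[full$edge[leaves]]
  lab <- paste0(sp_label, "_", stats::ave(seq_along(leaves), sp_label,
                                          FUN = seq_along))
  vtime <- numeric(nv)
  vtime[vid[ids]] <- full$time[ids]
  vt <- list(ntip = ntipP, nvert = nv, parent = parent, children = children,
             len = rep(NA_real_, nv), label = lab, root = rootv)
  ekeys <- if (st$nvert > 1L) species_edge_keys(st) else st$label[1]
  keys <- vtree_clade_keys(vt)
  ir <- internals
  realization <- data.frame(
    vertex = vid[ir], clade = keys[vid[ir]],
    point = NA_integer_, time = full$time[ir], delta = 0,
    type = full$type[ir],
    from = ifelse(full$type[ir] == "transfer", ekeys[full$edge[ir]], NA),
    to = ifelse(full$type[ir] == "transfer", ekeys[full$to[ir]], NA),
    s1 = NA_integer_, s2 = NA_integer_, stringsAsFactors = FALSE)
  realization <- structure(realization,
                           class = c("dlt_realization", "data.frame"),
                           topology = vtree_topology_key(vt),
                           continuous = TRUE)
  lm <- sp_label; names(lm) <- lab
  h$pruned <- list(vt = vt, vtime = vtime, realization = realization,
                   leaf_map = lm)
  h$usable <- TRUE
  h
}

#' @export
print.dlt_history <- function(x, ...) {
  cat("DLT history:", nrow(x$full), "events;",
      if (isTRUE(x$usable)) paste(x$pruned$vt$ntip, "surviving leaves,",
        sum(x$pruned$realization$type == "transfer"), "observable transfers")
      else "family extinct/unusable", "\n")
  invisible(x)
}

#' Relaxed-clock branch lengths for a simulated family
#'
#' Draws iid per-edge substitution rates from the gamma law with mean `m`
#' and coefficient of variation `cv` and multiplies them onto the edge time
#' durations of the pruned gene tree.
#'
#' @param h a usable `dlt_history`.
#' @param m,cv relaxed-clock parameters.
#' @return `h` with `pruned$vt$len` filled and `pruned$rates` recorded.
#' @export
relax_clock <- function(h, m = h$theta[["m"]], cv = h$theta[["cv"]]) {
  if (!isTRUE(h$usable)) stop("history has no usable pruned tree")
  if (cv <= 0) stop("cv must be > 0")
  vt <- h$pruned$vt
  durs <- rep(NA_real_, vt$nvert)
  for (v in seq_len(vt$nvert)) if (!is.na(vt$parent[v]))
    durs[v] <- h$pruned$vtime[vt$parent[v]] - h$pruned$vtime[v]
  rates <- stats::rgamma(vt$nvert, shape = 1 / cv^2, scale = m * cv^2)
  h$pruned$vt$len <- ifelse(is.na(durs), NA_real_, rates * durs)
  h$pruned$rates <- rates
  h$pruned$durations <- durs
  h
}

#' Simulate sequences down a gene tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' down every edge with the model's transition matrices; no indels.
#'
#' @param gene a rooted binary [ape::phylo] (or internal vtree) with edge
#'   lengths in substitutions/site.
#' @param n_sites number of sites.
#' @param model a [substitution_model].
#' @return a [dlt_msa].
#' @export
simulate_sequences <- function(gene, n_sites,
                               model = substitution_model("JC69")) {
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  stopifnot(n_sites >= 1)
  states <- matrix(0L, vt$nvert, n_sites)
  ordp <- rev(vtree_postorder(vt))          # preorder
  states[vt$root, ] <- sample.int(4, n_sites, replace = TRUE,
                                  prob = model$pi) - 1L
  for (v in ordp) {
    if (v == vt$root) next
    P <- submodel_P(model, vt$len[v])
    ps <- states[vt$parent[v], ]
    out <- integer(n_sites)
    for (s in 0:3) {
      idx <- which(ps == s)
      if (length(idx))
        out[idx] <- sample.int(4, length(idx), replace = TRUE,
                               prob = P[s + 1, ]) - 1L
    }
    states[v, ] <- out
  }
  seqs <- apply(states[seq_len(vt$ntip), , drop = FALSE], 1, function(r)
    paste(c("A", "C", "G", "T")[r + 1], collapse = ""))
  names(seqs) <- vt$label
  dlt_msa(seqs)
}

#' Simulate a complete usable gene family
#'
#' Repeatedly runs [dlt_simulate()] until the pruned family is usable (at
#' least `min_leaves` surviving leaves, at most `max_leaves`), optionally
#' conditioning on at least one observable transfer (`require_transfer`;
#' this biases the process and is recorded in the result), then applies the
#' relaxed clock and simulates sequences.
#'
#' @inheritParams dlt_simulate
#' @param n_sites alignment length.
#' @param model substitution model.
#' @param require_transfer logical: resample until a transfer survives.
#' @param min_leaves,max_leaves usable family size window.
#' @param max_tries resampling guard.
#' @return list with `msa`, `gene` (phylo with lengths), `leaf_map`,
#'   `history` (the accepted `dlt_history`), and `tries`.
#' @export
simulate_family <- function(st, theta, n_sites = 300,
                            model = substitution_model("JC69"),
                            require_transfer = FALSE,
                            min_leaves = 2, max_leaves = 100,
                            max_tries = 1000) {
  th <- as_params(theta)
  if (require_transfer && th[["tau"]] <= 0)
    stop("require_transfer is unsatisfiable with tau = 0")
  for (i in seq_len(max_tries)) {
    h <- dlt_simulate(st, th)
    if (!isTRUE(h$usable)) next
    nl <- h$pruned$vt$ntip
    if (nl < min_leaves || nl > max_leaves) next
    if (require_transfer &&
        !any(h$pruned$realization$type == "transfer")) next
    h <- relax_clock(h)
    msa <- simulate_sequences(h$pruned$vt, n_sites, model)
    return(list(msa = msa, gene = vtree_to_phylo(h$pruned$vt),
                leaf_map = h$pruned$leaf_map, history = h, tries = i))
  }
  stop("no usable family in ", max_tries, " attempts")
}

#' Monte-Carlo extinction frequency of the DLT process
#'
#' Estimates, by straight simulation of the generative process without
#' recording gene trees, the probability that a single lineage starting at
#' the stem tip leaves no descendant at any species leaf.  Serves as the
#' independent cross-check of [solve_extinction()].
#'
#' @inheritParams dlt_simulate
#' @param n number of replicates.
#' @return list with `p_extinct`, its standard error `se`, and `n`.
#' @export
dlt_survival_mc <- function(st, theta, n = 10000) {
  th <- as_params(theta)
  delta <- th[["delta"]]; mu <- th[["mu"]]; tau <- th[["tau"]]
  H <- st$time[st$root] + st$stem
  breaks <- sort(unique(c(st$time, H)))
  ptime <- ifelse(is.na(st$parent), H, st$time[st$parent])
  kmid <- vapply(seq_len(length(breaks) - 1), function(i) {
    tm <- (breaks[i] + breaks[i + 1]) / 2
    sum(st$time <= tm & ptime > tm)
  }, 0L)
  ext <- 0L
  pe <- integer(256); pt <- numeric(256)
  for (rep in seq_len(n)) {
    sp <- 1L; pe[1] <- st$root; pt[1] <- H
    alive <- FALSE
    while (sp > 0L) {
      e <- pe[sp]; t <- pt[sp]; sp <- sp - 1L
      repeat {
        iv <- findInterval(t, breaks, left.open = TRUE)
        tb <- max(if (iv >= 1) breaks[iv] else 0, st$time[e])
        k <- if (iv >= 1) kmid[iv] else 1L
        taueff <- if (k > 1L) tau else 0
        rate <- delta + mu + taueff
        w <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (sp + 2L > length(pe)) { pe <- c(pe, integer(length(pe)))
                                    pt <- c(pt, numeric(length(pt))) }
        if (t - w <= tb) {
          t <- tb
          if (t > st$time[e] + 1e-15) next
          if (e <= st$ntip) { alive <- TRUE; sp <- 0L }   # survival decided
          else {
            ch <- st$children[e, ]
            sp <- sp + 1L; pe[sp] <- ch[1]; pt[sp] <- t
            sp <- sp + 1L; pe[sp] <- ch[2]; pt[sp] <- t
          }
          break
        }
        t <- t - w
        u <- stats::runif(1) * rate
        if (u < delta) {
          sp <- sp + 1L; pe[sp] <- e; pt[sp] <- t
        } else if (u < delta + mu) break
        else {
          elig <- which(st$time <= t & ptime > t)
          elig <- elig[elig != e]
          f <- elig[sample.int(length(elig), 1L)]
          sp <- sp + 1L; pe[sp] <- f; pt[sp] <- t
        }
        if (sp > 5000L) { alive <- TRUE; sp <- 0L; break }  # cap: treat as surviving
      }
      if (alive) break
    }
    if (!alive) ext <- ext + 1L
  }
  p <- ext / n
  list(p_extinct = p, se = sqrt(p * (1 - p) / n), n = n)
}
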