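#' Control settings for a DLTRS fit
#'
#' @param iterations total MCMC iterations.
#' @param thinning keep every `thinning`-th state (plus the initial one).
#' @param resolution discretization resolution (sub-intervals per time slice).
#' @param moves proposal mixture weights over `topology` (NNI), `length`
#'   (multiplicative log-normal on one gene edge) and `parameter`
#'   (multiplicative log-normal on one of delta, mu, tau, m, cv).
#' @param sd_length,sd_param log-scale proposal standard deviations.
#' @param bounds uniform prior supports; the prior over theta is uniform and
#'   independent, made proper by these bounds.
#' @param init_theta optional [dltrs_params] starting value; default is the
#'   midpoint of each bound.
#' @param fixed names of parameters held fixed at their initial values.
#' @param target `"posterior"`; `"prior"` drops the sequence likelihood
#'   (targeting `p(G, l | theta, S) p(theta)`); `"flat"` drops both model
#'   factors, so the chain targets the prior `p(theta)` alone (used by
#'   prior-recovery checks).
#' @param ode_tol per-slice ODE tolerance.
#' @param model a [substitution_model].
#' @return a list of class `dltrs_control`.
#' @export
dltrs_control <- function(iterations = 20000,
                          thinning = max(1L, iterations %/% 1000L),
                          resolution = 10,
                          moves = c(topology = 0.3, length = 0.4,
                                    parameter = 0.3),
                          sd_length = 0.5, sd_param = 0.5,
                          bounds = list(delta = c(0, 10), mu = c(0, 10),
                                        tau = c(0, 10), m = c(1e-6, 10),
                                        cv = c(1e-6, 5)),
                          init_theta = NULL, fixed = character(),
                          target = c("posterior", "prior", "flat"),
                          ode_tol = 1e-6,
                          model = substitution_model("JC69")) {
  target <- match.arg(target)
  stopifnot(iterations >= 1, thinning >= 1, all(moves >= 0), sum(moves) > 0)
  structure(list(iterations = as.integer(iterations),
                 thinning = as.integer(thinning),
                 resolution = resolution, moves = moves / sum(moves),
                 sd_length = sd_length, sd_param = sd_param,
                 bounds = bounds, init_theta = init_theta, fixed = fixed,
                 target = target, ode_tol = ode_tol, model = model),
            class = "dltrs_control")
}

# multiplicative log-normal proposal; Hastings term is log(x'/x)
mh_propose_scale <- function(x, sd) {
  xn <- x * exp(sd * stats::rnorm(1))
  list(value = xn, log_hastings = log(xn / x))
}

#' Generic scalar Metropolis-Hastings chain
#'
#' Runs a chain on a positive scalar with the same multiplicative log-normal
#' kernel the model fit uses.  Mainly a verification utility: against a known
#' target density the chain's moments are checkable in closed form.
#'
#' @param log_target function of one positive scalar.
#' @param init starting value.
#' @param n iterations.
#' @param sd proposal log-scale sd.
#' @return numeric vector of sampled values.
#' @export
mh_chain_scalar <- function(log_target, init, n, sd = 0.5) {
  out <- numeric(n)
  x <- init; lt <- log_target(x)
  for (i in seq_len(n)) {
    pr <- mh_propose_scale(x, sd)
    ltn <- log_target(pr$value)
    if (is.finite(ltn) &&
        log(stats::runif(1)) < ltn - lt + pr$log_hastings) {
      x <- pr$value; lt <- ltn
    }
    out[i] <- x
  }
  out
}

init_gene_tree <- function(msa) {
  n <- length(msa$labels)
  chars <- matrix(c("a", "c", "g", "t", "n")[msa$codes + 1], nrow = n,
                  dimnames = list(msa$labels, NULL))
  dna <- ape::as.DNAbin(chars)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  mx <- suppressWarnings(max(d[is.finite(d)]))
  if (!is.finite(mx) || mx <= 0) mx <- 0.5
  d[!is.finite(d)] <- 2 * mx
  d[d <= 0] <- 1e-4
  phy <- tryCatch({
    p <- ape::nj(d)
    p <- phangorn::midpoint(p)
    ape::multi2di(p)
  }, error = function(e) phangorn::upgma(d))
  phy$edge.length[is.na(phy$edge.length) | phy$edge.length < 1e-4] <- 1e-4
  phy
}

#' Fit the DLTRS model to one gene family
#'
#' Samples the posterior \eqn{p(G, l, \theta | D, S) \propto
#' P(D | G, l)\, p(G, l | \theta, S)\, p(\theta)} by Metropolis-Hastings over
#' gene-tree topologies (NNI), edge lengths and model parameters.  The
#' normalizing constant is never evaluated — it cancels in the acceptance
#' ratio.  The sequence factor uses the peeling algorithm; the gene-tree
#' factor the discretized DLT dynamic programming.
#'
#' @param msa a [dlt_msa] (or FASTA path).
#' @param species_tree a [dated_species_tree] (or newick path).
#' @param leaf_map named character vector (or TSV path) mapping gene leaves
#'   to species leaves.
#' @param control a [dltrs_control].
#' @param seed optional RNG seed; a seeded run is exactly reproducible.
#' @param init_gene optional starting [ape::phylo] gene tree (default:
#'   neighbour-joining on JC distances, midpoint-rooted).
#' @return an object of class `dltrs`: the thinned trace (data frame), the
#'   best-seen state, the MAP topology, acceptance rates, burn-in index and
#'   all inputs.  Methods: `print`, `summary`, `coef`, `logLik`, `plot`,
#'   `simulate`, and [realizations()].
#' @export
dltrs <- function(msa, species_tree, leaf_map, control = dltrs_control(),
                  seed = NULL, init_gene = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(msa)) msa <- read_fasta(msa)
  if (is.character(species_tree)) species_tree <- read_species_tree(species_tree)
  if (is.character(leaf_map) && is.null(names(leaf_map)))
    leaf_map <- read_leaf_map(leaf_map)
  stopifnot(inherits(msa, "dlt_msa"), inherits(species_tree, "dated_species_tree"))
  check_leaf_map(leaf_map, msa$labels, species_tree)
  ctl <- control

  grid <- discretize(species_tree, ctl$resolution)
  gc <- grid_cpp(grid)
  attr(grid, "cpp") <- gc
  stemtip <- grid$top_pt[species_tree$root]

  phy0 <- if (is.null(init_gene)) init_gene_tree(msa) else init_gene
  vt <- as_vtree(phy0)
  check_leaf_map(leaf_map, vt$label, species_tree)
  pat <- msa_patterns(msa, vt$label)
  modcpp <- submodel_cpp(ctl$model)

  bounds <- ctl$bounds
  theta <- if (is.null(ctl$init_theta))
    dltrs_params(mean(bounds$delta), mean(bounds$mu), mean(bounds$tau),
                 mean(bounds$m), mean(bounds$cv))
  else as_params(ctl$init_theta)
  pnames <- c("delta", "mu", "tau", "m", "cv")
  free <- setdiff(pnames, ctl$fixed)

  sp_leaf <- match(leaf_map[vt$label[seq_len(vt$ntip)]],
                   species_tree$label[seq_len(species_tree$ntip)])
  leafpt0 <- grid$vertex_pt[sp_leaf]
  build_gene <- function(vt) {
    post <- vtree_postorder(vt)
    leafpt <- integer(vt$nvert); leafpt[seq_len(vt$ntip)] <- leafpt0
    list(M = vt$nvert,
         children1 = ifelse(is.na(vt$children[, 1]), 0L, vt$children[, 1]),
         children2 = ifelse(is.na(vt$children[, 2]), 0L, vt$children[, 2]),
         postorder = post[post > vt$ntip], root = vt$root, leafpt = leafpt,
         tiprow = c(seq_len(vt$ntip), integer(vt$nvert - vt$ntip)))
  }

  use_dens <- ctl$target != "flat"
  use_peel <- ctl$target == "posterior"
  make_tables <- function(th)
    cpp_dlt_tables(gc, th[["delta"]], th[["mu"]], th[["tau"]], ctl$ode_tol)
  make_lf <- function(v, l, th) lenfac_fast(l, grid, th[["m"]], th[["cv"]])
  eval_dens <- function(gene, lf, tabs, th) {
    if (!use_dens) return(0)
    cpp_dlt_density(gc, tabs$p11, gene, th[["delta"]], th[["tau"]], lf, 0L,
                    stemtip, FALSE)$logdens
  }
  eval_peel <- function(gene, lens) {
    if (!use_peel) return(0)
    cpp_peel(pat$patterns, pat$weights, gene, lens, modcpp)
  }

  gene <- build_gene(vt)
  lens <- vt$len; lens[vt$root] <- 0
  tabs <- make_tables(theta)
  lf <- lapply(seq_len(vt$nvert), function(v)
    if (v == vt$root) matrix(0, 1, 1) else make_lf(v, lens[v], theta))
  dens <- eval_dens(gene, lf, tabs, theta)
  peel <- eval_peel(gene, lens)

  nit <- ctl$iterations; thin <- ctl$thinning
  nrec <- nit %/% thin + 1L
  rec <- list(iteration = integer(nrec), delta = numeric(nrec),
              mu = numeric(nrec), tau = numeric(nrec), m = numeric(nrec),
              cv = numeric(nrec), log_seq = numeric(nrec),
              log_tree = numeric(nrec), newick = character(nrec))
  ri <- 0L
  record <- function(i) {
    ri <<- ri + 1L
    rec$iteration[ri] <<- i
    rec$delta[ri] <<- theta[["delta"]]; rec$mu[ri] <<- theta[["mu"]]
    rec$tau[ri] <<- theta[["tau"]]; rec$m[ri] <<- theta[["m"]]
    rec$cv[ri] <<- theta[["cv"]]
    rec$log_seq[ri] <<- peel; rec$log_tree[ri] <<- dens
    rec$newick[ri] <<- vtree_newick(vt)
  }
  record(0L)
  best <- list(logpost = peel + dens, vt = vt, lens = lens, theta = theta)
  prop_n <- c(topology = 0, length = 0, parameter = 0)
  acc_n <- prop_n
  mvn <- names(ctl$moves)
  movewts <- ctl$moves
  if (vt$ntip < 3) { movewts["topology"] <- 0; movewts <- movewts / sum(movewts) }
  internals <- setdiff(seq.int(vt$ntip + 1L, vt$nvert), vt$root)
  nonroot <- setdiff(seq_len(vt$nvert), vt$root)

  kinds <- mvn[sample.int(3L, nit, replace = TRUE, prob = movewts)]
  for (i in seq_len(nit)) {
    kind <- kinds[i]
    prop_n[kind] <- prop_n[kind] + 1
    logh <- 0
    if (kind == "topology") {
      vtn <- vt
      u <- internals[sample.int(length(internals), 1L)]
      p <- vtn$parent[u]
      slot_p <- which(vtn$children[p, ] != u)
      sib <- vtn$children[p, slot_p]
      ci <- sample.int(2L, 1L)
      cc <- vtn$children[u, ci]
      vtn$children[u, ci] <- sib; vtn$parent[sib] <- u
      vtn$children[p, slot_p] <- cc; vtn$parent[cc] <- p
      gene_n <- build_gene(vtn)
      dens_n <- eval_dens(gene_n, lf, tabs, theta)
      peel_n <- eval_peel(gene_n, lens)
      if (accept(peel_n + dens_n, peel + dens, logh)) {
        vt <- vtn; gene <- gene_n; dens <- dens_n; peel <- peel_n
        acc_n[kind] <- acc_n[kind] + 1
      }
    } else if (kind == "length") {
      v <- nonroot[sample.int(length(nonroot), 1L)]
      pr <- mh_propose_scale(lens[v], ctl$sd_length)
      logh <- pr$log_hastings
      lens_n <- lens; lens_n[v] <- pr$value
      lf_n <- lf; lf_n[[v]] <- make_lf(v, pr$value, theta)
      dens_n <- eval_dens(gene, lf_n, tabs, theta)
      peel_n <- eval_peel(gene, lens_n)
      if (accept(peel_n + dens_n, peel + dens, logh)) {
        lens <- lens_n; lf <- lf_n; dens <- dens_n; peel <- peel_n
        vt$len <- replace(vt$len, v, pr$value)
        acc_n[kind] <- acc_n[kind] + 1
      }
    } else {
      pn <- free[sample.int(length(free), 1L)]
      pr <- mh_propose_scale(theta[[pn]], ctl$sd_param)
      b <- bounds[[pn]]
      if (pr$value >= b[1] && pr$value <= b[2]) {
        logh <- pr$log_hastings
        thn <- theta; thn[[pn]] <- pr$value
        tabs_n <- if (use_dens && pn %in% c("delta", "mu", "tau"))
          make_tables(thn) else tabs
        lf_n <- if (use_dens && pn %in% c("m", "cv"))
          lapply(seq_len(vt$nvert), function(v)
            if (v == vt$root) matrix(0, 1, 1) else make_lf(v, lens[v], thn))
        else lf
        dens_n <- eval_dens(gene, lf_n, tabs_n, thn)
        if (accept(peel + dens_n, peel + dens, logh)) {
          theta <- thn; tabs <- tabs_n; lf <- lf_n; dens <- dens_n
          acc_n[kind] <- acc_n[kind] + 1
        }
      }
    }
    if (peel + dens > best$logpost) {
      best <- list(logpost = peel + dens, vt = vt, lens = lens, theta = theta)
    }
    if (i %% thin == 0L) record(i)
  }

  trace <- data.frame(rec[c("iteration", "delta", "mu", "tau", "m", "cv",
                            "log_seq", "log_tree")],
                      stringsAsFactors = FALSE)
  trace$log_post <- trace$log_seq + trace$log_tree
  trace$newick <- rec$newick
  burn <- burnin_maxess(trace$log_post)
  post <- trace[seq.int(burn, nrow(trace)), , drop = FALSE]
  topo <- vapply(post$newick, function(s)
    vtree_topology_key(as_vtree(ape::read.tree(text = s))), "",
    USE.NAMES = FALSE)
  tt <- sort(table(topo), decreasing = TRUE)
  cand <- names(tt)[tt == max(tt)]
  map_key <- if (length(cand) == 1L) cand else {
    sc <- vapply(cand, function(k) mean(post$log_post[topo == k]), 0)
    cand[which.max(sc)]
  }
  map_row <- which(topo == map_key)[1] + burn - 1L

  structure(list(trace = trace, burnin = burn,
                 map_topology = map_key,
                 map_support = unname(max(tt)) / length(topo),
                 map_tree = ape::read.tree(text = trace$newick[map_row]),
                 topology_post = topo,
                 best = best,
                 acceptance = ifelse(prop_n > 0, acc_n / prop_n, NA),
                 species_tree = species_tree, grid = grid, msa = msa,
                 leaf_map = leaf_map, control = ctl, seed = seed,
                 stemtip = stemtip),
            class = "dltrs")
}

accept <- function(lp_new, lp_old, logh) {
  if (!is.finite(lp_new)) return(FALSE)
  lp_new - lp_old + logh >= 0 || log(stats::runif(1)) < lp_new - lp_old + logh
}

#' @export
print.dltrs <- function(x, ...) {
  cat("DLTRS fit:", length(x$msa$labels), "gene leaves on",
      x$species_tree$ntip, "species;",
      x$control$iterations, "iterations, thinning", x$control$thinning, "\n")
  cat("MAP topology (posterior support ",
      format(x$map_support, digits = 3), "): ", x$map_topology, "\n", sep = "")
  print(coef(x))
  invisible(x)
}

#' @export
coef.dltrs <- function(object, ...) {
  tr <- object$trace[seq.int(object$burnin, nrow(object$trace)), ]
  vapply(tr[c("delta", "mu", "tau", "m", "cv")], mean, 0)
}

#' @export
logLik.dltrs <- function(object, ...) {
  structure(object$best$logpost, df = 5L, class = "logLik")
}

#' @export
summary.dltrs <- function(object, ...) {
  tr <- object$trace[seq.int(object$burnin, nrow(object$trace)), ]
  qs <- t(vapply(tr[c("delta", "mu", "tau", "m", "cv")],
                 stats::quantile, numeric(3), probs = c(0.025, 0.5, 0.975)))
  out <- list(theta = data.frame(mean = coef(object), qs, check.names = FALSE),
              map_topology = object$map_topology,
              map_support = object$map_support,
              acceptance = object$acceptance,
              burnin = object$burnin,
              n_samples = nrow(tr),
              diagnostics = tryCatch(diagnostics(object),
                                     error = function(e) NULL))
  class(out) <- "summary.dltrs"
  out
}

#' @export
print.summary.dltrs <- function(x, ...) {
  cat("Posterior over theta (", x$n_samples, " thinned samples after burn-in ",
      x$burnin, "):\n", sep = "")
  print(format(x$theta, digits = 4))
  cat("MAP topology (support ", format(x$map_support, digits = 3), "): ",
      x$map_topology, "\n", sep = "")
  cat("Acceptance rates:", paste(names(x$acceptance),
                                 format(x$acceptance, digits = 2),
                                 collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

#' @export
plot.dltrs <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("delta", "mu", "tau", "m", "cv", "log_post")) {
    graphics::plot(tr$iteration, tr[[p]], type = "l", xlab = "iteration",
                   ylab = p, main = p)
    graphics::abline(v = tr$iteration[x$burnin], col = 2, lty = 2)
  }
  invisible(x)
}

#' @export
simulate.dltrs <- function(object, nsim = 1, seed = NULL, n_sites = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- do.call(dltrs_params, as.list(coef(object)))
  if (is.null(n_sites)) n_sites <- object$msa$nsite
  replicate(nsim,
            simulate_family(object$species_tree, th, n_sites = n_sites,
                            model = object$control$model),
            simplify = FALSE)
}

#' Posterior realizations from a fitted model
#'
#' Draws realizations post hoc for retained trace samples: for each selected
#' sample `(G, l, theta)` the DP tables are rebuilt and `draws_per_sample`
#' realizations are drawn from the exact conditional distribution
#' (Rao-Blackwellised sampling).  By default only samples whose topology is
#' the MAP topology are used.
#'
#' @param fit a [dltrs] object.
#' @param max_samples cap on the number of trace samples used.
#' @param draws_per_sample realization draws per trace sample.
#' @param topology `"map"` (default) or `"all"`.
#' @return a `dlt_realizations` posterior.
#' @export
realizations <- function(fit, max_samples = 200, draws_per_sample = 1,
                         topology = c("map", "all")) {
  topology <- match.arg(topology)
  stopifnot(inherits(fit, "dltrs"))
  tr <- fit$trace[seq.int(fit$burnin, nrow(fit$trace)), ]
  if (topology == "map") tr <- tr[fit$topology_post == fit$map_topology, ]
  if (nrow(tr) < 1) stop("no post-burn-in samples with the requested topology")
  if (nrow(tr) > max_samples)
    tr <- tr[round(seq(1, nrow(tr), length.out = max_samples)), ]
  samples <- list()
  dp1 <- NULL
  for (i in seq_len(nrow(tr))) {
    gt <- ape::read.tree(text = tr$newick[i])
    th <- dltrs_params(tr$delta[i], tr$mu[i], tr$tau[i], tr$m[i], tr$cv[i])
    dp <- gene_tree_density(gt, fit$leaf_map, fit$grid, th,
                            tol = fit$control$ode_tol)
    if (is.null(dp1)) dp1 <- dp
    for (j in seq_len(draws_per_sample))
      samples[[length(samples) + 1L]] <- backtrace_one(dp, sample = TRUE)$real
  }
  new_realizations(samples, dp1)
}
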