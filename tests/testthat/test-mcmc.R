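test_that("a flat target with a symmetric-in-log kernel is always accepted", {
  set.seed(81)
  # log target constant in log-space measure: pi(x) dx ~ 1/x (so that the
  # multiplicative kernel's Hastings term cancels exactly)
  x <- mh_chain_scalar(function(x) -log(x), 1, 500, sd = 0.4)
  expect_true(all(x[-1] != x[-length(x)]))   # every proposal accepted
})

test_that("the multiplicative kernel samples a Gamma(2,1) target correctly", {
  set.seed(82)
  x <- mh_chain_scalar(function(x) stats::dgamma(x, 2, 1, log = TRUE),
                       2, 1e5, sd = 0.7)
  n_eff <- ess(x)
  se <- sqrt(2) / sqrt(n_eff)    # Var of Gamma(2,1) is 2
  expect_lt(abs(mean(x) - 2), 3 * se)
})

test_that("with a flat model the parameter marginals recover the prior", {
  set.seed(83)
  S <- fix_cherry()
  msa <- dlt_msa(c(g1 = "ACGT", g2 = "ACGA"))
  lm <- c(g1 = "A", g2 = "B")
  ctl <- dltrs_control(iterations = 60000, thinning = 30, resolution = 2,
                       target = "flat",
                       moves = c(topology = 0, length = 0, parameter = 1),
                       sd_param = 1.2)
  fit <- dltrs(msa, S, lm, control = ctl, seed = 831)
  tr <- fit$trace[-(1:500), ]    # generous burn-in from the midpoint start
  # sub-thin so the Kolmogorov-Smirnov test sees near-independent draws
  idx <- seq(1, nrow(tr), by = 8)
  expect_gt(stats::ks.test(tr$delta[idx], "punif", 0, 10)$p.value, 0.01)
  expect_gt(stats::ks.test(tr$cv[idx], "punif", 1e-6, 5)$p.value, 0.01)
  expect_lt(abs(mean(tr$mu) - 5), 0.3)
  expect_lt(abs(mean(tr$tau) - 5), 0.3)
})

test_that("seeded fits are exactly reproducible", {
  set.seed(84)
  S <- fix_3leaf()
  fam <- simulate_family(S, dltrs_params(0.3, 0.3, 0.3), n_sites = 60,
                         max_leaves = 6)
  ctl <- dltrs_control(iterations = 800, thinning = 10, resolution = 2)
  f1 <- dltrs(fam$msa, S, fam$leaf_map, control = ctl, seed = 99)
  f2 <- dltrs(fam$msa, S, fam$leaf_map, control = ctl, seed = 99)
  expect_identical(f1$trace, f2$trace)
  f3 <- dltrs(fam$msa, S, fam$leaf_map, control = ctl, seed = 100)
  expect_false(identical(f3$trace, f1$trace))
})

test_that("topology sampling matches exact finite-state enumeration", {
  # 3-leaf family with fixed lengths and theta: NNI moves walk a 3-state
  # space whose stationary law is the normalized joint density; compare the
  # chain's topology frequencies with the exact values
  set.seed(85)
  S <- fix_3leaf()
  th0 <- dltrs_params(0.4, 0.4, 0.4, 1, 0.5)
  fam <- simulate_family(S, th0, n_sites = 20, min_leaves = 3, max_leaves = 3)
  g <- discretize(S, 2)
  lm <- fam$leaf_map
  labs <- fam$msa$labels
  lens <- c(0.3, 0.5, 0.8, 0.4)        # leaf1, leaf2, leaf3, cherry
  mk <- function(out) {
    ins <- setdiff(1:3, out)
    txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g);",
                   labs[ins[1]], lens[ins[1]], labs[ins[2]], lens[ins[2]],
                   lens[4], labs[out], lens[out])
    ape::read.tree(text = txt)
  }
  dens <- vapply(1:3, function(out) {
    gt <- mk(out)
    peeling_likelihood(fam$msa, gt) +
      gene_tree_density(gt, lm, g, th0)$log_density
  }, 0)
  p_exact <- exp(dens - max(dens)); p_exact <- p_exact / sum(p_exact)
  names(p_exact) <- vapply(1:3, function(out)
    dltrs:::vtree_topology_key(dltrs:::as_vtree(mk(out))), "")
  ctl <- dltrs_control(iterations = 30000, thinning = 10, resolution = 2,
                       moves = c(topology = 1, length = 0, parameter = 0),
                       init_theta = th0, fixed = c("delta", "mu", "tau",
                                                   "m", "cv"))
  fit <- dltrs(fam$msa, S, lm, control = ctl, seed = 851, init_gene = mk(1))
  obs <- table(factor(fit$topology_post, levels = names(p_exact)))
  expect_gt(chisq_pooled(as.numeric(obs), p_exact * sum(obs)), 0.01)
})

test_that("fits expose coherent summaries, methods and trace output", {
  set.seed(86)
  S <- fix_3leaf()
  fam <- simulate_family(S, dltrs_params(0.3, 0.3, 0.3), n_sites = 80,
                         max_leaves = 6)
  ctl <- dltrs_control(iterations = 12000, thinning = 10, resolution = 2)
  fit <- dltrs(fam$msa, S, fam$leaf_map, control = ctl, seed = 7)
  expect_s3_class(fit, "dltrs")
  expect_equal(nrow(fit$trace), 12000 / 10 + 1)
  co <- coef(fit)
  expect_named(co, c("delta", "mu", "tau", "m", "cv"))
  expect_true(all(is.finite(co)))
  su <- summary(fit)
  expect_s3_class(su, "summary.dltrs")
  expect_true(fit$map_support > 0 && fit$map_support <= 1)
  expect_true(is.finite(logLik(fit)))
  # trace round-trips through the TSV writer
  f <- tempfile(fileext = ".tsv")
  write_trace(fit, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$log_tree, fit$trace$log_tree, tolerance = 1e-6)
  # realizations from the fit are well-formed
  post <- realizations(fit, max_samples = 30)
  expect_s3_class(post, "dlt_realizations")
  expect_true(length(post$samples) >= 1)
  su2 <- posterior_summary(post)
  expect_true(su2$expected_transfers >= 0)
})
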