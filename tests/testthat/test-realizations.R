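test_that("vanishing rates force the unique speciation-only realization", {
  S <- fix_3leaf()
  g <- discretize(S, 4)
  gt <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  lm <- c(a = "A", b = "B", c = "C")
  th <- dltrs_params(1e-12, 1e-12, 1e-12, 1, 0.5)
  dp <- gene_tree_density(gt, lm, g, th)
  set.seed(51)
  r <- sample_realization(dp, 3)
  for (s in r$samples) expect_true(all(s$type == "speciation"))
  dpm <- gene_tree_density(gt, lm, g, th, mode = "max")
  expect_true(all(map_realization(dpm)$realization$type == "speciation"))
})

test_that("sampled realizations follow the enumerated distribution", {
  set.seed(52)
  S <- fix_cherry()
  g <- discretize(S, 2)
  gt <- ape::read.tree(text = "(a:0.4,b:0.7);")
  lm <- c(a = "A", b = "B")
  th <- dltrs_params(0.4, 0.3, 0.6, 1, 0.8)
  en <- enumerate_realizations(gt, lm, g, th)
  dp <- gene_tree_density(gt, lm, g, th)
  expect_equal(dp$log_density, log(en$total), tolerance = 1e-10)
  n <- 3000
  dr <- sample_realization(dp, n)
  keys <- vapply(dr$samples, dltrs:::realization_key, "")
  obs <- table(factor(keys, levels = en$keys))
  expect_gt(chisq_pooled(as.numeric(obs), en$weights / en$total * n), 0.01)
})

test_that("MAP realization dominates sampled realizations", {
  set.seed(53)
  S <- fix_3leaf()
  g <- discretize(S, 2)
  gt <- ape::read.tree(text = "((a:0.3,c:0.5):0.4,b:0.9);")
  lm <- c(a = "A", b = "B", c = "C")
  th <- dltrs_params(0.3, 0.4, 0.6, 0.8, 0.6)
  en <- enumerate_realizations(gt, lm, g, th)
  dpm <- gene_tree_density(gt, lm, g, th, mode = "max")
  mp <- map_realization(dpm)
  i <- which.max(en$weights)
  expect_equal(mp$log_score, log(en$weights[i]), tolerance = 1e-10)
  expect_identical(dltrs:::realization_key(mp$realization), en$keys[i])
  dp <- gene_tree_density(gt, lm, g, th)
  draws <- sample_realization(dp, 200)
  sc <- vapply(draws$samples, function(d) realization_log_score(dp, d), 0)
  expect_true(all(sc <= mp$log_score + 1e-9))
})

test_that("every draw satisfies the realization invariants", {
  set.seed(54)
  ek_all <- NULL
  for (rep in 1:6) {
    S <- rand_species_tree(3, h = 1.5)
    g <- discretize(S, 3)
    fam <- NULL
    while (is.null(fam)) fam <- tryCatch(
      simulate_family(S, dltrs_params(0.3, 0.3, 0.5), n_sites = 10,
                      max_leaves = 5),
      error = function(e) NULL)
    th <- dltrs_params(0.4, 0.3, 0.5, 1, 0.6)
    dp <- gene_tree_density(fam$gene, fam$leaf_map, g, th)
    if (!is.finite(dp$log_density)) next
    vt <- dp$vt
    for (d in sample_realization(dp, 10)$samples) {
      # exactly one event type per internal vertex, full partition
      expect_equal(nrow(d), vt$nvert - vt$ntip)
      expect_true(all(d$type %in% c("speciation", "duplication", "transfer")))
      # speciation <=> species-vertex grid point
      expect_equal(d$type == "speciation", g$pt_kind[d$point] == 2L)
      # transfers carry distinct contemporaneous donor/recipient
      tr <- d[d$type == "transfer", ]
      if (nrow(tr)) {
        expect_true(all(tr$from != tr$to))
        ek <- g$edge_keys
        for (j in seq_len(nrow(tr))) {
          ce <- contemporaneous_edges(S, tr$time[j])
          expect_true(all(c(tr$from[j], tr$to[j]) %in% ek[ce]))
        }
      }
      # children never map to the same time as their parent, never above
      for (u in d$vertex) {
        for (cc in vt$children[u, ]) if (cc > vt$ntip) {
          expect_lt(d$time[d$vertex == cc], d$time[d$vertex == u])
        }
      }
    }
  }
})

test_that("posterior expectations match exact enumeration (Rao-Blackwell)", {
  set.seed(55)
  S <- fix_cherry()
  g <- discretize(S, 2)
  gt <- ape::read.tree(text = "(a:0.4,b:0.7);")
  lm <- c(a = "A", b = "B")
  th <- dltrs_params(0.4, 0.3, 0.6, 1, 0.8)
  en <- enumerate_realizations(gt, lm, g, th)
  ntr <- vapply(en$realizations, function(r) sum(r$type == "transfer"), 0)
  exact <- sum(ntr * en$weights) / en$total
  dp <- gene_tree_density(gt, lm, g, th)
  dr <- sample_realization(dp, 4000)
  est <- mean(vapply(dr$samples, function(r) sum(r$type == "transfer"), 0))
  mc_se <- stats::sd(vapply(dr$samples, function(r)
    sum(r$type == "transfer"), 0)) / sqrt(4000)
  expect_lt(abs(est - exact), 4 * mc_se)
})

test_that("posterior summaries aggregate transfers correctly", {
  S <- fix_cherry()
  g <- discretize(S, 2)
  base <- data.frame(vertex = 3L, clade = "a+b", point = 5L, time = 0.5,
                     delta = 0.25, type = "transfer", from = "A", to = "B",
                     s1 = 1L, s2 = 2L, stringsAsFactors = FALSE)
  spec <- base; spec$type <- "speciation"; spec$from <- NA; spec$to <- NA
  mk <- function(df) structure(df, class = c("dlt_realization", "data.frame"),
                               topology = "(a,b)")
  post <- structure(list(samples = list(mk(base), mk(base), mk(base),
                                        mk(spec)),
                         vt = NULL, grid = g, topology = "(a,b)"),
                    class = "dlt_realizations")
  su <- posterior_summary(post)
  expect_equal(su$expected_transfers, 0.75)
  expect_equal(unname(su$vertex_transfer_prob["a+b"]), 0.75)
  expect_equal(su$pair_prob$probability, 0.75)
  expect_equal(nrow(su$events), 1)       # 0.75 >= 0.5 (inclusive threshold)
  su2 <- posterior_summary(post, threshold = 0.8)
  expect_equal(nrow(su2$events), 0)
  # all-identical posterior: certainty
  post$samples <- list(mk(base), mk(base))
  su3 <- posterior_summary(post)
  expect_equal(su3$expected_transfers, 1)
  expect_equal(su3$pair_prob$probability, 1)
  expect_error(posterior_summary(structure(list(samples = list()),
                                           class = "dlt_realizations")),
               "empty")
})
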