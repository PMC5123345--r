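test_that("with all rates zero the gene tree mirrors the species tree", {
  set.seed(41)
  S <- fix_3leaf()
  h <- dlt_simulate(S, dltrs_params(0, 0, 0))
  expect_true(h$usable)
  expect_equal(h$pruned$vt$ntip, 3)
  expect_equal(attr(h$pruned$realization, "topology"),
               "((A_1,B_1),C_1)")
  expect_true(all(h$pruned$realization$type == "speciation"))
})

test_that("pure-birth leaf counts match the Yule expectation", {
  set.seed(42)
  S <- single_edge_tree(2)
  counts <- replicate(3000, {
    h <- dlt_simulate(S, dltrs_params(0.5, 0, 0))
    sum(h$full$type == "leaf")
  })
  # E = e^{delta t}, Var = e^{2 delta t}(1 - e^{-delta t})
  se <- sqrt(exp(2) * (1 - exp(-1)) / 3000)
  expect_lt(abs(mean(counts) - exp(1)), 3 * se)
})

test_that("transfer recipients are uniform over eligible edges", {
  set.seed(43)
  S <- fix_3leaf()
  eA <- match("A", S$label); eB <- match("B", S$label)
  eC <- match("C", S$label)
  recips <- integer(0)
  for (i in 1:600) {
    h <- dlt_simulate(S, dltrs_params(0, 0, 0.8))
    tr <- h$full[h$full$type == "transfer", ]
    tr <- tr[tr$edge == eA & tr$time < 1, ]   # donors on edge A: {B, C} eligible
    recips <- c(recips, tr$to)
  }
  expect_gt(length(recips), 100)
  tab <- table(factor(recips, levels = c(eB, eC)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("pruning suppresses lost lineages and their degree-2 parents", {
  # hand fixture: root speciation, one child subtree loses its only leaf
  full <- data.frame(
    node = 1:5,
    parent = c(0, 1, 1, 3, 3),
    type = c("speciation", "leaf", "duplication", "loss", "leaf"),
    edge = c(3, 1, 2, 2, 2),
    time = c(1, 0, 0.5, 0.2, 0),
    to = NA_integer_, stringsAsFactors = FALSE)
  S <- fix_cherry()
  h <- structure(list(full = full, tree = S,
                      theta = dltrs_params(0, 0.1, 0)),
                 class = "dlt_history")
  h <- prune_extinct(h)
  expect_true(h$usable)
  # duplication node 3 had one surviving child: suppressed; 2 leaves remain
  expect_equal(h$pruned$vt$ntip, 2)
  expect_equal(h$pruned$vt$nvert, 3)
  expect_true(all(h$pruned$realization$type == "speciation"))
})

test_that("pruned trees are strictly binary with recorded truths consistent", {
  set.seed(44)
  S <- fix_5leaf()
  ek <- dltrs:::species_edge_keys(S)
  for (i in 1:25) {
    h <- dlt_simulate(S, dltrs_params(0.4, 0.4, 0.5))
    if (!h$usable) next
    vt <- h$pruned$vt
    deg <- vapply(seq_len(vt$nvert), function(v)
      sum(!is.na(vt$children[v, ])), 0L)
    expect_true(all(deg[seq_len(vt$ntip)] == 0))
    expect_true(all(deg[-seq_len(vt$ntip)] == 2))
    r <- h$pruned$realization
    tr <- r[r$type == "transfer", ]
    if (nrow(tr)) {
      expect_true(all(tr$from != tr$to))
      # both edges alive at the event time
      for (j in seq_len(nrow(tr))) {
        ce <- contemporaneous_edges(S, tr$time[j])
        expect_true(all(c(tr$from[j], tr$to[j]) %in% ek[ce]))
      }
    }
    # event times fall within their species edge span, root-to-leaf ordered
    expect_true(all(r$time >= 0 & r$time <= S$time[S$root] + S$stem))
  }
})

test_that("the relaxed clock has the right moments and degenerate limit", {
  set.seed(45)
  S <- fix_3leaf()
  h <- NULL
  while (is.null(h) || !h$usable) h <- dlt_simulate(S, dltrs_params(0, 0, 0))
  h0 <- relax_clock(h, m = 2, cv = 0.001)
  nonroot <- setdiff(seq_len(h0$pruned$vt$nvert), h0$pruned$vt$root)
  expect_equal(h0$pruned$vt$len[nonroot],
               2 * h0$pruned$durations[nonroot], tolerance = 0.01)
  # moment check over many draws
  rt <- replicate(400, {
    hh <- relax_clock(h, m = 2, cv = 0.5)
    hh$pruned$rates[nonroot]
  })
  expect_lt(abs(mean(rt) - 2), 3 * stats::sd(rt) / sqrt(length(rt)))
  # rates do not depend on position in the tree (iid draw)
  depth <- h$pruned$vtime[nonroot]
  cors <- stats::cor(rowMeans(rt), depth)
  expect_lt(abs(cors), 0.9)   # smoke-level: no systematic structure
  expect_error(relax_clock(h, cv = 0), "cv")
})

test_that("sequence simulation matches JC69 expectations", {
  set.seed(46)
  gt <- ape::read.tree(text = "(x:0.25,y:0.25);")
  msa <- simulate_sequences(gt, 60000)
  mism <- mean(msa$codes[1, ] != msa$codes[2, ])
  p <- 0.75 * (1 - exp(-4 * 0.5 / 3))
  expect_lt(abs(mism - p), 3 * sqrt(p * (1 - p) / 60000))
  # base composition at a leaf is stationary
  tab <- table(factor(msa$codes[1, ], levels = 0:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # zero lengths copy the root sequence
  gt0 <- ape::read.tree(text = "(x:0,y:0);")
  msa0 <- simulate_sequences(gt0, 50)
  expect_identical(msa0$codes[1, ], msa0$codes[2, ])
})

test_that("seeded simulation is exactly reproducible", {
  S <- fix_3leaf()
  th <- dltrs_params(0.3, 0.3, 0.4)
  set.seed(47); f1 <- simulate_family(S, th, n_sites = 30)
  set.seed(47); f2 <- simulate_family(S, th, n_sites = 30)
  expect_identical(f1$msa$codes, f2$msa$codes)
  expect_identical(f1$history$full, f2$history$full)
})

test_that("conditioning on a surviving transfer is honoured or refused", {
  set.seed(48)
  S <- fix_3leaf()
  fam <- simulate_family(S, dltrs_params(0.2, 0.2, 0.5), n_sites = 20,
                         require_transfer = TRUE)
  expect_gt(sum(fam$history$pruned$realization$type == "transfer"), 0)
  expect_error(simulate_family(S, dltrs_params(0.2, 0.2, 0), n_sites = 20,
                               require_transfer = TRUE), "unsatisfiable")
})
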