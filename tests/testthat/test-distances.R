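mk_real <- function(df, topo) {
  structure(df, class = c("dlt_realization", "data.frame"), topology = topo)
}

# 4-leaf caterpillar gene tree (((a,b),c),d) and its vtree
cat4 <- function() {
  gt <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  dltrs:::as_vtree(gt)
}

# a realization fragment with transfers at the given clades/times
tr_real <- function(vt, clades, times, deltas = 0, from = "A", to = "B") {
  keys <- dltrs:::vtree_clade_keys(vt)
  n <- length(clades)
  df <- data.frame(vertex = match(clades, keys), clade = clades,
                   point = rep(NA_integer_, n), time = times,
                   delta = rep(deltas, length.out = n),
                   type = rep("transfer", n),
                   from = rep(from, length.out = n),
                   to = rep(to, length.out = n),
                   stringsAsFactors = FALSE)
  mk_real(df, dltrs:::vtree_topology_key(vt))
}

test_that("topological distance is the gene-tree path length of transfers", {
  vt <- cat4()
  d1 <- tr_real(vt, "a+b", 0.5)
  expect_equal(topological_distance(d1, d1, vt), c(average = 0, maximum = 0))
  # transfer at a vertex vs at its parent: path length 1
  d2 <- tr_real(vt, "a+b+c", 0.5)
  expect_equal(topological_distance(d1, d2, vt), c(average = 1, maximum = 1))
  # grandparent: 2
  d3 <- tr_real(vt, "a+b+c+d", 0.5)
  expect_equal(topological_distance(d1, d3, vt), c(average = 2, maximum = 2))
  # symmetry
  expect_equal(topological_distance(d3, d1, vt),
               topological_distance(d1, d3, vt))
})

test_that("unequal transfer counts incur diameter / root-height penalties", {
  vt <- cat4()
  S <- fix_3leaf()
  g <- discretize(S, 2)
  d0 <- mk_real(data.frame(vertex = integer(), clade = character(),
                           point = integer(), time = numeric(),
                           delta = numeric(), type = character(),
                           from = character(), to = character(),
                           stringsAsFactors = FALSE),
                dltrs:::vtree_topology_key(vt))
  d1 <- tr_real(vt, "a+b", 0.5)
  diam <- dltrs:::vtree_diameter(vt)
  expect_equal(topological_distance(d0, d1, vt),
               c(average = diam, maximum = diam))
  expect_equal(temporal_distance(d0, d1, vt, g),
               c(average = 2, maximum = 2))   # root height of the 3-leaf tree
  expect_equal(topological_distance(d0, d0, vt), c(average = 0, maximum = 0))
})

test_that("minimum-cost matching equals brute force over bijections", {
  vt <- cat4()
  d1 <- tr_real(vt, c("a+b", "a+b+c+d"), c(0.3, 0.9))
  d2 <- tr_real(vt, c("a+b+c", "a+b"), c(0.4, 0.2))
  # optimal: a+b<->a+b (0), a+b+c+d<->a+b+c (1): avg 0.5; greedy-by-first
  # pairing a+b->a+b+c (1), a+b+c+d->a+b (2) would give 1.5
  expect_equal(topological_distance(d1, d2, vt),
               c(average = 0.5, maximum = 1))
})

test_that("temporal distance is the gap between placement intervals", {
  vt <- cat4()
  S <- fix_3leaf()
  g <- discretize(S, 2)
  a <- tr_real(vt, "a+b", 0.25, deltas = 0.1)    # interval [0.2, 0.3]
  b <- tr_real(vt, "a+b", 0.55, deltas = 0.1)    # interval [0.5, 0.6]
  expect_equal(temporal_distance(a, b, vt, g),
               c(average = 0.2, maximum = 0.2))
  # overlapping intervals: 0
  c_ <- tr_real(vt, "a+b", 0.28, deltas = 0.1)
  expect_equal(temporal_distance(a, c_, vt, g),
               c(average = 0, maximum = 0))
  expect_equal(temporal_distance(a, b, vt, g), temporal_distance(b, a, vt, g))
})

test_that("average never exceeds maximum on random realization pairs", {
  set.seed(61)
  vt <- cat4()
  S <- fix_3leaf()
  g <- discretize(S, 2)
  clades <- c("a+b", "a+b+c", "a+b+c+d")
  for (i in 1:20) {
    n1 <- sample(0:3, 1); n2 <- sample(0:3, 1)
    d1 <- tr_real(vt, sample(clades, n1), runif(n1, 0, 2), deltas = 0.1)
    d2 <- tr_real(vt, sample(clades, n2), runif(n2, 0, 2), deltas = 0.1)
    tg <- topological_distance(d1, d2, vt)
    tt <- temporal_distance(d1, d2, vt, g)
    expect_gte(tg["maximum"], tg["average"])
    expect_gte(tt["maximum"], tt["average"])
    expect_gte(min(tg, tt), 0)
  }
})

test_that("expected distances are posterior means of per-sample distances", {
  vt <- cat4()
  S <- fix_3leaf()
  g <- discretize(S, 2)
  truth <- tr_real(vt, "a+b", 0.5)
  same <- tr_real(vt, "a+b", 0.5)
  far <- tr_real(vt, "a+b+c+d", 0.5)   # topological distance 2
  post <- structure(list(samples = list(same, far), vt = vt, grid = g,
                         topology = attr(truth, "topology")),
                    class = "dlt_realizations")
  ed <- expected_distances(truth, post, g)
  expect_equal(ed$E_DGa, 1)            # (0 + 2) / 2
  expect_equal(ed$E_DGm, 1)
  expect_equal(ed$E_DTa, 0)
  # point mass at truth: all zero
  post0 <- structure(list(samples = list(same, same), vt = vt, grid = g,
                          topology = attr(truth, "topology")),
                     class = "dlt_realizations")
  ed0 <- expected_distances(truth, post0, g)
  expect_equal(c(ed0$E_DGa, ed0$E_DGm, ed0$E_DTa, ed0$E_DTm), rep(0, 4))
  # duplicating every sample leaves expectations unchanged
  post2 <- post; post2$samples <- c(post$samples, post$samples)
  expect_equal(expected_distances(truth, post2, g)$E_DGa, ed$E_DGa)
})

test_that("realizations over different gene trees are rejected", {
  vt <- cat4()
  d1 <- tr_real(vt, "a+b", 0.5)
  d2 <- d1; attr(d2, "topology") <- "((a,c),(b,d))"
  expect_error(topological_distance(d1, d2, vt), "different gene trees")
})
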