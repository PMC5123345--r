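test_that("extinction table matches closed forms and basic limits", {
  g1 <- discretize(single_edge_tree(1), 10)
  stp <- g1$top_pt[1]
  # mu = 0: nothing can die
  expect_equal(max(solve_extinction(g1, dltrs_params(2, 0, 0))), 0)
  # linear birth-death closed form on a single host edge
  bd_ext <- function(d, m, t) m * (exp((d - m) * t) - 1) /
    (d * exp((d - m) * t) - m)
  ext <- solve_extinction(g1, dltrs_params(2, 1, 0))
  expect_equal(ext[stp], bd_ext(2, 1, 1), tolerance = 1e-4)
  # values in [0,1], non-decreasing along the edge when mu > 0
  ord <- g1$edge_pts[[1]]
  expect_true(all(ext >= 0 & ext <= 1))
  expect_true(all(diff(ext[ord]) >= -1e-12))
})

test_that("propagation is exponential under pure death and composes", {
  S <- fix_3leaf()
  g <- discretize(S, 4)
  pp <- solve_propagation(g, dltrs_params(0, 0.7, 0))
  eC <- match("C", S$label)
  ids <- g$edge_pts[[eC]]
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    x <- ids[i]; y <- ids[j]
    expect_equal(pp$p11[x, y], exp(-0.7 * (g$pt_time[x] - g$pt_time[y])),
                 tolerance = 1e-6)
  }
  # composition along an edge holds for arbitrary rates
  pp2 <- solve_propagation(g, dltrs_params(0.8, 0.5, 0.9))
  x <- ids[5]; y <- ids[3]; z <- ids[1]
  expect_equal(pp2$p11[x, z], pp2$p11[x, y] * pp2$p11[y, z],
               tolerance = 1e-9)
  # with all rates zero, within-edge propagation is certain
  pp0 <- solve_propagation(g, dltrs_params(0, 0, 0))
  expect_equal(pp0$p11[ids[4], ids[1]], 1)
  # crossing a speciation multiplies in the sibling extinction
  th <- dltrs_params(0, 0.7, 0)
  ext <- solve_extinction(g, th)
  stp <- g$top_pt[S$root]
  pa <- g$vertex_pt[match("A", S$label)]
  eB <- match("B", S$label); eAB <- S$parent[eB]
  expect_equal(pp$p11[stp, pa],
               exp(-0.7 * 2.2) * ext[g$top_pt[eC]] * ext[g$top_pt[eB]],
               tolerance = 1e-9)
})

test_that("extinction ODE agrees with an independent general-purpose solver", {
  S <- fix_3leaf()
  g <- discretize(S, 4)
  th <- dltrs_params(0.6, 0.8, 0.5)
  ext <- solve_extinction(g, th)
  deriv <- function(t, E, p) {
    SE <- sum(E)
    list(p$mu - (p$d + p$mu + p$tau) * E + p$d * E^2 +
           p$tau / (length(E) - 1) * E * (SE - E))
  }
  # bottom slice [0, 1]: edges A, B, C all start extinct-free at the leaves
  out <- deSolve::ode(y = c(0, 0, 0), times = c(0, 1), func = deriv,
                      parms = list(d = 0.6, mu = 0.8, tau = 0.5),
                      rtol = 1e-10, atol = 1e-12)
  for (i in 1:3) {
    e <- match(c("A", "B", "C")[i], S$label)
    p1 <- g$edge_pts[[e]]
    at1 <- p1[abs(g$pt_time[p1] - 1) < 1e-12]
    expect_equal(ext[at1], out[2, 1 + i], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("extinction matches Monte-Carlo simulation of the process", {
  set.seed(21)
  S <- fix_3leaf()
  g <- discretize(S, 8)
  th <- dltrs_params(0.8, 0.9, 0.7)
  mc <- dlt_survival_mc(S, th, n = 20000)
  ode <- solve_extinction(g, th)[g$top_pt[S$root]]
  expect_lt(abs(mc$p_extinct - ode), 3.5 * mc$se)
})

test_that("edge length density is a proper density with the right limits", {
  # shape 1 (cv = 1) is exponential: density 1 at l = 0 when m = t = 1
  expect_equal(edge_length_density(0, 1, 1, 1), 1)
  # integrates to 1
  for (p in list(c(1, 1, 0.5), c(2, 0.5, 1), c(0.7, 2, 0.3))) {
    q <- stats::integrate(edge_length_density, 0, Inf, t = p[1], m = p[2],
                          cv = p[3])
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  # small cv concentrates mass at l = m * t
  l <- seq(0.5, 1.5, by = 0.001)
  d <- edge_length_density(l, t = 2, m = 0.5, cv = 0.01)
  expect_gt(l[which.max(d)], 0.95)
  expect_lt(l[which.max(d)], 1.05)
  expect_error(edge_length_density(1, 0, 1, 1), "> 0")
})

test_that("gene tree density approaches the clock product as rates vanish", {
  S <- fix_3leaf()
  g <- discretize(S, 10)
  gt <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  lm <- c(a = "A", b = "B", c = "C")
  th <- dltrs_params(1e-9, 1e-9, 1e-9, m = 1, cv = 0.5)
  dp <- gene_tree_density(gt, lm, g, th)
  expected <- sum(log(edge_length_density(c(1, 1, 2, 1), c(1, 1, 2, 1),
                                          1, 0.5)))
  expect_equal(dp$log_density, expected, tolerance = 0.01)
})

test_that("density is invariant under consistent leaf relabeling", {
  S <- fix_3leaf()
  g <- discretize(S, 4)
  th <- dltrs_params(0.3, 0.4, 0.5, 0.9, 0.6)
  gt <- ape::read.tree(text = "((x:0.4,y:0.6):0.3,z:1.1);")
  d1 <- gene_tree_density(gt, c(x = "A", y = "B", z = "C"), g, th)$log_density
  # swap the roles of the two cherry species and the gene labels with them
  gt2 <- ape::read.tree(text = "((y:0.4,x:0.6):0.3,z:1.1);")
  d2 <- gene_tree_density(gt2, c(y = "B", x = "A", z = "C"), g,
                          th)$log_density
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("density converges as the grid is refined", {
  S <- fix_cherry()
  gt <- ape::read.tree(text = "((a1:0.3,b1:0.5):0.2,a2:0.6);")
  lm <- c(a1 = "A", b1 = "B", a2 = "A")
  th <- dltrs_params(0.4, 0.3, 0.5, 1, 0.6)
  d <- vapply(c(5, 10, 20), function(r)
    gene_tree_density(gt, lm, discretize(S, r), th)$log_density, 0)
  expect_lt(abs(d[3] - d[2]), abs(d[2] - d[1]) + 1e-9)
  expect_lt(abs(d[3] - d[2]), 0.02)
})

test_that("DP cell values decompose into their event-term contributions", {
  S <- fix_3leaf()
  g <- discretize(S, 3)
  gt <- ape::read.tree(text = "((a:0.4,b:0.6):0.3,c:1.1);")
  th <- dltrs_params(0.5, 0.4, 0.6, 1, 0.7)
  dp <- gene_tree_density(gt, c(a = "A", b = "B", c = "C"), g, th)
  vt <- dp$vt
  u <- vt$root
  c1 <- vt$children[u, 1]; c2 <- vt$children[u, 2]
  # undo the per-row rescaling of A (children scales live in the D rows)
  own <- exp(dp$cs[u] - dp$cs[c1] - dp$cs[c2])
  for (x in which(g$pt_kind == 3L)) {
    dup <- 2 * th[["delta"]] * dp$D[c1, x] * dp$D[c2, x]
    tr <- 0
    if (g$pt_k[x] > 1) {
      mix <- th[["tau"]] / (g$pt_k[x] - 1)
      for (x2 in g$partners[[x]])
        tr <- tr + mix * (dp$D[c1, x] * dp$D[c2, x2] +
                          dp$D[c2, x] * dp$D[c1, x2])
    }
    expect_equal(dp$A[u, x] * own, dup + tr, tolerance = 1e-12)
  }
})

test_that("with tau = 0 no realization contains a transfer", {
  S <- fix_cherry()
  g <- discretize(S, 2)
  gt <- ape::read.tree(text = "((a1:0.3,b1:0.5):0.2,b2:0.6);")
  lm <- c(a1 = "A", b1 = "B", b2 = "B")
  th <- dltrs_params(0.5, 0.4, 0, 1, 0.7)
  en <- enumerate_realizations(gt, lm, g, th)
  expect_gt(length(en$weights), 0)
  types <- unlist(lapply(en$realizations, function(r) r$type))
  expect_false(any(types == "transfer"))
  dp <- gene_tree_density(gt, lm, g, th)
  expect_equal(dp$log_density, log(en$total), tolerance = 1e-10)
})
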