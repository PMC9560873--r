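# Brownian covariance, GLS group tests, phylogenetic regression, and the
# simulation-based phylogenetic ANOVA.

test_that("Brownian covariance has the path-length structure", {
  # star tree with equal depths: C = t * I
  star <- ape::stree(6, "star")
  star$edge.length <- rep(2, 6)
  C <- brownian_vcv(star)
  expect_equal(unname(C), diag(2, 6))
  # two sisters joined below the root share the stem length
  tr <- ape::read.tree(text = "((a:1,b:1):2,c:3);")
  C2 <- brownian_vcv(tr)
  expect_equal(C2["a", "b"], 2)
  expect_equal(C2["a", "c"], 0)
  expect_equal(C2["a", "a"], 3)
  # symmetric PSD on random trees, and equal to the ape construction
  set.seed(12)
  for (i in 1:25) {
    t <- ape::rtree(sample(4:12, 1))
    C3 <- brownian_vcv(t)
    expect_equal(C3, t(C3))
    expect_gte(min(eigen(C3, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    Ca <- ape::vcv(t)
    expect_equal(C3[rownames(Ca), colnames(Ca)], Ca, tolerance = 1e-12)
  }
})

test_that("phylogenetic t-test matches hand-rolled GLS and handles edge cases", {
  # 3-taxon worked case solved by explicit matrix algebra
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  y <- c(a = 1.0, b = 2.0, c = 4.0)
  g <- c(a = 0, b = 0, c = 1)
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  X <- cbind(1, g)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Ci %*% r) / 1
  se <- sqrt(s2 * diag(solve(t(X) %*% Ci %*% X)))
  tstat <- beta[2] / se[2]
  pexp <- 2 * pt(-abs(tstat), df = 1)
  res <- phylo_ttest(y, g, tr)
  expect_equal(res$estimate, unname(beta[2]), tolerance = 1e-10)
  expect_equal(res$se, unname(se[2]), tolerance = 1e-10)
  expect_equal(res$p, unname(pexp), tolerance = 1e-10)
  # identical trait values: no group effect, p = 1
  y0 <- c(a = 3, b = 3, c = 3)
  r0 <- phylo_ttest(y0, g, tr)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$p, 1)
  expect_error(phylo_ttest(y, c(a = 0, b = 0, c = 0), tr), "singular")
})

test_that("GLS matches nlme::gls with Brownian correlation on ultrametric trees", {
  skip_if_not_installed("nlme")
  set.seed(14)
  tr <- ape::rcoal(10)
  y <- simulate_brownian_traits(tr, 1, seed = 3)
  g <- stats::setNames(rep(c(0, 1), 5), tr$tip.label)[names(y)]
  mine <- phylo_ttest(y, g, tr)
  d <- data.frame(y = y, g = g, tax = names(y))
  ref <- summary(nlme::gls(y ~ g, data = d,
                           correlation = ape::corBrownian(1, tr,
                                                          form = ~tax)))
  expect_equal(mine$estimate, unname(ref$tTable[2, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(ref$tTable[2, 4]), tolerance = 1e-6)
})

test_that("pgls recovers exact linear relations and the OLS limit", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  set.seed(15)
  x <- stats::setNames(rnorm(8), star$tip.label)
  # exact y = 2x: slope 2, p ~ 0
  y <- 2 * x
  res <- pgls(y, x, star)
  expect_equal(res$estimate, 2, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
  # star tree: GLS equals OLS to 1e-10
  y2 <- stats::setNames(rnorm(8), star$tip.label)
  res2 <- pgls(y2, x, star)
  ols <- summary(lm(y2 ~ x))$coefficients
  expect_equal(res2$estimate, unname(ols[2, 1]), tolerance = 1e-10)
  expect_equal(res2$p, unname(ols[2, 4]), tolerance = 1e-10)
  expect_error(pgls(y2, x * 0 + 1, star), "constant x")
})

test_that("phylo_ttest and pgls hold their type-I rate under the Brownian null", {
  set.seed(16)
  tr <- ape::rcoal(12)
  g <- stats::setNames(rep(c(0, 1), 6), tr$tip.label)
  rej_t <- 0L
  rej_p <- 0L
  n <- 1000L
  for (i in seq_len(n)) {
    y <- simulate_brownian_traits(tr, 1, seed = 40000 + i)
    x <- simulate_brownian_traits(tr, 1, seed = 80000 + i)
    if (phylo_ttest(y, g, tr)$p < 0.05) rej_t <- rej_t + 1L
    if (pgls(y, x, tr)$p < 0.05) rej_p <- rej_p + 1L
  }
  expect_gte(rej_t / n, 0.03)
  expect_lte(rej_t / n, 0.07)
  expect_gte(rej_p / n, 0.03)
  expect_lte(rej_p / n, 0.07)
})

test_that("phylo_anova matches the observed F of phytools and is reproducible", {
  skip_if_not_installed("phytools")
  set.seed(17)
  tr <- ape::rcoal(12)
  grp <- stats::setNames(rep(c("A", "B", "C"), 4), tr$tip.label)
  y <- simulate_brownian_traits(tr, 1, grp, list(A = 0, B = 0, C = 3),
                                seed = 9)
  mine <- phylo_anova(y, grp, tr, n_sim = 1500, seed = 21)
  ref <- phytools::phylANOVA(tr, grp[names(y)], y, nsim = 1500)
  expect_equal(mine$F, ref$F, tolerance = 1e-8)
  expect_lt(abs(mine$p - ref$Pf), 0.05)
  # reproducible under a fixed seed and invariant to input order
  again <- phylo_anova(y, grp, tr, n_sim = 1500, seed = 21)
  expect_identical(mine$p, again$p)
  perm <- sample(names(y))
  shuffled <- phylo_anova(y[perm], grp[perm], tr, n_sim = 1500, seed = 21)
  expect_equal(shuffled$F, mine$F, tolerance = 1e-12)
  # Holm-corrected post-hoc p-values never drop below the raw ones
  expect_true(all(mine$posthoc >= mine$posthoc_raw, na.rm = TRUE))
  expect_equal(mine$posthoc, t(mine$posthoc))
})

test_that("phylo_anova detects a large planted shift and agrees with the t-test at k = 2", {
  set.seed(18)
  tr <- ape::rcoal(12)
  grp <- stats::setNames(rep(c("A", "B"), 6), tr$tip.label)
  y <- simulate_brownian_traits(tr, 1, grp, list(A = 0, B = 10), seed = 11)
  pa <- phylo_anova(y, grp, tr, n_sim = 1000, seed = 31)
  expect_lt(pa$p, 0.01)
  tt <- phylo_ttest(y, as.numeric(grp[names(y)] == "B"), tr)
  expect_equal(unname(sign(diff(pa$group_means))),
               unname(sign(tt$estimate)))
  expect_error(phylo_anova(y * 0, grp, tr, n_sim = 500, seed = 1),
               "constant")
})

test_that("simulated Brownian tip covariance matches sigma2 * C", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:0.5,d:0.5):1.5);")
  C <- brownian_vcv(tr)
  n <- 4000
  Y <- matrix(0, n, 4, dimnames = list(NULL, colnames(C)))
  for (i in seq_len(n))
    Y[i, ] <- simulate_brownian_traits(tr, sigma2 = 2, seed = 300000 + i)[colnames(C)]
  Chat <- stats::cov(Y)
  relerr <- norm(Chat - 2 * C, "F") / norm(2 * C, "F")
  expect_lt(relerr, 0.08)
  # sigma2 = 0 collapses every tip to the root value
  y0 <- simulate_brownian_traits(tr, 0, seed = 1)
  expect_true(all(y0 == 0))
})
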