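# Phylogenetically corrected comparisons.  All tests share the Brownian
# covariance C[i,j] = shared root-to-MRCA path length; group contrasts are
# GLS fits with a dummy-coded regressor, and the phylogenetic ANOVA draws
# its null F distribution from Brownian simulation on the tree.

#' Brownian-motion covariance matrix of the tips
#'
#' C[i,j] is the shared path length from the root to the most recent common
#' ancestor of tips i and j; C[i,i] is the root-to-tip depth.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(nnode)
  plen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  depth <- numeric(nnode)
  # preorder depths
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord)))
    depth[ord[e, 2L]] <- depth[ord[e, 1L]] + plen[ord[e, 2L]]
  anc <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    path <- i
    v <- i
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    anc[[i]] <- path
  }
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    C[i, i] <- depth[i]
    if (i < ntip) for (j in (i + 1L):ntip) {
      common <- intersect(anc[[i]], anc[[j]])
      C[i, j] <- C[j, i] <- max(depth[common])
    }
  }
  if (max(diag(C)) <= 0) stop("zero-depth tree: covariance is singular")
  C
}

# GLS fit of y on design X with covariance proportional to C; returns
# coefficients, their standard errors and the residual variance estimate
gls_fit <- function(y, X, C) {
  n <- length(y)
  Cc <- C
  ch <- tryCatch(chol(Cc), error = function(e) NULL)
  if (is.null(ch)) {
    # zero-length-branch-induced singularity: ridge the diagonal, logged
    Cc <- Cc + diag(1e-8 * max(diag(C)), n)
    message("singular Brownian covariance; adding 1e-8 * depth ridge")
    ch <- chol(Cc)
  }
  # whiten: solve(t(ch)) %*% x
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  qr_ <- qr(wX)
  if (qr_$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qr_, wy)
  res <- wy - wX %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * diag(XtX_inv))
  list(beta = as.numeric(beta), se = se, sigma2 = sigma2, df = df,
       rss = sum(res^2))
}

# t statistic with a guard for numerically exact fits: when the residual
# variance vanishes, a zero slope carries no evidence (t = 0, p = 1) while a
# nonzero slope is an exact relation (t = Inf, p = 0)
gls_tstat <- function(fit, y) {
  tol <- 1e-10 * (1 + sum(y^2))
  if (fit$rss < tol) {
    if (abs(fit$beta[2L]) < sqrt(tol)) 0 else Inf
  } else fit$beta[2L] / fit$se[2L]
}

#' Phylogenetic t-test via dummy-coded GLS
#'
#' Fits y = b0 + b1 * g by generalized least squares with Brownian error
#' covariance from the tree, g being the 0/1 group dummy; t = b1 / SE(b1)
#' with n - 2 degrees of freedom, two-sided.
#'
#' @param y named numeric trait vector (names = tip labels).
#' @param group01 0/1 vector aligned with y (e.g. 0 = IR-lacking, 1 =
#'   canonical-IR relatives).
#' @param tree rooted `ape::phylo` containing all names of y.
#' @return list of class `comparative_test`: method, estimate (group effect
#'   b1), se, statistic, df, p, group_means.
#' @export
phylo_ttest <- function(y, group01, tree) {
  stopifnot(!is.null(names(y)), all(names(y) %in% tree$tip.label))
  if (any(!is.finite(y))) stop("y must be finite")
  g <- as.numeric(group01)
  if (length(unique(g)) < 2L) stop("singular design: one group is empty")
  keep <- names(y)
  C <- brownian_vcv(ape::keep.tip(tree, keep))[keep, keep]
  X <- cbind(1, g)
  fit <- gls_fit(y, X, C)
  tstat <- gls_tstat(fit, y)
  p <- 2 * stats::pt(-abs(tstat), df = fit$df)
  structure(list(method = "phylo_t", estimate = fit$beta[2L],
                 se = fit$se[2L], statistic = tstat, df = fit$df, p = p,
                 group_means = c(`0` = fit$beta[1L],
                                 `1` = fit$beta[1L] + fit$beta[2L])),
            class = "comparative_test")
}

#' Phylogenetic least-squares regression
#'
#' GLS slope of y on x under Brownian covariance; two-sided t test of the
#' slope.  On a star tree with equal depths (C proportional to the identity)
#' the estimates equal ordinary least squares.
#'
#' @param y,x named numeric vectors (same names, tip labels of the tree).
#' @param tree rooted `ape::phylo`.
#' @return `comparative_test` with slope estimate, intercept, statistic, p.
#' @export
pgls <- function(y, x, tree) {
  stopifnot(!is.null(names(y)), identical(sort(names(y)), sort(names(x))))
  x <- x[names(y)]
  if (length(y) < 3L) stop("need at least 3 taxa")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  if (any(!is.finite(c(x, y)))) stop("x and y must be finite")
  keep <- names(y)
  C <- brownian_vcv(ape::keep.tip(tree, keep))[keep, keep]
  X <- cbind(1, x)
  fit <- gls_fit(y, X, C)
  tstat <- gls_tstat(fit, y)
  p <- 2 * stats::pt(-abs(tstat), df = fit$df)
  structure(list(method = "pgls", estimate = fit$beta[2L],
                 intercept = fit$beta[1L], se = fit$se[2L],
                 statistic = tstat, df = fit$df, p = p),
            class = "comparative_test")
}

#' @export
print.comparative_test <- function(x, ...) {
  cat("<comparative_test> ", x$method, ": estimate = ",
      signif(x$estimate, 5), ", statistic = ", signif(x$statistic, 5),
      ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simulation-based phylogenetic ANOVA with post-hoc tests
#'
#' The observed F statistic of a one-way ANOVA is compared against a null
#' distribution generated by Brownian-motion simulation on the tree, with
#' the rate estimated from the data by the GLS residual estimator.  Post-hoc
#' pairwise t statistics use the pooled mean square and the same simulated
#' null, with Holm correction (configurable).
#'
#' @param y named numeric trait vector.
#' @param groups named group labels (same names), k >= 2 levels.
#' @param tree rooted `ape::phylo`.
#' @param n_sim number of Brownian null simulations (>= 100).
#' @param seed RNG seed for reproducibility.
#' @param posthoc_method p-adjustment method for the pairwise matrix.
#' @return list of class `phylo_anova`: F, p, df, group_means, posthoc
#'   (corrected pairwise p matrix), posthoc_raw, n_sim.
#' @export
phylo_anova <- function(y, groups, tree, n_sim = 1000L, seed = NULL,
                        posthoc_method = "holm") {
  stopifnot(!is.null(names(y)), identical(sort(names(y)),
                                          sort(names(groups))))
  groups <- groups[names(y)]
  if (stats::sd(y) == 0) stop("constant y: F undefined")
  lev <- sort(unique(as.character(groups)))
  k <- length(lev)
  if (k < 2L) stop("need at least 2 groups")
  if (n_sim < 100L) stop("n_sim too small")
  keep <- names(y)
  tr <- ape::keep.tip(tree, keep)
  C <- brownian_vcv(tr)[keep, keep]
  n <- length(y)

  f_of <- function(v) {
    gm <- tapply(v, groups, mean)
    ssb <- sum(tapply(v, groups, length) * (gm - mean(v))^2)
    ssw <- sum((v - gm[as.character(groups)])^2)
    msb <- ssb / (k - 1L)
    msw <- ssw / (n - k)
    list(F = msb / msw, msw = msw, means = gm)
  }
  t_pairs <- function(v, msw) {
    gm <- tapply(v, groups, mean)
    cnt <- tapply(v, groups, length)
    out <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      tt <- (gm[lev[a]] - gm[lev[b]]) /
        sqrt(msw * (1 / cnt[lev[a]] + 1 / cnt[lev[b]]))
      out[a, b] <- out[b, a] <- tt
    }
    out
  }

  obs <- f_of(y)
  t_obs <- t_pairs(y, obs$msw)

  # GLS rate estimate under the grand-mean model
  one <- matrix(1, n, 1L)
  gfit <- gls_fit(y, one, C)
  sigma2 <- gfit$rss / n          # ML-style rate for simulation
  ch <- chol(C + diag(1e-12 * max(diag(C)), n))

  sim_F <- numeric(n_sim)
  sim_T <- array(NA_real_, c(k, k, n_sim))
  with_seed(seed, {
    for (s in seq_len(n_sim)) {
      z <- sqrt(sigma2) * drop(t(ch) %*% stats::rnorm(n))
      names(z) <- keep
      fs <- f_of(z)
      sim_F[s] <- fs$F
      sim_T[, , s] <- t_pairs(z, fs$msw)
    }
  })
  p <- (sum(sim_F >= obs$F) + 1L) / (n_sim + 1L)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    p_raw[a, b] <- p_raw[b, a] <-
      (sum(abs(sim_T[a, b, ]) >= abs(t_obs[a, b])) + 1L) / (n_sim + 1L)
  }
  pv <- p_raw[upper.tri(p_raw)]
  padj <- stats::p.adjust(pv, method = posthoc_method)
  p_adj <- p_raw
  p_adj[upper.tri(p_adj)] <- padj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(method = "phylo_anova", F = obs$F, p = p,
                 df = c(k - 1L, n - k), group_means = obs$means,
                 statistic_pairs = t_obs, posthoc = p_adj,
                 posthoc_raw = p_raw, n_sim = n_sim, sigma2 = sigma2),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("<phylo_anova> F = ", signif(x$F, 5), " (df ", x$df[1L], ",",
      x$df[2L], "), simulation p = ", format.pval(x$p, digits = 4),
      " [", x$n_sim, " sims]\n", sep = "")
  invisible(x)
}
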