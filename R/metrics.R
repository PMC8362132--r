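#' @title Size-difference metrics
#' @description Five metrics assess differences in log10 body size between
#'   two habitat-use groups on a clade: (i) difference of log10 means;
#'   (ii) difference of phylogenetic (GLS) means; (iii) Wilcoxon rank-sum
#'   test; (iv) simulation-based phylogenetic ANOVA; (v) PGLS ANOVA with
#'   residual randomization.  Per-habitat summary metrics (richness,
#'   migratory percentage, mean tip branch duration, trophic means and
#'   variance-vs-simulated) feed the alignment and mechanism analyses.
#' @name size-metrics
NULL

metric_outcome <- function(metric, diff, p = NA_real_, n_first, n_second,
                           tol = 1e-12) {
  larger <- if (!is.finite(diff)) NA_character_
  else if (abs(diff) <= tol) "tie"
  else if (diff > 0) "first" else "second"
  list(metric = metric, signed_difference = diff, larger = larger,
       p_value = p, n_first = n_first, n_second = n_second)
}

#' Difference of log10 means between two groups
#'
#' @param values_a,values_b numeric vectors (log10 sizes); first minus
#'   second.
#' @return a metric outcome list: `metric`, `signed_difference`, `larger`
#'   (`"first"`, `"second"` or `"tie"`), `p_value`, `n_first`, `n_second`.
#' @export
mean_log10_diff <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  metric_outcome("mean_log10", mean(values_a) - mean(values_b),
                 n_first = length(values_a), n_second = length(values_b))
}

# Cholesky of the BM covariance with a ridge fallback for near-singular
# trees (e.g. zero-length terminal cherries).
chol_bm <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    warning("BM covariance not positive definite; adding ridge",
            call. = FALSE)
    U <- chol(C + diag(1e-8 * mean(diag(C)), nrow(C)))
  }
  U
}

# GLS fit of y on a design X under covariance C (via its Cholesky U).
gls_fit <- function(U, X, y) {
  Zx <- backsolve(U, X, transpose = TRUE)
  zy <- backsolve(U, y, transpose = TRUE)
  fit <- qr(Zx)
  if (fit$rank < ncol(X))
    stop("singular GLS design (a group is absent)", call. = FALSE)
  beta <- qr.coef(fit, zy)
  list(beta = beta, resid = zy - Zx %*% beta, Zx = Zx, zy = zy)
}

#' Phylogenetic (GLS) group means
#'
#' Least-squares habitat means from a GLS fit of the trait on group
#' indicator columns with Brownian tip covariance `C`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`.  On a star tree (C proportional to
#' the identity) these equal the ordinary group means.
#'
#' @param tree clade tree whose tips carry `y`.
#' @param y named trait vector (names = tip labels) or vector in tip
#'   order.
#' @param groups group label per tip.
#' @return list with `ls_means` (named per group) and `pairwise`, a
#'   data.frame of signed LS-mean differences for every ordered group
#'   pair.
#' @export
phylo_ls_means <- function(tree, y, groups) {
  if (!is.null(names(y))) y <- y[tree$tip.label]
  groups <- as.character(groups)
  g <- factor(groups)
  if (nlevels(g) < 1) stop("no groups", call. = FALSE)
  C <- bm_covariance(tree)
  U <- chol_bm(C)
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  fit <- gls_fit(U, X, y)
  ls <- setNames(as.numeric(fit$beta), levels(g))
  prs <- if (nlevels(g) >= 2) {
    cc <- combn(levels(g), 2)
    data.frame(first = cc[1, ], second = cc[2, ],
               diff = ls[cc[1, ]] - ls[cc[2, ]],
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(first = character(0), second = character(0),
                    diff = numeric(0))
  list(ls_means = ls, pairwise = prs)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Exact null enumeration when `n_a + n_b <= 12` and the data contain no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections.  The signed difference reported is the rank-biserial
#' correlation `2 W / (n_a n_b) - 1` (positive when the first group tends
#' larger).
#'
#' @param values_a,values_b numeric vectors.
#' @return a metric outcome list (see [mean_log10_diff()]).
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (!na || !nb) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (na + nb) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  rb <- 2 * unname(wt$statistic) / (na * nb) - 1
  metric_outcome("wilcoxon", rb, p = wt$p.value,
                 n_first = na, n_second = nb)
}

#' Maximum-likelihood Brownian rate on a tree
#'
#' GLS intercept (phylogenetic mean) and ML rate
#' `sigma^2 = e' C^-1 e / n`; with `reml = TRUE` the denominator is
#' `n - 1`.
#'
#' @param tree clade tree.
#' @param y named trait vector.
#' @param reml logical.
#' @return list `mu`, `sig2`, and `U` (Cholesky of C).
#' @export
bm_rate_ml <- function(tree, y, reml = FALSE) {
  if (!is.null(names(y))) y <- y[tree$tip.label]
  C <- bm_covariance(tree)
  U <- chol_bm(C)
  n <- length(y)
  fit <- gls_fit(U, matrix(1, n, 1), y)
  sig2 <- sum(fit$resid^2) / (if (reml) n - 1 else n)
  list(mu = as.numeric(fit$beta), sig2 = sig2, U = U)
}

# BM simulations with covariance sig2*C given U = chol(C):
# returns n x nsim matrix (mean mu).
sim_bm_gauss <- function(U, sig2, nsim, mu = 0) {
  n <- nrow(U)
  Z <- matrix(rnorm(n * nsim), n, nsim)
  mu + sqrt(sig2) * crossprod(U, Z)
}

# vectorized one-way F statistics for columns of Y
fstat_cols <- function(Y, g) {
  n <- nrow(Y); ng <- tabulate(g); k <- length(ng)
  gm <- rowsum(Y, g) / ng
  grand <- colSums(Y) / n
  ssb <- colSums(ng * gm^2) - n * grand^2
  sst <- colSums(Y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  fs <- (ssb / (k - 1)) / (ssw / (n - k))
  fs[ssw == 0 & ssb == 0] <- 0
  fs
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed one-way F statistic on the tip data is compared to a null
#' distribution of F statistics from `n_sim` Brownian simulations on the
#' clade tree (rate = ML estimate from the data), with group membership
#' held fixed.  `p = (1 + #\{F_sim >= F_obs\}) / (1 + n_sim)`.
#'
#' @param tree clade tree.
#' @param y named trait vector.
#' @param groups group label per tip.
#' @param n_sim number of Brownian null simulations.
#' @param seed RNG seed.
#' @param reml use the REML rate estimate.
#' @return a metric outcome list; `signed_difference` is the difference of
#'   arithmetic group means when exactly two groups are supplied, NA
#'   otherwise.
#' @export
phylo_anova_sim <- function(tree, y, groups, n_sim = 999, seed = NULL,
                            reml = FALSE) {
  if (!is.null(names(y))) y <- y[tree$tip.label]
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (var(y) == 0) {
    warning("zero-variance trait; p = 1", call. = FALSE)
    return(metric_outcome("phylo_anova", 0, p = 1,
                          n_first = sum(g == levels(g)[1]),
                          n_second = sum(g == levels(g)[2])))
  }
  est <- bm_rate_ml(tree, y, reml = reml)
  f_obs <- fstat_cols(matrix(y, ncol = 1), g)
  f_sim <- with_seed(seed, {
    Y <- sim_bm_gauss(est$U, est$sig2, n_sim)
    fstat_cols(Y, g)
  })
  p <- (1 + sum(f_sim >= f_obs - 1e-12)) / (1 + n_sim)
  d <- if (nlevels(g) == 2)
    mean(y[g == levels(g)[1]]) - mean(y[g == levels(g)[2]]) else NA_real_
  metric_outcome("phylo_anova", d, p = p,
                 n_first = sum(g == levels(g)[1]),
                 n_second = sum(g == levels(g)[2]))
}

#' PGLS ANOVA with residual randomization
#'
#' The trait and designs are whitened with the Cholesky factor of the
#' Brownian covariance; the test statistic is the reduction in residual
#' sum of squares from the intercept-only model to the group model in the
#' whitened space.  The null distribution permutes the whitened
#' null-model residuals (`n_perm` times), adds them back to the null
#' fitted values, and recomputes the statistic.
#'
#' @inheritParams phylo_anova_sim
#' @param n_perm number of residual permutations.
#' @return a metric outcome list; `signed_difference` is the LS-mean
#'   difference for two groups.
#' @export
pgls_anova_perm <- function(tree, y, groups, n_perm = 999, seed = NULL) {
  if (!is.null(names(y))) y <- y[tree$tip.label]
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- length(y)
  C <- bm_covariance(tree)
  U <- chol_bm(C)
  w <- backsolve(U, y, transpose = TRUE)
  Z0 <- backsolve(U, matrix(1, n, 1), transpose = TRUE)
  X <- stats::model.matrix(~ 0 + g)
  Z1 <- backsolve(U, X, transpose = TRUE)
  Q0 <- qr.Q(qr(Z0))
  Q1 <- qr.Q(qr(Z1))
  stat <- function(v) sum(crossprod(Q1, v)^2) - sum(crossprod(Q0, v)^2)
  s_obs <- stat(w)
  f0 <- Q0 %*% crossprod(Q0, w)
  e0 <- as.numeric(w - f0)
  s_perm <- with_seed(seed, {
    E <- vapply(seq_len(n_perm), function(i) e0[sample.int(n)],
                numeric(n))
    Ystar <- as.numeric(f0) + E
    colSums(crossprod(Q1, Ystar)^2) - colSums(crossprod(Q0, Ystar)^2)
  })
  p <- (1 + sum(s_perm >= s_obs - 1e-12)) / (1 + n_perm)
  beta <- qr.coef(qr(Z1), w)
  d <- if (nlevels(g) == 2) beta[1] - beta[2] else NA_real_
  metric_outcome("pgls_anova", unname(d), p = p,
                 n_first = sum(g == levels(g)[1]),
                 n_second = sum(g == levels(g)[2]))
}

#' Observed trait variance of a habitat versus Brownian simulations
#'
#' Compares the observed variance of a habitat's tip values with the
#' variances of the same tip subset under `n_sim` Brownian simulations on
#' the clade tree (ML rate from all clade tips).  The quantile position
#' `(1 + #\{var_sim < var_obs\}) / (1 + n_sim)` is approximately uniform
#' when the trait itself evolved by Brownian motion.
#'
#' @param tree clade tree.
#' @param y named trait vector over all clade tips.
#' Because the Brownian rate is estimated from the same data (REML by
#' default), the quantile is only approximately uniform under the null:
#' the plug-in estimate tracks the observed variance, mildly
#' under-dispersing the quantiles.
#'
#' @param tips tip labels of the focal habitat (>= 2).
#' @param n_sim number of simulations.
#' @param seed RNG seed.
#' @param reml use the REML (n - 1) rate estimate (less downward bias
#'   than ML).
#' @return list `observed`, `null_median`, `quantile`.
#' @export
variance_vs_sim <- function(tree, y, tips, n_sim = 999, seed = NULL,
                            reml = TRUE) {
  if (!is.null(names(y))) y <- y[tree$tip.label]
  idx <- match(tips, tree$tip.label)
  if (length(idx) < 2 || anyNA(idx))
    stop("need >= 2 tips of the focal habitat present in the clade",
         call. = FALSE)
  est <- bm_rate_ml(tree, y, reml = reml)
  v_obs <- var(y[idx])
  v_sim <- with_seed(seed, {
    Y <- sim_bm_gauss(est$U, est$sig2, n_sim)
    apply(Y[idx, , drop = FALSE], 2, var)
  })
  list(observed = v_obs, null_median = median(v_sim),
       quantile = (1 + sum(v_sim < v_obs)) / (1 + n_sim))
}

#' Per-habitat summary metrics for a clade
#'
#' Richness, migratory percentage (denominator = taxa with a known flag),
#' mean terminal branch duration, and ordinary plus phylogenetic (GLS)
#' means of size and trophic level.  Phylogenetic trophic means are
#' computed on the clade pruned to trophic-complete taxa.
#'
#' @param dataset a `habitat_dataset` restricted to one clade.
#' @return data.frame, one row per habitat present.
#' @export
habitat_summaries <- function(dataset) {
  rec <- dataset$records
  tree <- dataset$tree
  tipdur <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                            tree$edge[, 2])],
                     tree$tip.label)
  habs <- intersect(habitat_levels(), unique(rec$habitat))
  size_pm <- rep(NA_real_, length(habs)); names(size_pm) <- habs
  if (length(tree$tip.label) >= 2) {
    pm <- try(phylo_ls_means(tree, setNames(rec$log10_size, rec$species),
                             rec$habitat), silent = TRUE)
    if (!inherits(pm, "try-error"))
      size_pm[names(pm$ls_means)] <- pm$ls_means
  }
  troph_pm <- rep(NA_real_, length(habs)); names(troph_pm) <- habs
  tkeep <- rec$species[!is.na(rec$trophic_level)]
  if (length(tkeep) >= 2 && length(unique(rec$habitat[match(tkeep,
      rec$species)])) >= 1) {
    sub <- try(prune_dataset(dataset, tkeep), silent = TRUE)
    if (!inherits(sub, "try-error")) {
      tpm <- try(phylo_ls_means(sub$tree,
                                setNames(sub$records$trophic_level,
                                         sub$records$species),
                                sub$records$habitat), silent = TRUE)
      if (!inherits(tpm, "try-error"))
        troph_pm[names(tpm$ls_means)] <- tpm$ls_means
    }
  }
  do.call(rbind, lapply(habs, function(h) {
    r <- rec[rec$habitat == h, ]
    known <- !is.na(r$migratory)
    data.frame(habitat = h,
               richness = nrow(r),
               migratory_pct = if (any(known))
                 100 * sum(r$migratory[known]) / sum(known) else NA_real_,
               n_migr_known = sum(known),
               mean_tip_duration = mean(tipdur[r$species]),
               size_mean = mean(r$log10_size),
               size_phylo_mean = size_pm[[h]],
               trophic_mean = if (any(!is.na(r$trophic_level)))
                 mean(r$trophic_level, na.rm = TRUE) else NA_real_,
               n_trophic = sum(!is.na(r$trophic_level)),
               trophic_phylo_mean = troph_pm[[h]],
               stringsAsFactors = FALSE)
  }))
}
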