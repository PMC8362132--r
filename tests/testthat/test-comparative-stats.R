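test_that("mean_log10_diff is a plain mean difference with tie handling", {
  expect_equal(mean_log10_diff(c(1, 1), c(1, 1))$larger, "tie")
  out <- mean_log10_diff(c(2, 2, 2), c(1, 1))
  expect_equal(out$signed_difference, 1)
  expect_equal(out$larger, "first")
  for (s in 1:5) {
    x <- with_seed_local(s, rnorm(7)); y <- with_seed_local(s + 100, rnorm(5))
    expect_equal(mean_log10_diff(x, y)$signed_difference,
                 mean(x) - mean(y))
  }
  expect_error(mean_log10_diff(numeric(0), 1), "non-empty")
})

test_that("wilcoxon matches exact enumeration and the tie-corrected normal", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # enumeration oracle across group sizes (no ties, n_a + n_b <= 10)
  for (na in 2:5) for (nb in 2:(10 - na)) {
    x <- with_seed_local(na * 10 + nb, sample(seq(1, 100), na + nb))
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, wilcox_enum_p(a, b),
                 tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  # large-sample: independent normal-approximation implementation
  a <- with_seed_local(1, round(rnorm(30, 0, 2), 1))
  b <- with_seed_local(2, round(rnorm(25, 0.5, 2), 1))
  r <- rank(c(a, b)); na <- 30; nb <- 25; n <- na + nb
  W <- sum(r[1:na]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  sig <- sqrt(na * nb / 12 * ((n + 1) - sum(ties^3 - ties) /
                                (n * (n - 1))))
  z <- (W - na * nb / 2 - sign(W - na * nb / 2) * 0.5) / sig
  p_ref <- 2 * min(pnorm(z), 1 - pnorm(z), 0.5)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, p_ref, tolerance = 1e-6)
  # direction: rank-biserial sign
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(1, 2, 3))$larger, "first")
})

test_that("phylogenetic LS means: star-tree identity and GLS oracle", {
  tr <- star_tree(9)
  y <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 9), tr$tip.label)
  g <- rep(c("a", "b", "c"), each = 3)
  pm <- phylo_ls_means(tr, y, g)
  expect_equal(unname(pm$ls_means),
               as.vector(tapply(y, g, mean)), tolerance = 1e-10)
  # hand-built 6-tip tree against explicit matrix inversion
  tr2 <- ape::read.tree(
    text = "(((A:1,B:1):0.5,C:1.5):0.5,((D:0.7,E:0.7):0.8,F:1.5):0.5);")
  y2 <- setNames(c(0.2, 0.5, 1.1, 1.4, 1.9, 0.8), LETTERS[1:6])
  g2 <- c("m", "m", "f", "f", "m", "f")
  pm2 <- phylo_ls_means(tr2, y2, g2)
  C <- bm_cov_oracle(tr2)[tr2$tip.label, tr2$tip.label]
  X <- cbind(f = as.numeric(g2 == "f"), m = as.numeric(g2 == "m"))
  expect_equal(unname(pm2$ls_means[c("f", "m")]),
               gls_means_oracle(C, X, y2[tr2$tip.label]),
               tolerance = 1e-10)
  expect_equal(pm2$pairwise$diff,
               pm2$ls_means["f"] - pm2$ls_means["m"],
               ignore_attr = TRUE)
  # constant trait
  pm3 <- phylo_ls_means(tr2, setNames(rep(2.2, 6), LETTERS[1:6]), g2)
  expect_equal(unname(pm3$ls_means), c(2.2, 2.2), tolerance = 1e-10)
})

test_that("simulation ANOVA saturates, is deterministic, and handles
           degenerate traits", {
  tr <- with_seed_local(5, ape::rphylo(40, 1, 0))
  g <- rep(c("a", "b"), each = 20)
  y <- setNames(c(rnorm(20), rnorm(20) + 10), tr$tip.label)
  out <- phylo_anova_sim(tr, y, g, n_sim = 99, seed = 1)
  expect_lte(out$p_value, 2 / 100)
  expect_identical(out$p_value,
                   phylo_anova_sim(tr, y, g, n_sim = 99, seed = 1)$p_value)
  expect_warning(
    outc <- phylo_anova_sim(tr, setNames(rep(1, 40), tr$tip.label), g,
                            n_sim = 49, seed = 1),
    "zero-variance")
  expect_equal(outc$p_value, 1)
})

test_that("PGLS ANOVA agrees with classical ANOVA on a star tree", {
  tr <- star_tree(24)
  y <- setNames(with_seed_local(3, rnorm(24) + rep(c(0, 0.9), each = 12)),
                tr$tip.label)
  g <- rep(c("a", "b"), each = 12)
  out <- pgls_anova_perm(tr, y, g, n_perm = 1999, seed = 2)
  p_aov <- anova(lm(y ~ g))[1, "Pr(>F)"]
  expect_lt(abs(out$p_value - p_aov), 0.05)
  expect_equal(out$larger, "second")
  # constant trait -> p = 1
  outc <- pgls_anova_perm(tr, setNames(rep(3, 24), tr$tip.label), g,
                          n_perm = 99, seed = 1)
  expect_equal(outc$p_value, 1)
  expect_identical(out$p_value,
                   pgls_anova_perm(tr, y, g, n_perm = 1999,
                                   seed = 2)$p_value)
})

test_that("variance-vs-simulated quantile is approximately calibrated
           under BM", {
  # The plug-in rate estimate makes the null quantile only approximately
  # uniform (slightly under-dispersed), so exact KS uniformity is not
  # asserted; see the methods vignette.
  tr <- with_seed_local(7, ape::rphylo(50, 1, 0))
  tips <- tr$tip.label[1:20]
  qs <- vapply(1:300, function(s) {
    y <- habsize:::simulate_bm_tips(tr, 0.5, 0, seed = s)
    variance_vs_sim(tr, y, tips, n_sim = 199, seed = s + 1000)$quantile
  }, numeric(1))
  expect_gt(mean(qs), 0.42); expect_lt(mean(qs), 0.62)
  expect_gt(sd(qs), 0.2); expect_lt(sd(qs), 0.35)
  expect_gt(mean(qs < 0.1), 0.02)   # tails are populated
  expect_gt(mean(qs > 0.9), 0.02)
  # constant trait: observed variance 0, below every simulation
  v <- variance_vs_sim(tr, setNames(rep(1, 50), tr$tip.label),
                       tips, n_sim = 99, seed = 1)
  expect_equal(v$observed, 0)
  expect_equal(v$quantile, 1 / 100)
  expect_error(variance_vs_sim(tr, setNames(rnorm(50), tr$tip.label),
                               tips[1], n_sim = 9), ">= 2 tips")
})

test_that("habitat summaries report the documented quantities", {
  tr <- ape::read.tree(text = "((A:1,B:3):1,(C:2,D:2):1);")
  rec <- taxon_records(LETTERS[1:4],
                       c("marine", "marine", "euryhaline", "euryhaline"),
                       c(1, 2, 3, 4),
                       trophic_level = c(2, 3, 4, NA),
                       migratory = c(FALSE, NA, TRUE, TRUE))
  ds <- match_tree_table(tr, rec)
  s <- habitat_summaries(ds)
  eury <- s[s$habitat == "euryhaline", ]
  mar <- s[s$habitat == "marine", ]
  expect_equal(eury$migratory_pct, 100)
  expect_equal(mar$migratory_pct, 0)     # one known flag, not migratory
  expect_equal(mar$n_migr_known, 1)
  expect_equal(mar$mean_tip_duration, 2) # branches 1 and 3
  expect_equal(mar$richness, 2)
  expect_equal(mar$trophic_mean, 2.5)
  expect_equal(eury$n_trophic, 1)
})

test_that("all five size metrics agree on cleanly separated star-tree data", {
  tr <- star_tree(30)
  g <- rep(c("freshwater", "marine"), each = 15)
  y <- setNames(with_seed_local(8, rnorm(30, 0, 0.05)) +
                  rep(c(0, 2), each = 15), tr$tip.label)
  expect_equal(mean_log10_diff(y[1:15], y[16:30])$larger, "second")
  expect_equal(wilcoxon_rank_sum(y[1:15], y[16:30])$larger, "second")
  pm <- phylo_ls_means(tr, y, g)
  expect_lt(pm$pairwise$diff[1], 0)
  expect_equal(phylo_anova_sim(tr, y, g, 99, seed = 1)$larger, "second")
  expect_equal(pgls_anova_perm(tr, y, g, 99, seed = 1)$larger, "second")
})
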