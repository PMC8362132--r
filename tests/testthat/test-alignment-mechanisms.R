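test_that("percentage alignment: identical, opposite, and independent
           metrics", {
  n <- 40
  d <- with_seed_local(1, rnorm(n))
  r1 <- fake_results("tax3", sprintf("c%d", 1:n), "freshwater", "marine",
                     "m1", d)
  r2 <- fake_results("tax3", sprintf("c%d", 1:n), "freshwater", "marine",
                     "m2", d)
  r3 <- fake_results("tax3", sprintf("c%d", 1:n), "freshwater", "marine",
                     "m3", -d)
  res <- structure(rbind(r1, r2, r3),
                   class = c("comparison_results", "data.frame"))
  expect_equal(percentage_alignment(res, "m1", "m2")$pct_aligned, 100)
  expect_equal(percentage_alignment(res, "m1", "m1")$pct_aligned, 100)
  expect_equal(percentage_alignment(res, "m1", "m3")$pct_aligned, 0)

  # independent random signs: binomial check around 50%
  n2 <- 1000
  ra <- fake_results("tax3", sprintf("c%d", 1:n2), "freshwater", "marine",
                     "ma", with_seed_local(2, sample(c(-1, 1), n2, TRUE)))
  rb <- fake_results("tax3", sprintf("c%d", 1:n2), "freshwater", "marine",
                     "mb", with_seed_local(3, sample(c(-1, 1), n2, TRUE)))
  resab <- structure(rbind(ra, rb),
                     class = c("comparison_results", "data.frame"))
  pct <- percentage_alignment(resab, "ma", "mb")$pct_aligned
  expect_gte(pct, 45); expect_lte(pct, 55)

  # ties are excluded and logged
  rt <- fake_results("tax3", c("c1", "c2", "c3"), "freshwater", "marine",
                     "mt", c(0, 1, -1))
  resT <- structure(rbind(rt, fake_results("tax3", c("c1", "c2", "c3"),
                                           "freshwater", "marine", "mu",
                                           c(1, 1, -1))),
                    class = c("comparison_results", "data.frame"))
  al <- percentage_alignment(resT, "mt", "mu")
  expect_equal(al$n_compared, 2)
  expect_equal(nrow(attr(al, "excluded")), 1)
})

test_that("continuous association: exact line, quadrant recount,
           influential clades", {
  n <- 12
  dx <- with_seed_local(4, rnorm(n))
  r1 <- fake_results("order", sprintf("c%d", 1:n), "euryhaline", "marine",
                     "mx", dx)
  r2 <- fake_results("order", sprintf("c%d", 1:n), "euryhaline", "marine",
                     "my", 2 * dx)
  res <- structure(rbind(r1, r2),
                   class = c("comparison_results", "data.frame"))
  ca <- continuous_association(res, "mx", "my", "euryhaline", "marine",
                               "order")
  expect_equal(ca$slope, 2, tolerance = 1e-10)
  expect_equal(ca$r2, 1, tolerance = 1e-10)
  expect_equal(unname(ca$quadrant_counts[c("mismatch_x_pos",
                                           "mismatch_y_pos")]),
               c(0L, 0L), ignore_attr = TRUE)
  expect_equal(sum(ca$quadrant_counts), n)
  # quadrant recount oracle
  expect_equal(unname(ca$quadrant_counts["agree_pos"]),
               sum(dx > 0 & 2 * dx > 0))

  # a single outlier manufactures significance; jackknife flags it
  dx2 <- c(with_seed_local(5, rnorm(8, 0, 0.1)), 5)
  dy2 <- c(with_seed_local(6, rnorm(8, 0, 0.1)), 5)
  ro1 <- fake_results("order", sprintf("c%d", 1:9), "euryhaline",
                      "freshwater", "mx", dx2)
  ro2 <- fake_results("order", sprintf("c%d", 1:9), "euryhaline",
                      "freshwater", "my", dy2)
  reso <- structure(rbind(ro1, ro2),
                    class = c("comparison_results", "data.frame"))
  cao <- continuous_association(reso, "mx", "my", "euryhaline",
                                "freshwater", "order")
  expect_lt(cao$p, 0.05)
  expect_true("c9" %in% cao$influential)
  expect_error(continuous_association(res[1:4, ], "mx", "my",
                                      "euryhaline", "marine", "order"),
               ">= 3 clades")
})

mk_summ <- function(size_larger_troph_pm, other_troph_pm,
                    mig_L = 0, mig_O = 0, dur_L = 1, dur_O = 1,
                    rich_L = 10, rich_O = 10,
                    troph_mean_L = NA, troph_mean_O = NA) {
  data.frame(habitat = c("freshwater", "marine"),
             richness = c(rich_L, rich_O),
             migratory_pct = c(mig_L, mig_O),
             n_migr_known = c(5, 5),
             mean_tip_duration = c(dur_L, dur_O),
             size_mean = c(2, 1), size_phylo_mean = c(2, 1),
             trophic_mean = c(troph_mean_L, troph_mean_O),
             n_trophic = c(5, 5),
             trophic_phylo_mean = c(size_larger_troph_pm,
                                    other_troph_pm),
             stringsAsFactors = FALSE)
}

test_that("mechanism rules score the documented cases", {
  # higher trophic + migratory 50 vs 10 -> A, Bi, Bii; not Biii
  led <- classify_mechanisms("freshwater", "marine", "freshwater",
                             mk_summ(3.5, 3.0, mig_L = 50, mig_O = 10))
  expect_true(led$A); expect_true(led$Bi); expect_true(led$Bii)
  expect_false(led$Biii)
  expect_true(led$A_or_Biii); expect_true(led$any_of_four)

  # boundary: a gap of exactly 20 points supports Bi
  led20 <- classify_mechanisms("freshwater", "marine", "freshwater",
                               mk_summ(3.0, 3.5, mig_L = 25, mig_O = 5))
  expect_true(led20$Bi)
  expect_true(led20$Biii)   # Bi holds, A does not
  led19 <- classify_mechanisms("freshwater", "marine", "freshwater",
                               mk_summ(3.0, 3.5, mig_L = 24.9,
                                       mig_O = 5))
  expect_false(led19$Bi)

  # printed example row: A = 1, Bi = 0, C = 0, D = 1 -> union = 1
  led1 <- classify_mechanisms("freshwater", "marine", "freshwater",
                              mk_summ(3.5, 3.0, dur_L = 1, dur_O = 2,
                                      rich_L = 5, rich_O = 50))
  expect_equal(as.integer(c(led1$A, led1$Bi, led1$C, led1$D)),
               c(1L, 0L, 0L, 1L))
  expect_true(led1$any_of_four)

  # printed all-zero example row -> union = 0
  led0 <- classify_mechanisms("freshwater", "marine", "freshwater",
                              mk_summ(3.0, 3.5, dur_L = 1, dur_O = 2,
                                      rich_L = 50, rich_O = 5))
  expect_equal(as.integer(c(led0$A, led0$Bi, led0$C, led0$D)),
               c(0L, 0L, 0L, 0L))
  expect_false(led0$any_of_four)

  # missing migration data propagates as NA
  ledNA <- classify_mechanisms("freshwater", "marine", "freshwater",
                               mk_summ(3.5, 3.0, mig_L = NA))
  expect_true(is.na(ledNA$Bi))
})

test_that("aggregation reproduces ratio arithmetic and count identities", {
  led <- make_ledger(A = c(rep(TRUE, 9), rep(FALSE, 12),
                           rep(TRUE, 46), rep(FALSE, 25)),
                     Bi = c(rep(TRUE, 21), rep(FALSE, 71)),
                     C = rep(FALSE, 92), D = rep(FALSE, 92))
  agg <- aggregate_mechanisms(led)
  ov <- agg[agg$comparison == "overall", ]
  expect_equal(ov$Bi_n, 21); expect_equal(ov$Bii_n, 9)
  expect_equal(ov$Biii_n, 12)
  expect_equal(round(ov$Bii_prime, 1), 42.9)
  expect_equal(round(ov$Biii_prime, 1), 57.1)
  # Bii + Biii = Bi; union identity; monotone union
  for (s in 1:5) {
    rl <- with_seed_local(s, make_ledger(A = runif(30) < 0.5,
                                         Bi = runif(30) < 0.4,
                                         C = runif(30) < 0.5,
                                         D = runif(30) < 0.5))
    ag <- aggregate_mechanisms(rl)[1, ]
    expect_equal(ag$Bii_n + ag$Biii_n, ag$Bi_n)
    expect_equal(ag$A_or_Biii_n, ag$A_n + ag$Bi_n - ag$Bii_n)
    expect_gte(ag$any_of_four_n,
               max(ag$A_n, ag$Bi_n, ag$C_n, ag$D_n))
  }
  # Bi = 0 leaves the primed ratios undefined
  agg0 <- aggregate_mechanisms(make_ledger(A = c(TRUE, FALSE),
                                           Bi = c(FALSE, FALSE),
                                           C = c(FALSE, FALSE),
                                           D = c(FALSE, FALSE)))
  expect_true(is.na(agg0$Bii_prime[1]))
  expect_error(aggregate_mechanisms(NULL), "empty")
})

test_that("migration bands follow the documented cut points", {
  s <- data.frame(migratory_pct = c(31, 30, 5, 4.9, NA))
  b <- annotate_migration(s)$migration_band
  expect_equal(b, c("M", "m", "m", "none", NA))
})

test_that("the ledger built from a pipeline run respects its invariants", {
  sim <- simulate_dataset(sim_config(n_tips = 250, seed = 17))
  scales <- build_scales(sim$dataset, c("tax4", "full"))
  cfg <- list(metrics = c("mean_log10", "phylo_mean"),
              summary_metrics = TRUE, seed = 4)
  red <- reduce_and_retain(sim$dataset, scales, cfg)
  led <- mechanism_ledger(red)
  expect_true(!is.null(led))
  ok <- !is.na(led$A) & !is.na(led$Bi)
  expect_equal(led$Bii[ok], led$A[ok] & led$Bi[ok])
  expect_equal(led$Biii[ok], led$Bi[ok] & !led$A[ok])
  expect_equal(led$A_or_Biii[ok], led$A[ok] | led$Biii[ok])
  # every ledger row corresponds to a retained comparison
  ret <- red$retained[red$retained$retained, ]
  expect_true(all(paste(led$scale, led$clade_id, led$first, led$second)
                  %in% paste(ret$scale, ret$clade_id, ret$first,
                             ret$second)))
})
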