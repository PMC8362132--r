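engine_fixture <- function() {
  # 24-tip star dataset, 3 habitats x 8 taxa, known offsets
  tree <- star_tree(24, labels = sprintf("sp%02d", 1:24))
  hab <- rep(c("freshwater", "marine", "euryhaline"), each = 8)
  size <- with_seed_local(1, rnorm(24, 0, 0.05)) +
    rep(c(1, 1.4, 1.8), each = 8)
  rec <- taxon_records(sprintf("sp%02d", 1:24), hab, size,
                       trophic_level = 3, migratory = FALSE,
                       family = rep(c("f1", "f2"), 12),
                       order = rep(c("o1", "o2"), each = 12))
  match_tree_table(tree, rec)
}

test_that("enumeration respects min_n and logs skipped pairs", {
  ds <- engine_fixture()
  scales <- list(full = build_scales(ds, "full")$full)
  e <- enumerate_comparisons(ds, scales, min_n = 3)
  expect_equal(nrow(e), 3)  # three habitats -> three canonical pairs
  expect_true(all(e$first %in% habitat_levels(TRUE)))

  # single-habitat clade yields no pairs
  one <- prune_dataset(ds, ds$records$species[ds$records$habitat ==
                                                "marine"])
  e1 <- enumerate_comparisons(one, list(full = build_scales(one,
                                                            "full")$full))
  expect_equal(nrow(e1), 0)

  # min_n excludes a habitat with fewer taxa and logs it
  small <- prune_dataset(ds, ds$records$species[c(1:8, 9:10, 17:24)])
  es <- enumerate_comparisons(small,
                              list(full = build_scales(small,
                                                       "full")$full),
                              min_n = 3)
  expect_equal(nrow(es), 1)
  expect_true(any(grepl("below min_n", attr(es, "skipped")$reason)))
})

test_that("run_all conserves the enumeration, is deterministic, and
           recovers the generating order", {
  ds <- engine_fixture()
  # labels on a star tree are never monophyletic; that is the point of
  # the warning, silenced here
  scales <- suppressWarnings(build_scales(ds, c("order", "full")))
  cfg <- list(n_sim = 49, n_perm = 49, seed = 3)
  res <- run_all(ds, scales, cfg)
  e <- enumerate_comparisons(ds, scales)
  # every enumerated comparison has one row per size metric
  expect_equal(sum(res$metric == "mean_log10"), nrow(e))
  expect_equal(sum(res$metric == "phylo_mean"), nrow(e))
  res2 <- run_all(ds, scales, cfg)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # clean separation: all size metrics point the generator's way
  sz <- res[res$metric %in% c("mean_log10", "phylo_mean", "wilcoxon"), ]
  expected <- c(freshwater = 1, marine = 1.4, euryhaline = 1.8)
  right <- ifelse(expected[sz$first] > expected[sz$second],
                  sz$first, sz$second)
  expect_true(all(sz$larger_habitat == right))
})

test_that("majority summaries tally directions and handle ties", {
  res <- fake_results(scale = "order",
                      clade_id = sprintf("c%d", 1:10),
                      first = "freshwater", second = "marine",
                      metric = "mean_log10",
                      diff = c(rep(1, 8), -1, -1))
  m <- majority_summaries(res, "mean_log10")
  expect_equal(m$n_clades, 10)
  expect_equal(m$pct_first_larger, 80)

  res_tie <- fake_results("order", sprintf("c%d", 1:4), "freshwater",
                          "marine", "mean_log10", rep(0, 4))
  mt <- majority_summaries(res_tie, "mean_log10")
  expect_equal(mt$n_tie, 4)
  expect_true(is.na(mt$pct_first_larger))

  # recount oracle against the raw rows
  ds <- engine_fixture()
  scales <- suppressWarnings(build_scales(ds, c("order", "full")))
  res3 <- run_all(ds, scales, list(metrics = "mean_log10",
                                   summary_metrics = FALSE, seed = 1))
  m3 <- majority_summaries(res3, "mean_log10")
  for (i in seq_len(nrow(m3))) {
    rows <- res3[res3$scale == m3$scale[i] & res3$first == m3$first[i] &
                   res3$second == m3$second[i] &
                   res3$metric == "mean_log10", ]
    expect_equal(m3$n_first_larger[i],
                 sum(rows$larger_habitat == rows$first))
    expect_equal(m3$n_clades[i], nrow(rows))
  }
  # counts sum to clades per scale/pair
  expect_true(all(m3$n_first_larger + m3$n_second_larger + m3$n_tie ==
                    m3$n_clades))
})

test_that("pair reversal antisymmetry holds at the metric level", {
  a <- c(1.2, 1.4, 1.1); b <- c(0.9, 1.0, 0.8, 1.1)
  expect_equal(mean_log10_diff(a, b)$signed_difference,
               -mean_log10_diff(b, a)$signed_difference)
  expect_equal(wilcoxon_rank_sum(a, b)$signed_difference,
               -wilcoxon_rank_sum(b, a)$signed_difference)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
})

test_that("reduce_and_retain drops exactly the comparison whose direction
           flips after pruning", {
  ds <- flip_fixture()
  scales <- build_scales(ds, "full")
  cfg <- list(metrics = c("mean_log10", "phylo_mean"),
              summary_metrics = TRUE, seed = 2)
  full <- run_all(ds, scales, cfg)
  fm <- full[full$metric == "phylo_mean" & full$first == "freshwater" &
               full$second == "marine", ]
  expect_equal(fm$larger_habitat, "freshwater")  # 2.1 vs 2.0
  red <- reduce_and_retain(ds, scales, cfg, full_results = full)
  ret <- red$retained
  flipped <- ret[ret$first == "freshwater" & ret$second == "marine", ]
  expect_false(flipped$retained)
  others <- ret[!(ret$first == "freshwater" & ret$second == "marine"), ]
  expect_true(all(others$retained))
  # retained count equals a recount of direction matches
  pm_f <- full[full$metric == "phylo_mean", ]
  pm_p <- red$results[red$results$metric == "phylo_mean", ]
  key <- function(d) paste(d$scale, d$clade_id, d$first, d$second)
  agree <- pm_p$larger_habitat ==
    pm_f$larger_habitat[match(key(pm_p), key(pm_f))]
  expect_equal(sum(ret$retained), sum(agree & pm_p$larger_habitat !=
                                        "tie"))
})

test_that("no trophic data at all is an error", {
  ds <- engine_fixture()
  ds$records$trophic_level <- NA_real_
  expect_error(reduce_and_retain(ds, build_scales(ds, "full"),
                                 list(seed = 1)),
               "no taxa with trophic data")
})
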