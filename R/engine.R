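#' @title Comparison engine
#' @description Enumerates every clade x habitat-pair comparison at every
#'   observation scale, runs the requested metrics, tallies majority
#'   percentages across clades, and applies the reduced-and-retained
#'   protocol that anchors the trophic and mechanism analyses.
#' @name comparison-engine
NULL

SIZE_METRICS <- c("mean_log10", "phylo_mean", "wilcoxon", "phylo_anova",
                  "pgls_anova")
SUMMARY_METRICS <- c("richness", "tip_duration", "migratory_pct",
                     "trophic_mean", "trophic_phylo_mean")
VARIANCE_METRICS <- c("var_vs_sim_size", "var_vs_sim_trophic")

#' Enumerate feasible clade x habitat-pair comparisons
#'
#' A pair is feasible within a clade when both habitats have at least
#' `min_n` taxa there.  Exclusively brackish taxa never enter pairwise
#' comparisons.  Skipped pairs (one habitat present but under `min_n`)
#' are logged on the `"skipped"` attribute.
#'
#' @param dataset a `habitat_dataset`.
#' @param scales named list of `clade_scale` objects.
#' @param min_n minimum taxa per habitat per clade (default 3).
#' @return data.frame (scale, clade_id, first, second, n_first, n_second)
#'   with a `"skipped"` attribute.
#' @export
enumerate_comparisons <- function(dataset, scales, min_n = 3) {
  pairs <- habitat_pairs()
  rows <- list(); skipped <- list()
  for (sc in scales) {
    for (cid in names(sc$clades)) {
      rec <- dataset$records[dataset$records$species %in% sc$clades[[cid]], ]
      cnt <- table(factor(rec$habitat, levels = habitat_levels(TRUE)))
      for (i in seq_len(nrow(pairs))) {
        n1 <- cnt[[pairs$first[i]]]; n2 <- cnt[[pairs$second[i]]]
        if (n1 >= min_n && n2 >= min_n) {
          rows[[length(rows) + 1L]] <-
            data.frame(scale = sc$scale_name, clade_id = cid,
                       first = pairs$first[i], second = pairs$second[i],
                       n_first = n1, n_second = n2,
                       stringsAsFactors = FALSE)
        } else if (n1 > 0 && n2 > 0) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(scale = sc$scale_name, clade_id = cid,
                       first = pairs$first[i], second = pairs$second[i],
                       reason = sprintf("n below min_n (%d, %d)", n1, n2),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scale = character(0), clade_id = character(0),
               first = character(0), second = character(0),
               n_first = integer(0), n_second = integer(0))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  out
}

significance_band <- function(p) {
  ifelse(is.na(p), "none",
         ifelse(p < 0.05, "p<0.05", ifelse(p < 0.1, "p<0.1", "none")))
}

orient_outcome <- function(out, first, levels_first) {
  # metric helpers order groups alphabetically; flip the sign so that
  # positive always means the canonical first habitat is larger
  if (!identical(levels_first, first)) {
    out$signed_difference <- -out$signed_difference
    if (!is.na(out$larger))
      out$larger <- switch(out$larger, first = "second",
                           second = "first", out$larger)
  }
  out
}

result_row <- function(scale, clade_id, first, second, metric, out) {
  larger <- if (is.na(out$larger)) NA_character_ else
    switch(out$larger, first = first, second = second, tie = "tie")
  data.frame(scale = scale, clade_id = clade_id, first = first,
             second = second, metric = metric,
             n_first = out$n_first, n_second = out$n_second,
             signed_difference = out$signed_difference,
             larger_habitat = larger, p_value = out$p_value,
             significance_band = significance_band(out$p_value),
             stringsAsFactors = FALSE)
}

summary_diff_row <- function(scale, cid, first, second, metric, v1, v2,
                             n1, n2) {
  d <- if (is.na(v1) || is.na(v2)) NA_real_ else v1 - v2
  out <- metric_outcome(metric, d, n_first = n1, n_second = n2)
  result_row(scale, cid, first, second, metric, out)
}

#' Run all metrics over every enumerated comparison
#'
#' @param dataset a `habitat_dataset`.
#' @param scales named list of `clade_scale` objects.
#' @param config list of parameters: `min_n` (3), `metrics`
#'   (size metrics to run), `summary_metrics` (logical, include richness /
#'   tip duration / migratory / trophic difference rows), `variance_metrics`
#'   (logical, include variance-vs-simulated quantile differences),
#'   `n_sim`, `n_perm` (999), `seed`.
#' @return a `comparison_results` data.frame in long format (one row per
#'   clade x pair x metric) with attributes `summaries` (per clade x
#'   habitat summary table) and `skipped`.
#' @export
run_all <- function(dataset, scales, config = list()) {
  cfg <- utils::modifyList(list(min_n = 3, metrics = SIZE_METRICS,
                                summary_metrics = TRUE,
                                variance_metrics = FALSE,
                                n_sim = 999, n_perm = 999, seed = 1L),
                           config)
  enum <- enumerate_comparisons(dataset, scales, cfg$min_n)
  clade_keys <- unique(enum[, c("scale", "clade_id")])
  seeds <- derive_seeds(cfg$seed, max(nrow(enum), 1) * 2L +

                          max(nrow(clade_keys), 1))
  rows <- list(); summ_rows <- list()
  si <- 0L
  for (ci in seq_len(nrow(clade_keys))) {
    scname <- clade_keys$scale[ci]; cid <- clade_keys$clade_id[ci]
    tips <- scales[[which(vapply(scales, function(s)
      s$scale_name == scname, logical(1)))[1]]]$clades[[cid]]
    sub <- enum[enum$scale == scname & enum$clade_id == cid, ]
    cds <- prune_dataset(dataset, tips)
    summ <- habitat_summaries(cds)
    if (isTRUE(cfg$variance_metrics)) {
      si <- si + 1L
      vs <- clade_variance_quantiles(cds, cfg$n_sim, seeds[length(seeds) -
                                                            si + 1L])
      summ <- merge(summ, vs, by = "habitat", all.x = TRUE, sort = FALSE)
    }
    summ_rows[[ci]] <- cbind(scale = scname, clade_id = cid, summ)
    pm <- setNames(summ$size_phylo_mean, summ$habitat)
    for (ri in seq_len(nrow(sub))) {
      first <- sub$first[ri]; second <- sub$second[ri]
      ei <- which(enum$scale == scname & enum$clade_id == cid &
                    enum$first == first & enum$second == second)[1]
      rec <- cds$records
      va <- rec$log10_size[rec$habitat == first]
      vb <- rec$log10_size[rec$habitat == second]
      if ("mean_log10" %in% cfg$metrics)
        rows[[length(rows) + 1L]] <-
          result_row(scname, cid, first, second, "mean_log10",
                     mean_log10_diff(va, vb))
      if ("phylo_mean" %in% cfg$metrics) {
        out <- metric_outcome("phylo_mean", pm[[first]] - pm[[second]],
                              n_first = length(va), n_second = length(vb))
        rows[[length(rows) + 1L]] <-
          result_row(scname, cid, first, second, "phylo_mean", out)
      }
      if ("wilcoxon" %in% cfg$metrics)
        rows[[length(rows) + 1L]] <-
          result_row(scname, cid, first, second, "wilcoxon",
                     wilcoxon_rank_sum(va, vb))
      if (any(c("phylo_anova", "pgls_anova") %in% cfg$metrics)) {
        ptips <- rec$species[rec$habitat %in% c(first, second)]
        pair_ds <- try(prune_dataset(cds, ptips), silent = TRUE)
        if (!inherits(pair_ds, "try-error")) {
          py <- setNames(pair_ds$records$log10_size,
                         pair_ds$records$species)
          pg <- pair_ds$records$habitat
          lev1 <- levels(factor(pg))[1]
          if ("phylo_anova" %in% cfg$metrics) {
            out <- try(phylo_anova_sim(pair_ds$tree, py, pg, cfg$n_sim,
                                       seed = seeds[2L * ei - 1L]),
                       silent = TRUE)
            if (!inherits(out, "try-error"))
              rows[[length(rows) + 1L]] <-
                result_row(scname, cid, first, second, "phylo_anova",
                           orient_outcome(out, first, lev1))
          }
          if ("pgls_anova" %in% cfg$metrics) {
            out <- try(pgls_anova_perm(pair_ds$tree, py, pg, cfg$n_perm,
                                       seed = seeds[2L * ei]),
                       silent = TRUE)
            if (!inherits(out, "try-error"))
              rows[[length(rows) + 1L]] <-
                result_row(scname, cid, first, second, "pgls_anova",
                           orient_outcome(out, first, lev1))
          }
        }
      }
      if (isTRUE(cfg$summary_metrics)) {
        s1 <- summ[summ$habitat == first, ]; s2 <- summ[summ$habitat == second, ]
        add <- function(metric, col)
          rows[[length(rows) + 1L]] <<-
            summary_diff_row(scname, cid, first, second, metric,
                             s1[[col]], s2[[col]], s1$richness, s2$richness)
        add("richness", "richness")
        add("tip_duration", "mean_tip_duration")
        add("migratory_pct", "migratory_pct")
        add("trophic_mean", "trophic_mean")
        add("trophic_phylo_mean", "trophic_phylo_mean")
        if (isTRUE(cfg$variance_metrics)) {
          add("var_vs_sim_size", "var_q_size")
          add("var_vs_sim_trophic", "var_q_trophic")
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scale = character(0), clade_id = character(0),
               first = character(0), second = character(0),
               metric = character(0), n_first = integer(0),
               n_second = integer(0), signed_difference = numeric(0),
               larger_habitat = character(0), p_value = numeric(0),
               significance_band = character(0))
  structure(out,
            summaries = if (length(summ_rows)) do.call(rbind, summ_rows)
              else NULL,
            skipped = attr(enum, "skipped"),
            class = c("comparison_results", "data.frame"))
}

# variance-vs-simulated quantile per habitat for size and trophic level
clade_variance_quantiles <- function(cds, n_sim, seed) {
  rec <- cds$records
  habs <- intersect(habitat_levels(), unique(rec$habitat))
  qs <- data.frame(habitat = habs, var_q_size = NA_real_,
                   var_q_trophic = NA_real_)
  seeds <- derive_seeds(seed, 2L * length(habs))
  for (i in seq_along(habs)) {
    tips <- rec$species[rec$habitat == habs[i]]
    if (length(tips) >= 2) {
      v <- try(variance_vs_sim(cds$tree,
                               setNames(rec$log10_size, rec$species),
                               tips, n_sim, seed = seeds[2L * i - 1L]),
               silent = TRUE)
      if (!inherits(v, "try-error")) qs$var_q_size[i] <- v$quantile
    }
    tt <- rec$species[rec$habitat == habs[i] & !is.na(rec$trophic_level)]
    tall <- rec$species[!is.na(rec$trophic_level)]
    if (length(tt) >= 2 && length(tall) >= 3) {
      sub <- try(prune_dataset(cds, tall), silent = TRUE)
      if (!inherits(sub, "try-error")) {
        v <- try(variance_vs_sim(sub$tree,
                                 setNames(sub$records$trophic_level,
                                          sub$records$species),
                                 tt, n_sim, seed = seeds[2L * i]),
                 silent = TRUE)
        if (!inherits(v, "try-error")) qs$var_q_trophic[i] <- v$quantile
      }
    }
  }
  qs
}

#' Majority summaries across clades (figure-2-style cells)
#'
#' For each scale x habitat pair, the percentage of clades in which the
#' first-listed habitat holds the larger value of `metric`.  Ties are
#' excluded from the percentage denominator.
#'
#' @param results a `comparison_results` object.
#' @param metric metric name.
#' @return data.frame (scale, first, second, metric, n_clades,
#'   n_first_larger, n_second_larger, n_tie, pct_first_larger).
#' @export
majority_summaries <- function(results, metric) {
  df <- results[results$metric == metric & !is.na(results$larger_habitat), ]
  if (!nrow(df)) return(NULL)
  key <- interaction(df$scale, df$first, df$second, drop = TRUE)
  do.call(rbind, lapply(split(df, key), function(d) {
    nf <- sum(d$larger_habitat == d$first)
    ns <- sum(d$larger_habitat == d$second)
    nt <- sum(d$larger_habitat == "tie")
    data.frame(scale = d$scale[1], first = d$first[1], second = d$second[1],
               metric = metric, n_clades = nrow(d), n_first_larger = nf,
               n_second_larger = ns, n_tie = nt,
               pct_first_larger = if (nrow(d) > nt)
                 100 * nf / (nrow(d) - nt) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Order-scale donut table
#'
#' Counts of which habitat holds the larger mean per pair at one scale,
#' with circle completeness = number of clades supporting the pair
#' relative to the best-sampled pair.
#'
#' @param results a `comparison_results` object.
#' @param metric metric used for direction.
#' @param scale scale name (default `"order"`).
#' @return data.frame with counts and `completeness`.
#' @export
donut_table <- function(results, metric = "mean_log10", scale = "order") {
  maj <- majority_summaries(results[results$scale == scale, ], metric)
  if (is.null(maj)) return(NULL)
  maj$completeness <- maj$n_clades / max(maj$n_clades)
  maj
}

#' The reduced-and-retained protocol
#'
#' Prunes the dataset to taxa with known trophic level, reruns the size
#' comparisons on the pruned data, and retains only comparisons whose
#' size direction (on the anchoring metric, the phylogenetic mean by
#' default; all five size metrics in strict mode) matches the full-data
#' direction.  All downstream trophic and mechanism analyses use retained
#' comparisons only.
#'
#' @param dataset full `habitat_dataset`.
#' @param scales scales built on the full dataset.
#' @param config engine config (see [run_all()]); `anchor_metric`
#'   (default `"phylo_mean"`) and `strict` (default `FALSE`) control
#'   retention.
#' @param full_results optional precomputed full-data results.
#' @return list with `dataset` (pruned), `scales` (restricted), `results`
#'   (pruned-data comparison results including trophic metrics), and
#'   `retained` (data.frame keyed by scale/clade/pair with a logical
#'   `retained` flag), plus `dropped` (comparisons lost to min_n).
#' @export
reduce_and_retain <- function(dataset, scales, config = list(),
                              full_results = NULL) {
  cfg <- utils::modifyList(list(anchor_metric = "phylo_mean",
                                strict = FALSE), config)
  anchors <- if (isTRUE(cfg$strict)) SIZE_METRICS else cfg$anchor_metric
  eng_cfg <- config
  eng_cfg$metrics <- union(config$metrics %||% SIZE_METRICS, anchors)
  if (is.null(full_results))
    full_results <- run_all(dataset, scales, eng_cfg)
  keep <- dataset$records$species[!is.na(dataset$records$trophic_level)]
  if (length(keep) < 2)
    stop("no taxa with trophic data", call. = FALSE)
  pruned <- prune_dataset(dataset, keep)
  rscales <- restrict_scales(scales, keep)
  pruned_results <- run_all(pruned, rscales, eng_cfg)
  key <- function(d) paste(d$scale, d$clade_id, d$first, d$second, d$metric)
  fa <- full_results[full_results$metric %in% anchors, ]
  pa <- pruned_results[pruned_results$metric %in% anchors, ]
  m <- match(key(pa), key(fa))
  agree <- !is.na(m) &
    pa$larger_habitat == fa$larger_habitat[m] &
    pa$larger_habitat != "tie"
  ckey <- paste(pa$scale, pa$clade_id, pa$first, pa$second)
  retained_by_cmp <- tapply(agree, ckey, all)
  ucmp <- unique(pa[, c("scale", "clade_id", "first", "second")])
  ucmp$retained <- as.logical(
    retained_by_cmp[paste(ucmp$scale, ucmp$clade_id, ucmp$first,
                          ucmp$second)])
  full_cmp <- unique(fa[, c("scale", "clade_id", "first", "second")])
  dropped <- full_cmp[!(paste(full_cmp$scale, full_cmp$clade_id,
                              full_cmp$first, full_cmp$second) %in%
                          paste(ucmp$scale, ucmp$clade_id, ucmp$first,
                                ucmp$second)), ]
  list(dataset = pruned, scales = rscales, results = pruned_results,
       retained = ucmp, dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
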