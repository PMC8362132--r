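#' @title Metric alignment and mechanism support
#' @description Percentage alignments between metric pairs across clades,
#'   continuous signed-difference regressions, and the rule-based
#'   classifier of support for four suites of mechanisms that could drive
#'   size-by-habitat patterns: trophic level (A), migration (Bi, with the
#'   joint and strong variants Bii and Biii), lineage age / Deperet-style
#'   trends (C), and reduced ecological limits via low species richness
#'   (D).
#' @name alignment-mechanisms
NULL

#' Percentage alignment between two metrics
#'
#' Two metrics are aligned in a clade when the same habitat holds the
#' larger value under both.  Ties and missing outcomes are excluded from
#' the denominator and logged on the `"excluded"` attribute.
#'
#' @param results a `comparison_results` object.
#' @param metric1,metric2 metric names.
#' @return data.frame (scale, first, second, metric_pair, n_compared,
#'   n_aligned, pct_aligned).
#' @export
percentage_alignment <- function(results, metric1, metric2) {
  key <- function(d) paste(d$scale, d$clade_id, d$first, d$second)
  d1 <- results[results$metric == metric1, ]
  d2 <- results[results$metric == metric2, ]
  m <- match(key(d1), key(d2))
  ok <- !is.na(m)
  d1 <- d1[ok, ]; d2 <- d2[m[ok], ]
  usable <- !is.na(d1$larger_habitat) & !is.na(d2$larger_habitat) &
    d1$larger_habitat != "tie" & d2$larger_habitat != "tie"
  excluded <- d1[!usable, c("scale", "clade_id", "first", "second")]
  d1 <- d1[usable, ]; d2 <- d2[usable, ]
  if (!nrow(d1)) {
    out <- data.frame(scale = character(0), first = character(0),
                      second = character(0), metric_pair = character(0),
                      n_compared = integer(0), n_aligned = integer(0),
                      pct_aligned = numeric(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  aligned <- d1$larger_habitat == d2$larger_habitat
  grp <- interaction(d1$scale, d1$first, d1$second, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(aligned), grp), function(i) {
    data.frame(scale = d1$scale[i[1]], first = d1$first[i[1]],
               second = d1$second[i[1]],
               metric_pair = paste(metric1, metric2, sep = "|"),
               n_compared = length(i), n_aligned = sum(aligned[i]),
               pct_aligned = 100 * sum(aligned[i]) / length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Continuous association between two metrics' signed differences
#'
#' Ordinary least-squares regression of the clade-level signed difference
#' in `metricY` on the signed difference in `metricX` for one habitat
#' pair at one scale, with sign-quadrant counts (agreement = both
#' differences share a sign) and a leave-one-out report flagging clades
#' whose removal flips the slope's significance at 0.05.
#'
#' @param results a `comparison_results` object.
#' @param metricX,metricY metric names.
#' @param first,second habitat pair.
#' @param scale scale name.
#' @return list `slope`, `r2`, `p`, `n`, `quadrant_counts` (agree_pos,
#'   agree_neg, mismatch_x_pos, mismatch_y_pos), `influential` (clade ids).
#' @export
continuous_association <- function(results, metricX, metricY, first,
                                   second, scale) {
  sel <- results$scale == scale & results$first == first &
    results$second == second
  dx <- results[sel & results$metric == metricX, ]
  dy <- results[sel & results$metric == metricY, ]
  m <- match(dx$clade_id, dy$clade_id)
  ok <- !is.na(m) & !is.na(dx$signed_difference) &
    !is.na(dy$signed_difference[m])
  x <- dx$signed_difference[ok]
  y <- dy$signed_difference[m[ok]]
  ids <- dx$clade_id[ok]
  if (length(x) < 3)
    stop("need >= 3 clades with both differences", call. = FALSE)
  quad <- c(agree_pos = sum(x > 0 & y > 0),
            agree_neg = sum(x < 0 & y < 0),
            mismatch_x_pos = sum(x > 0 & y < 0),
            mismatch_y_pos = sum(x < 0 & y > 0))
  if (var(x) == 0) {
    return(list(slope = NA_real_, r2 = NA_real_, p = NA_real_,
                n = length(x), quadrant_counts = quad,
                influential = character(0)))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  p <- sm$coefficients[2, 4]
  infl <- character(0)
  if (length(x) > 3) {
    sig <- p < 0.05
    for (i in seq_along(x)) {
      if (var(x[-i]) == 0) next
      pi <- suppressWarnings(
        summary(lm(y[-i] ~ x[-i]))$coefficients[2, 4])
      if ((pi < 0.05) != sig) infl <- c(infl, ids[i])
    }
  }
  list(slope = unname(coef(fit)[2]), r2 = sm$r.squared, p = p,
       n = length(x), quadrant_counts = quad, influential = infl)
}

#' Classify mechanism support for one habitat comparison
#'
#' Given which habitat holds the larger phylogenetic mean size and the
#' per-habitat summaries for the clade, scores:
#' \describe{
#'   \item{A}{size-larger habitat has the higher phylogenetic mean
#'     trophic level (`A_prime` uses the non-phylogenetic mean).}
#'   \item{Bi}{size-larger habitat's migratory percentage exceeds the
#'     other's by at least `bi_threshold` percentage points (>= 20 by
#'     default, boundary counts as supported).}
#'   \item{Bii}{A and Bi both hold.}
#'   \item{Biii}{Bi holds but A does not.}
#'   \item{C}{size-larger habitat has the strictly larger mean tip branch
#'     duration.}
#'   \item{D}{size-larger habitat has the strictly lower species richness
#'     within the clade.}
#'   \item{A_or_Biii, any_of_four}{unions `A | Biii` and
#'     `A | Bi | C | D`; no comparison is counted more than once.}
#' }
#' Indicators whose inputs are missing are `NA` and are excluded from
#' aggregate denominators.
#'
#' @param first,second the habitat pair (canonical order).
#' @param size_larger which habitat holds the larger size
#'   (`first`/`second` habitat name).
#' @param summ per-habitat summary data.frame for the clade (see
#'   [habitat_summaries()]).
#' @param bi_threshold migratory-percentage gap for Bi, in points.
#' @return one-row data.frame of indicator columns.
#' @export
classify_mechanisms <- function(first, second, size_larger, summ,
                                bi_threshold = 20) {
  stopifnot(size_larger %in% c(first, second))
  other <- if (size_larger == first) second else first
  sL <- summ[summ$habitat == size_larger, ]
  sO <- summ[summ$habitat == other, ]
  if (nrow(sL) != 1 || nrow(sO) != 1)
    stop("summaries must contain exactly one row per habitat",
         call. = FALSE)
  cmpgt <- function(a, b) if (is.na(a) || is.na(b)) NA else a > b
  A  <- cmpgt(sL$trophic_phylo_mean, sO$trophic_phylo_mean)
  Ap <- cmpgt(sL$trophic_mean, sO$trophic_mean)
  Bi <- if (is.na(sL$migratory_pct) || is.na(sO$migratory_pct)) NA
        else sL$migratory_pct >= sO$migratory_pct + bi_threshold
  Bii  <- A & Bi
  Biii <- Bi & !A
  C <- cmpgt(sL$mean_tip_duration, sO$mean_tip_duration)
  D <- cmpgt(sO$richness, sL$richness)
  data.frame(first = first, second = second, size_larger = size_larger,
             A = A, A_prime = Ap, Bi = Bi, Bii = Bii, Biii = Biii,
             C = C, D = D,
             A_or_Biii = A | Biii,
             any_of_four = A | Bi | C | D,
             stringsAsFactors = FALSE)
}

#' Build the mechanism ledger for all retained comparisons
#'
#' @param reduced result of [reduce_and_retain()].
#' @param bi_threshold migratory gap threshold for Bi.
#' @param size_metric metric anchoring the size direction (default the
#'   phylogenetic mean).
#' @return data.frame, one row per retained comparison, with indicator
#'   columns (a "mechanism ledger").
#' @export
mechanism_ledger <- function(reduced, bi_threshold = 20,
                             size_metric = "phylo_mean") {
  res <- reduced$results
  summaries <- attr(res, "summaries")
  ret <- reduced$retained[!is.na(reduced$retained$retained) &
                            reduced$retained$retained, ]
  size_rows <- res[res$metric == size_metric, ]
  key <- function(d) paste(d$scale, d$clade_id, d$first, d$second)
  m <- match(key(ret), key(size_rows))
  out <- list()
  for (i in seq_len(nrow(ret))) {
    if (is.na(m[i])) next
    sl <- size_rows$larger_habitat[m[i]]
    if (is.na(sl) || sl == "tie") next
    summ <- summaries[summaries$scale == ret$scale[i] &
                        summaries$clade_id == ret$clade_id[i], ]
    led <- classify_mechanisms(ret$first[i], ret$second[i], sl, summ,
                               bi_threshold)
    out[[length(out) + 1L]] <-
      cbind(scale = ret$scale[i], clade_id = ret$clade_id[i], led)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Aggregate a mechanism ledger into per-pair and overall summaries
#'
#' Reports, for each habitat pair and overall, the count and percentage
#' of comparisons supporting each indicator, plus the ratios
#' `Bii_prime = Bii / Bi` and `Biii_prime = Biii / Bi` (as percentages of
#' Bi-supported comparisons, `NA` when Bi = 0).  Comparisons with a
#' missing indicator are excluded from that indicator's denominator.
#'
#' @param ledger data.frame from [mechanism_ledger()] or any data.frame
#'   with logical columns `A`, `A_prime`, `Bi`, `Bii`, `Biii`, `C`, `D`,
#'   `A_or_Biii`, `any_of_four`.
#' @return data.frame, one row per habitat pair plus an `overall` row;
#'   columns `<ind>_n`, `<ind>_total`, `<ind>_pct` for each indicator and
#'   `Bii_prime` / `Biii_prime`.
#' @export
aggregate_mechanisms <- function(ledger) {
  if (is.null(ledger) || !nrow(ledger))
    stop("empty mechanism ledger", call. = FALSE)
  inds <- c("A", "A_prime", "Bi", "Bii", "Biii", "C", "D",
            "A_or_Biii", "any_of_four")
  one <- function(d, label) {
    row <- data.frame(comparison = label, n_comparisons = nrow(d),
                      stringsAsFactors = FALSE)
    for (ind in inds) {
      v <- d[[ind]]
      tot <- sum(!is.na(v)); n <- sum(v, na.rm = TRUE)
      row[[paste0(ind, "_n")]] <- n
      row[[paste0(ind, "_total")]] <- tot
      row[[paste0(ind, "_pct")]] <- if (tot) 100 * n / tot else NA_real_
    }
    nbi <- row$Bi_n
    row$Bii_prime <- if (nbi > 0) 100 * row$Bii_n / nbi else NA_real_
    row$Biii_prime <- if (nbi > 0) 100 * row$Biii_n / nbi else NA_real_
    row
  }
  pairs <- unique(ledger[, c("first", "second")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- ledger[ledger$first == pairs$first[i] &
                  ledger$second == pairs$second[i], ]
    one(d, paste(pairs$first[i], "vs", pairs$second[i]))
  })
  out <- rbind(one(ledger, "overall"), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Migration bands for figure annotation
#'
#' `M` for habitats with more than 30% migratory species, `m` for 5-30%
#' (inclusive), `none` below 5%.
#'
#' @param summaries per-clade habitat summary table (attribute of
#'   [run_all()] results, or [habitat_summaries()] output).
#' @return the input with a `migration_band` column appended.
#' @export
annotate_migration <- function(summaries) {
  p <- summaries$migratory_pct
  summaries$migration_band <- ifelse(is.na(p), NA_character_,
                                     ifelse(p > 30, "M",
                                            ifelse(p >= 5, "m", "none")))
  summaries
}
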