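#' @title Observation scales
#' @description A `clade_scale` is a named set of tip sets (clades) over
#'   which every pairwise habitat comparison is run.  Nine scales are used:
#'   family, order, four tree partitions of decreasing resolution (tax3 =
#'   13 sections, tax4 = 9, tax5 = 5, tax6 = 3), the full dataset, and
#'   transition hotspots (plain and expanded).
#' @name observation-scales
NULL

new_clade_scale <- function(scale_name, clades, flags = list()) {
  structure(list(scale_name = scale_name, clades = clades, flags = flags),
            class = "clade_scale")
}

#' @export
print.clade_scale <- function(x, ...) {
  cat("clade_scale '", x$scale_name, "': ", length(x$clades),
      " clades, sizes ", paste(range(lengths(x$clades)), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Build an observation scale from family or order labels
#'
#' One clade per distinct label.  Labels need not be monophyletic on the
#' tree; non-monophyletic labels are emitted with a warning, and singleton
#' clades are flagged.
#'
#' @param dataset a `habitat_dataset`.
#' @param level `"family"` or `"order"`.
#' @return a `clade_scale`.
#' @export
scale_from_labels <- function(dataset, level = c("family", "order")) {
  level <- match.arg(level)
  lab <- dataset$records[[level]]
  if (anyNA(lab) || any(lab == ""))
    stop("missing ", level, " labels for: ",
         paste(head(dataset$records$species[is.na(lab) | lab == ""], 10),
               collapse = ", "), call. = FALSE)
  clades <- split(dataset$records$species, lab)
  sets <- node_tip_sets(dataset$tree)
  nonmono <- character(0)
  for (nm in names(clades)) {
    tips <- clades[[nm]]
    if (length(tips) < 2) next
    mrca <- ape::getMRCA(dataset$tree, tips)
    if (length(sets[[mrca]]) != length(tips)) nonmono <- c(nonmono, nm)
  }
  if (length(nonmono))
    warning("non-monophyletic ", level, " labels: ",
            paste(nonmono, collapse = ", "), call. = FALSE)
  new_clade_scale(level, clades,
                  flags = list(singletons = names(clades)[lengths(clades) == 1],
                               non_monophyletic = nonmono))
}

#' Partition a tree into k monophyletic sections
#'
#' Starting from the root clade, iteratively splits the section with the
#' most tips at its root node until `k` sections exist.  Ties on size are
#' broken by the lexicographically smallest contained tip label, making the
#' partition deterministic and invariant to the tip order of the input
#' Newick.  Section ids are the smallest contained tip label.
#'
#' @param tree a `phylo` tree.
#' @param k requested number of sections (1 <= k <= number of tips).
#' @param scale_name name recorded on the resulting scale.
#' @return a `clade_scale` whose clades are disjoint, monophyletic, and
#'   jointly cover all tips.
#' @export
partition_tree <- function(tree, k, scale_name = paste0("part", k)) {
  nt <- length(tree$tip.label)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nt) stop("k exceeds number of tips", call. = FALSE)
  sets <- node_tip_sets(tree)
  kids <- node_children(tree)
  active <- root_node(tree)
  while (length(active) < k) {
    sizes <- lengths(sets[active])
    splittable <- active[sizes > 1]
    if (!length(splittable)) break
    ssz <- lengths(sets[splittable])
    cand <- splittable[ssz == max(ssz)]
    if (length(cand) > 1) {
      minlab <- vapply(cand, function(nd)
        min(tree$tip.label[sets[[nd]]]), character(1))
      cand <- cand[order(minlab)][1]
    }
    ch <- kids[[cand[1]]]
    if (length(active) - 1L + length(ch) > k)
      warning("polytomy split overshoots k; returning ",
              length(active) - 1L + length(ch), " sections", call. = FALSE)
    active <- c(setdiff(active, cand[1]), ch)
  }
  clades <- lapply(active, function(nd) sort(tree$tip.label[sets[[nd]]]))
  names(clades) <- vapply(clades, `[`, character(1), 1)
  clades <- clades[order(names(clades))]
  new_clade_scale(scale_name, clades)
}

#' Build the transition-hotspot observation scale
#'
#' Hotspots are the candidate clades (the order scale by default) with the
#' highest rate of habitat transition events per tip, measured from a
#' stochastic-map summary.  With `expand = TRUE` each hotspot is merged
#' with its sister clade in the tree.
#'
#' @param dataset a `habitat_dataset`.
#' @param transition_summary a `stochastic_map_summary` (see
#'   [stochastic_maps()]) carrying per-edge mean change counts.
#' @param top_m number of hotspot clades to return.
#' @param expand merge each hotspot with its sister clade.
#' @param candidates optional `clade_scale` of candidate clades.
#' @return a `clade_scale` (name `hotspot` or `hotspot_expanded`).
#' @export
hotspot_scale <- function(dataset, transition_summary, top_m = 2,
                          expand = FALSE, candidates = NULL) {
  if (is.null(transition_summary) ||
      is.null(transition_summary$edge_mean_changes))
    stop("transition summary with per-edge changes required", call. = FALSE)
  if (is.null(candidates)) {
    if (all(!is.na(dataset$records$order)))
      candidates <- scale_from_labels(dataset, "order")
    else stop("no candidate clades: order labels missing", call. = FALSE)
  }
  tree <- dataset$tree
  sets <- node_tip_sets(tree)
  tipidx <- setNames(seq_along(tree$tip.label), tree$tip.label)
  per_clade <- vapply(candidates$clades, function(tips) {
    idx <- tipidx[tips]
    # edges whose descendant tip set lies entirely within the clade
    # (includes the clade's stem edge)
    inner <- which(vapply(tree$edge[, 2], function(ch)
      all(sets[[ch]] %in% idx), logical(1)))
    sum(transition_summary$edge_mean_changes[inner]) / length(idx)
  }, numeric(1))
  if (top_m > length(per_clade)) {
    warning("top_m exceeds candidate count; returning all candidates",
            call. = FALSE)
    top_m <- length(per_clade)
  }
  ord <- order(-per_clade, names(per_clade))
  pick <- names(per_clade)[ord[seq_len(top_m)]]
  clades <- candidates$clades[pick]
  if (expand) {
    clades <- lapply(clades, function(tips) {
      if (length(tips) == length(tree$tip.label)) return(sort(tips))
      nd <- if (length(tips) == 1) tipidx[tips] else ape::getMRCA(tree, tips)
      parent <- tree$edge[tree$edge[, 2] == nd, 1]
      sort(unique(c(tips, tree$tip.label[sets[[parent]]])))
    })
  }
  new_clade_scale(if (expand) "hotspot_expanded" else "hotspot", clades,
                  flags = list(events_per_tip = per_clade[pick]))
}

#' Build a set of observation scales
#'
#' @param dataset a `habitat_dataset`.
#' @param scales character vector among `family`, `order`, `tax3`, `tax4`,
#'   `tax5`, `tax6`, `full`, `hotspot`, `hotspot_expanded`.
#' @param tax_sections section counts for the four tree-partition scales.
#' @param transition_summary needed for hotspot scales.
#' @param top_m hotspot count.
#' @return named list of `clade_scale` objects.
#' @export
build_scales <- function(dataset,
                         scales = c("family", "order", "tax3", "tax4",
                                    "tax5", "tax6", "full"),
                         tax_sections = c(tax3 = 13, tax4 = 9,
                                          tax5 = 5, tax6 = 3),
                         transition_summary = NULL, top_m = 2) {
  out <- list()
  for (s in scales) {
    out[[s]] <- switch(s,
      family = scale_from_labels(dataset, "family"),
      order = scale_from_labels(dataset, "order"),
      tax3 = , tax4 = , tax5 = , tax6 =
        partition_tree(dataset$tree,
                       min(tax_sections[[s]], length(dataset$tree$tip.label)),
                       scale_name = s),
      full = new_clade_scale("full",
                             list(full = sort(dataset$tree$tip.label))),
      hotspot = hotspot_scale(dataset, transition_summary, top_m, FALSE),
      hotspot_expanded = hotspot_scale(dataset, transition_summary, top_m,
                                       TRUE),
      stop("unknown scale: ", s, call. = FALSE))
  }
  out
}

#' Restrict scales to a subset of tips
#'
#' Keeps clade identities but intersects each tip set with `species`;
#' emptied clades are dropped.  Used by the reduced-and-retained protocol.
#'
#' @param scales named list of `clade_scale` objects.
#' @param species tip names to keep.
#' @return restricted list of `clade_scale` objects.
#' @export
restrict_scales <- function(scales, species) {
  lapply(scales, function(sc) {
    clades <- lapply(sc$clades, intersect, species)
    clades <- clades[lengths(clades) > 0]
    new_clade_scale(sc$scale_name, clades, sc$flags)
  })
}

#' Serialize scales to a long-format table
#'
#' @param scales named list of `clade_scale` objects.
#' @return data.frame with columns scale, clade_id, species.
#' @export
scales_to_table <- function(scales) {
  do.call(rbind, lapply(scales, function(sc) {
    do.call(rbind, lapply(names(sc$clades), function(id)
      data.frame(scale = sc$scale_name, clade_id = id,
                 species = sc$clades[[id]], stringsAsFactors = FALSE)))
  }))
}
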