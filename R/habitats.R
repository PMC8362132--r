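#' Habitat-use categories
#'
#' Six salinity-defined habitat-use categories. The canonical order of the
#' five categories entering pairwise size comparisons is (freshwater,
#' freshwater_brackish, marine, marine_brackish, euryhaline); exclusively
#' brackish taxa are retained in datasets and transition analyses but are
#' not part of the pairwise comparison set.
#'
#' @param comparison logical; if `TRUE` return only the five categories
#'   used in pairwise comparisons, in canonical order.
#' @return character vector of habitat names.
#' @export
habitat_levels <- function(comparison = FALSE) {
  comp <- c("freshwater", "freshwater_brackish", "marine",
            "marine_brackish", "euryhaline")
  if (comparison) comp else c(comp, "brackish")
}

#' The ten ordered habitat pairs used in pairwise comparisons
#'
#' Pairs are ordered so the first habitat is the earlier one in the
#' canonical order; all signed differences are first minus second.
#'
#' @return data.frame with columns `first`, `second`.
#' @export
habitat_pairs <- function() {
  h <- habitat_levels(comparison = TRUE)
  cc <- combn(h, 2)
  data.frame(first = cc[1, ], second = cc[2, ], stringsAsFactors = FALSE)
}

assert_habitat <- function(x) {
  bad <- setdiff(unique(x), habitat_levels())
  if (length(bad))
    stop("unknown habitat categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}
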