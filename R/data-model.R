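#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream statistics rely on: every edge must carry a branch length,
#' lengths must be non-negative and tip labels must be unique.
#'
#' @param path path to a Newick file.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree))
    stop("malformed Newick in '", path, "'", call. = FALSE)
  validate_tree(tree)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @param digits significant digits for branch lengths (default keeps
#'   round-trips faithful to >= 10 significant digits).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", bad, " (",
         tree$edge[bad, 1], " -> ", tree$edge[bad, 2], ")", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    stop("negative branch length on edge ", bad, call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Brownian-motion tip covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances.  This is the covariance (up to the rate) of a Brownian
#' trait at the tips and underlies the GLS habitat means, the simulation
#' ANOVA null and the PGLS ANOVA.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return an n x n symmetric positive semi-definite matrix with tip
#'   labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv(tree)
}

normalise_species <- function(x) gsub(" +", "_", trimws(x))

#' Construct and validate a taxon record table
#'
#' @param species character vector of species identifiers.
#' @param habitat habitat-use category, one of [habitat_levels()].
#' @param log10_size log10 maximum length in cm.
#' @param trophic_level optional trophic level, in (1, 6].
#' @param migratory optional logical migratory flag.
#' @param family,order optional taxonomic labels.
#' @return a `data.frame` with one row per species.
#' @export
taxon_records <- function(species, habitat, log10_size,
                          trophic_level = NA_real_, migratory = NA,
                          family = NA_character_, order = NA_character_) {
  species <- normalise_species(as.character(species))
  if (anyDuplicated(species))
    stop("duplicated species identifiers", call. = FALSE)
  assert_habitat(habitat)
  if (any(!is.finite(log10_size)))
    stop("non-finite log10_size values", call. = FALSE)
  tl <- as.numeric(trophic_level)
  bad <- !is.na(tl) & (tl <= 1 | tl > 6)
  if (any(bad))
    stop("trophic_level outside (1, 6] for: ",
         paste(species[bad], collapse = ", "), call. = FALSE)
  data.frame(species = species,
             habitat = as.character(habitat),
             log10_size = as.numeric(log10_size),
             trophic_level = tl,
             migratory = as.logical(migratory),
             family = as.character(family),
             order = as.character(order),
             stringsAsFactors = FALSE)
}

#' Read a taxon table from TSV
#'
#' Expects header columns `species`, `habitat`, `max_length_cm` and
#' optionally `trophic_level`, `migratory`, `family`, `order`.  Raw
#' maximum lengths (cm) are log10-transformed once at ingest.
#'
#' @param path path to a tab-separated file.
#' @return a taxon record `data.frame` (see [taxon_records()]).
#' @export
read_taxon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "habitat", "max_length_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxon table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$max_length_cm) | df$max_length_cm <= 0))
    stop("max_length_cm must be finite and positive", call. = FALSE)
  opt <- function(col, default) if (col %in% names(df)) df[[col]] else default
  taxon_records(species = df$species,
                habitat = df$habitat,
                log10_size = log10(df$max_length_cm),
                trophic_level = opt("trophic_level", NA_real_),
                migratory = opt("migratory", NA),
                family = opt("family", NA_character_),
                order = opt("order", NA_character_))
}

#' Write a taxon table to TSV
#'
#' Inverse of [read_taxon_table()]: `log10_size` is written back as
#' `max_length_cm`.
#'
#' @param records taxon record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(records, path) {
  out <- data.frame(species = records$species,
                    habitat = records$habitat,
                    max_length_cm = 10^records$log10_size,
                    trophic_level = records$trophic_level,
                    migratory = records$migratory,
                    family = records$family,
                    order = records$order)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match a phylogeny against a taxon table
#'
#' Prunes both sides to the intersection of tip labels and species
#' identifiers (exact string match after space/underscore normalisation)
#' and reports how many entries were dropped from each side.
#'
#' @param tree a `phylo` object.
#' @param records taxon record data.frame.
#' @return a `habitat_dataset`: list with elements `tree`, `records`
#'   (rows in tip order) and `dropped` (counts per side).
#' @export
match_tree_table <- function(tree, records) {
  validate_tree(tree)
  tree$tip.label <- normalise_species(tree$tip.label)
  records$species <- normalise_species(records$species)
  keep <- intersect(tree$tip.label, records$species)
  if (!length(keep))
    stop("no overlap between tree tips and taxon table", call. = FALSE)
  dropped <- c(tips = length(setdiff(tree$tip.label, keep)),
               records = length(setdiff(records$species, keep)))
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  records <- records[match(tree$tip.label, records$species), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(tree = tree, records = records, dropped = dropped),
            class = "habitat_dataset")
}

#' @export
print.habitat_dataset <- function(x, ...) {
  cat("habitat_dataset:", length(x$tree$tip.label), "tips\n")
  print(table(x$records$habitat))
  invisible(x)
}

#' Validate a habitat dataset
#'
#' Checks the one-record-per-tip contract and all record invariants.
#'
#' @param dataset a `habitat_dataset`.
#' @return the dataset, invisibly.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "habitat_dataset"))
  validate_tree(dataset$tree)
  if (!identical(dataset$tree$tip.label, dataset$records$species))
    stop("records are not aligned with tree tips", call. = FALSE)
  assert_habitat(dataset$records$habitat)
  if (any(!is.finite(dataset$records$log10_size)))
    stop("non-finite log10_size", call. = FALSE)
  tl <- dataset$records$trophic_level
  if (any(!is.na(tl) & (tl <= 1 | tl > 6)))
    stop("trophic_level outside (1, 6]", call. = FALSE)
  invisible(dataset)
}

#' Restrict a dataset to a subset of species
#'
#' @param dataset a `habitat_dataset`.
#' @param species species to keep.
#' @return a pruned, still-consistent `habitat_dataset`.
#' @export
prune_dataset <- function(dataset, species) {
  keep <- intersect(dataset$tree$tip.label, species)
  if (length(keep) < 2)
    stop("pruning would leave fewer than 2 tips", call. = FALSE)
  tree <- ape::keep.tip(dataset$tree, keep)
  records <- dataset$records[match(tree$tip.label, dataset$records$species), ,
                             drop = FALSE]
  rownames(records) <- NULL
  structure(list(tree = tree, records = records,
                 dropped = c(tips = length(dataset$tree$tip.label) -
                               length(keep), records = 0L)),
            class = "habitat_dataset")
}
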