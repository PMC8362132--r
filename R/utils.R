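# Internal helpers shared across modules.

# Run expr with a local RNG seeded at `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seeds derived from one root seed, kept < 2^31.
derive_seeds <- function(seed, n, labels = NULL) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

# Tip index sets of every node (tips + internal), postorder accumulation.
node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  sets[seq_len(nt)] <- as.list(seq_len(nt))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

root_node <- function(tree) length(tree$tip.label) + 1L

# children of each node as a list indexed by node id
node_children <- function(tree) {
  nt <- length(tree$tip.label)
  ch <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}
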