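# Shared fixtures and independent oracles, all built in code.

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

balanced8_tree <- function()
  ape::read.tree(text =
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")

star_tree <- function(n, depth = 1, labels = sprintf("t%02d", seq_len(n))) {
  txt <- paste0("(", paste0(labels, ":", depth, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# independent BM-covariance oracle: C_ij = (d_i + d_j - D_ij) / 2 with
# tip depths d and cophenetic distances D.
bm_cov_oracle <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  C <- (outer(d, d, "+") - D) / 2
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
wilcox_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_w <- apply(combn(na + nb, na), 2, function(idx)
    sum(seq_len(na + nb)[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force GLS group means via explicit matrix inversion
gls_means_oracle <- function(C, X, y) {
  Ci <- solve(C)
  as.numeric(solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y)
}

# build a mechanism ledger data.frame from raw indicator vectors,
# deriving the joint columns by their definitions
make_ledger <- function(A, Bi, C, D, first = "freshwater",
                        second = "marine") {
  data.frame(scale = "tax3", clade_id = sprintf("c%03d", seq_along(A)),
             first = first, second = second, size_larger = first,
             A = A, A_prime = A, Bi = Bi, Bii = A & Bi, Biii = Bi & !A,
             C = C, D = D, A_or_Biii = A | (Bi & !A),
             any_of_four = A | Bi | C | D, stringsAsFactors = FALSE)
}

# 12-taxon star fixture in which pruning to trophic-complete taxa flips
# the freshwater-vs-marine size direction and nothing else
flip_fixture <- function() {
  tree <- star_tree(12, depth = 1,
                    labels = sprintf("sp%02d", 1:12))
  rec <- taxon_records(
    species = sprintf("sp%02d", 1:12),
    habitat = c(rep("marine", 4), rep("freshwater", 5),
                rep("euryhaline", 3)),
    log10_size = c(rep(2, 4),            # marine
                   1, 1, 1, 3.75, 3.75,  # freshwater: mean 2.1 full, 1 pruned
                   4, 4, 4),             # euryhaline
    trophic_level = c(rep(3, 4), 2.5, 2.5, 2.5, NA, NA, 3.5, 3.5, 3.5),
    migratory = FALSE,
    family = "famA", order = "ordA")
  match_tree_table(tree, rec)
}

# minimal comparison_results data.frame for alignment tests
fake_results <- function(scale, clade_id, first, second, metric, diff) {
  larger <- ifelse(diff == 0, "tie", ifelse(diff > 0, first, second))
  structure(data.frame(scale = scale, clade_id = clade_id, first = first,
                       second = second, metric = metric,
                       n_first = 5L, n_second = 5L,
                       signed_difference = diff, larger_habitat = larger,
                       p_value = NA_real_, significance_band = "none",
                       stringsAsFactors = FALSE),
            class = c("comparison_results", "data.frame"))
}
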