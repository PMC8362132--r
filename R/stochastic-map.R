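#' Stochastic character maps of habitat evolution
#'
#' Samples full character histories consistent with the tip data and a
#' fitted Mk model: internal node states are drawn from their conditional
#' distributions (pre-order pass over pruning partials), then an
#' endpoint-conditioned path is sampled along every edge by
#' uniformization, with a rejection-sampling fallback for pathological
#' generators.  Every state change is counted, and counts are averaged
#' over `n_maps` maps.
#'
#' @param tree a `phylo` tree.
#' @param tip_states named character vector of tip states.
#' @param model a (fitted) [mk_model()].
#' @param n_maps number of maps (100 mirrors common practice).
#' @param seed RNG seed.
#' @return a `stochastic_map_summary`: list with `n_maps`, `mean_counts`
#'   (k x k, from -> to, zero diagonal), `per_map_counts` (n_maps x k x k
#'   array), `edge_mean_changes` (mean changes per edge, in `tree$edge`
#'   order) and `node_state_freq` (empirical state frequencies per node).
#' @export
stochastic_maps <- function(tree, tip_states, model, n_maps = 100,
                            seed = NULL) {
  states <- model$states
  k <- length(states)
  Q <- model$Q
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  pr <- mk_partials(tree, tip_states, model)
  part <- pr$partials
  P <- pr$P
  rootn <- root_node(tree)
  w_root <- root_prior_weights(model, part[rootn, ]) * part[rootn, ]
  if (sum(w_root) <= 0)
    stop("zero likelihood at root; data inconsistent with model",
         call. = FALSE)
  w_root <- w_root / sum(w_root)
  eo <- ape::reorder.phylo(tree, "cladewise")
  emap <- match(paste(eo$edge[, 1], eo$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  omega <- max(-diag(Q))
  R <- if (omega > 0) diag(k) + Q / omega else diag(k)
  Rpow <- list(diag(k), R)   # R^0, R^1, grown on demand
  get_Rpow <- function(n) {
    while (length(Rpow) < n + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% R
    Rpow[[n + 1L]]
  }
  sample_n_jumps <- function(a, b, t, pab) {
    # P(N = n | a, b, t) propto dpois(n, omega t) * (R^n)[a, b]
    u <- runif(1) * pab
    acc <- 0; n <- 0
    repeat {
      acc <- acc + dpois(n, omega * t) * get_Rpow(n)[a, b]
      if (acc >= u || n > 5000) break
      n <- n + 1
    }
    if (n > 5000) NA_integer_ else n
  }
  sample_path_changes <- function(a, b, t, pab) {
    # returns sequence of real state changes (from,to) along the edge
    if (omega == 0) return(NULL)
    n <- sample_n_jumps(a, b, t, pab)
    if (is.na(n)) {                 # rejection-sampling fallback
      repeat {
        s <- a; chg <- NULL; time <- 0
        repeat {
          rate <- -Q[s, s]
          if (rate <= 0) { time <- t; break }
          time <- time + rexp(1, rate)
          if (time >= t) break
          to <- sample.int(k, 1, prob = pmax(Q[s, ], 0) *
                             (seq_len(k) != s))
          chg <- rbind(chg, c(s, to)); s <- to
        }
        if (s == b) return(chg)
      }
    }
    if (n == 0) return(NULL)
    s <- a; chg <- NULL
    for (i in seq_len(n)) {
      if (i < n) {
        wts <- R[s, ] * get_Rpow(n - i)[, b]
        j <- sample.int(k, 1, prob = pmax(wts, 0))
      } else j <- b
      if (j != s) chg <- rbind(chg, c(s, j))
      s <- j
    }
    chg
  }
  per_map <- array(0, c(n_maps, k, k),
                   dimnames = list(NULL, states, states))
  edge_changes <- matrix(0, n_maps, nrow(tree$edge))
  node_freq <- matrix(0, ntot, k, dimnames = list(NULL, states))
  with_seed(seed, {
    for (m in seq_len(n_maps)) {
      node_state <- integer(ntot)
      node_state[rootn] <- sample.int(k, 1, prob = w_root)
      for (e in seq_len(nrow(eo$edge))) {
        pa <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
        Pe <- P[[emap[e]]]
        wts <- Pe[node_state[pa], ] * part[ch, ]
        node_state[ch] <- sample.int(k, 1, prob = pmax(wts, 0))
        pab <- Pe[node_state[pa], node_state[ch]]
        chg <- sample_path_changes(node_state[pa], node_state[ch],
                                   eo$edge.length[e], pab)
        if (!is.null(chg)) {
          for (r in seq_len(nrow(chg)))
            per_map[m, chg[r, 1], chg[r, 2]] <-
              per_map[m, chg[r, 1], chg[r, 2]] + 1
          edge_changes[m, emap[e]] <- nrow(chg)
        }
      }
      node_freq[cbind(seq_len(ntot), node_state)] <-
        node_freq[cbind(seq_len(ntot), node_state)] + 1
    }
  })
  mean_counts <- apply(per_map, c(2, 3), mean)
  diag(mean_counts) <- 0
  structure(list(n_maps = n_maps, states = states,
                 mean_counts = mean_counts, per_map_counts = per_map,
                 edge_mean_changes = colMeans(edge_changes),
                 node_state_freq = node_freq / n_maps),
            class = "stochastic_map_summary")
}

#' @export
print.stochastic_map_summary <- function(x, ...) {
  cat("stochastic_map_summary:", x$n_maps, "maps,",
      round(sum(x$mean_counts), 2), "mean transitions\n")
  print(round(x$mean_counts, 2))
  invisible(x)
}

#' Long-format transition count table
#'
#' @param summary a `stochastic_map_summary`.
#' @return data.frame (from_habitat, to_habitat, mean_count).
#' @export
transition_table <- function(summary) {
  k <- length(summary$states)
  idx <- which(row(summary$mean_counts) != col(summary$mean_counts),
               arr.ind = TRUE)
  data.frame(from_habitat = summary$states[idx[, 1]],
             to_habitat = summary$states[idx[, 2]],
             mean_count = summary$mean_counts[idx],
             stringsAsFactors = FALSE)
}
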