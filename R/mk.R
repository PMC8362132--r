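#' @title Mk models of habitat evolution
#' @description Continuous-time Markov (Mk) models of the six habitat-use
#'   states: pruning-algorithm likelihood, maximum-likelihood rate fitting
#'   under ER / SYM / ARD constraints, and stochastic character mapping by
#'   uniformization to obtain per-branch transition histories and average
#'   transition counts.
#' @name mk-models
NULL

#' Construct an Mk model
#'
#' @param states ordered state names (<= 6).
#' @param Q generator matrix (off-diagonals >= 0, rows sum to 0).
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param root_prior `"equal"`, `"stationary"` or `"fitzjohn"`.
#' @return an `mk_model` object.
#' @export
mk_model <- function(states, Q,
                     constraint = c("ARD", "SYM", "ER"),
                     root_prior = c("equal", "stationary", "fitzjohn")) {
  constraint <- match.arg(constraint)
  root_prior <- match.arg(root_prior)
  stopifnot(length(states) == nrow(Q))
  dimnames(Q) <- list(states, states)
  validate_Q(Q)
  structure(list(states = states, Q = Q, constraint = constraint,
                 root_prior = root_prior), class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("mk_model (", x$constraint, ", root prior ", x$root_prior, "), ",
      length(x$states), " states\n", sep = "")
  print(round(x$Q, 4))
  if (!is.null(x$loglik)) cat("log-likelihood:", x$loglik, "\n")
  invisible(x)
}

#' Transition probability matrix expm(Q t)
#'
#' Eigendecomposition-based matrix exponential with a fall-back to
#' [ape::matexpo()] when Q is defective or ill-conditioned.  Rows are
#' clamped to non-negative values and renormalized to sum to one.
#'
#' @param Q generator matrix.
#' @param t elapsed time (>= 0).
#' @return stochastic matrix of the same dimension.
#' @export
expm_Q <- function(Q, t) {
  make_Pfun(Q)(t)
}

make_Pfun <- function(Q) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eg))
    tryCatch(solve(eg$vectors), error = function(e) NULL) else NULL
  ok <- !is.null(Vi) &&
    all(is.finite(Mod(Vi))) && max(Mod(Vi)) < 1e12
  if (ok) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      if (any(!is.finite(P)))
        stop("non-finite transition matrix at t = ", t, call. = FALSE)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      P <- ape::matexpo(Q * t)
      if (any(!is.finite(P)))
        stop("non-finite transition matrix at t = ", t, call. = FALSE)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

root_prior_weights <- function(model, L_root) {
  k <- length(model$states)
  switch(model$root_prior,
         equal = rep(1 / k, k),
         stationary = {
           ev <- eigen(t(model$Q))
           i <- which.min(abs(ev$values))
           p <- Re(ev$vectors[, i]); p <- pmax(p, 0)
           if (sum(p) <= 0) rep(1 / k, k) else p / sum(p)
         },
         fitzjohn = {
           if (sum(L_root) <= 0) rep(1 / k, k)
           else L_root / sum(L_root)
         })
}

# All per-edge transition matrices expm(Q * t_e) at once: one
# eigendecomposition and a single complex matmul across edges, with a
# per-edge matexpo fallback for defective generators.
edge_P_matrices <- function(Q, lens) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eg))
    tryCatch(solve(eg$vectors), error = function(e) NULL) else NULL
  if (!is.null(Vi) && all(is.finite(Mod(Vi))) && max(Mod(Vi)) < 1e12) {
    B <- matrix(0 + 0i, k, k * k)
    for (s in seq_len(k))
      B[s, ] <- as.vector(outer(eg$vectors[, s], Vi[s, ]))
    W <- exp(outer(lens, eg$values))        # E x k
    Pflat <- Re(W %*% B)                    # E x k^2
    if (any(!is.finite(Pflat)))
      stop("non-finite transition matrix", call. = FALSE)
    Pflat[Pflat < 0] <- 0
    lapply(seq_along(lens), function(e) {
      P <- matrix(Pflat[e, ], k, k)
      P / rowSums(P)
    })
  } else {
    lapply(lens, function(t) {
      P <- ape::matexpo(Q * t)
      if (any(!is.finite(P)))
        stop("non-finite transition matrix at t = ", t, call. = FALSE)
      P[P < 0] <- 0
      P / rowSums(P)
    })
  }
}

# Precompute the traversal so repeated likelihood evaluations (ML
# fitting) only pay for the edge matrices and the pruning pass.
mk_pruner_ctx <- function(tree, tip_states, states) {
  nt <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  if (anyNA(match(st, states)))
    stop("tip states outside model states: ",
         paste(unique(st[!st %in% states]), collapse = ", "),
         call. = FALSE)
  eo <- ape::reorder.phylo(tree, "postorder")
  emap <- match(paste(eo$edge[, 1], eo$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(nt = nt, nnode = tree$Nnode, tip_idx = match(st, states),
       edge = eo$edge, emap = emap, lens = tree$edge.length,
       root = nt + 1L)
}

mk_partials_ctx <- function(ctx, Q) {
  k <- nrow(Q)
  P <- edge_P_matrices(Q, ctx$lens)
  part <- matrix(1, ctx$nt + ctx$nnode, k)
  part[seq_len(ctx$nt), ] <- 0
  part[cbind(seq_len(ctx$nt), ctx$tip_idx)] <- 1
  logscale <- 0
  for (i in seq_len(nrow(ctx$edge))) {
    par <- ctx$edge[i, 1]; ch <- ctx$edge[i, 2]
    part[par, ] <- part[par, ] *
      as.numeric(P[[ctx$emap[i]]] %*% part[ch, ])
    m <- max(part[par, ])
    if (m > 0 && m < 1e-100) {
      part[par, ] <- part[par, ] / m
      logscale <- logscale + log(m)
    }
  }
  list(partials = part, logscale = logscale, P = P)
}

# conditional likelihoods at every node (pruning), with log scalers.
mk_partials <- function(tree, tip_states, model) {
  ctx <- mk_pruner_ctx(tree, tip_states, model$states)
  mk_partials_ctx(ctx, model$Q)
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Post-order pruning with per-edge transition matrices `expm(Q t)`; the
#' root is handled according to the model's root prior.
#'
#' @param tree a `phylo` tree.
#' @param tip_states named character vector of tip states.
#' @param model an [mk_model()].
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  pr <- mk_partials(tree, tip_states, model)
  L_root <- pr$partials[root_node(tree), ]
  w <- root_prior_weights(model, L_root)
  lik <- sum(w * L_root)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

rate_index_matrix <- function(k, constraint) {
  M <- matrix(0L, k, k)
  idx <- 0L
  if (constraint == "ER") {
    M[row(M) != col(M)] <- 1L
  } else if (constraint == "SYM") {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      M[i, j] <- idx; M[j, i] <- idx
    }
  } else {
    for (i in 1:k) for (j in 1:k) if (i != j) {
      idx <- idx + 1L
      M[i, j] <- idx
    }
  }
  M
}

build_Q <- function(rates, index, states) {
  Q <- matrix(0, nrow(index), ncol(index), dimnames = list(states, states))
  off <- index > 0
  Q[off] <- rates[index[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale with `L-BFGS-B` from multiple
#' seeded starting points (ARD on six states has 30 weakly identified
#' rates, so multi-start matters).
#'
#' @param tree a `phylo` tree.
#' @param tip_states named character vector of tip states.
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param states model states; defaults to the observed states in
#'   [habitat_levels()] order (unknown states keep their own order).
#' @param root_prior root prior (see [mk_model()]).
#' @param n_starts number of optimization starts.
#' @param rate_upper upper bound on any single rate.
#' @param seed RNG seed for the starting points.
#' @return fitted `mk_model` with elements `loglik` and `convergence`.
#' @export
fit_mk <- function(tree, tip_states, constraint = c("ARD", "SYM", "ER"),
                   states = NULL, root_prior = "equal", n_starts = 5,
                   rate_upper = 1e3, seed = NULL) {
  constraint <- match.arg(constraint)
  obs <- unique(tip_states)
  if (length(obs) < 2)
    stop("need >= 2 observed states to fit an Mk model", call. = FALSE)
  if (is.null(states)) {
    canon <- habitat_levels()
    states <- c(intersect(canon, obs), setdiff(sort(obs), canon))
  }
  k <- length(states)
  index <- rate_index_matrix(k, constraint)
  npar <- max(index)
  total_len <- sum(tree$edge.length)
  base <- log(max(length(obs) - 1, 1) * k / max(total_len, 1e-8))
  ctx <- mk_pruner_ctx(tree, tip_states, states)
  prior_stub <- list(states = states, Q = diag(0, k),
                     root_prior = root_prior)
  nll <- function(lp) {
    Q <- build_Q(exp(lp), index, states)
    ll <- tryCatch({
      pr <- mk_partials_ctx(ctx, Q)
      L_root <- pr$partials[ctx$root, ]
      prior_stub$Q <- Q
      w <- root_prior_weights(prior_stub, L_root)
      lik <- sum(w * L_root)
      if (lik <= 0) -Inf else log(lik) + pr$logscale
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i)
    base + if (i == 1) rep(0, npar) else rnorm(npar, 0, 1)))
  best <- NULL
  conv <- logical(0)
  for (s in starts) {
    op <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = log(1e-9), upper = log(rate_upper),
            control = list(maxit = 300, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(op)) next
    conv <- c(conv, op$convergence == 0)
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("Mk optimization failed in all starts", call. = FALSE)
  model <- mk_model(states, build_Q(exp(best$par), index, states),
                    constraint, root_prior)
  model$loglik <- -best$value
  model$convergence <- list(any_converged = any(conv),
                            n_starts = length(starts),
                            n_converged = sum(conv))
  if (!any(conv))
    warning("no optimization start reported convergence; returning ",
            "best value found", call. = FALSE)
  model
}
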