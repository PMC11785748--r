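#' Number of mutation destinations per update
#'
#' A mutating individual adopts one of the other three behavioural types of
#' the full strategy set uniformly at random; in reduced variants, mutations
#' toward excluded types are void (the individual keeps its strategy), so
#' each active alternative is reached with probability `mu / 3` and the
#' realised per-individual mutation rate is `mu * (S - 1) / 3`. This keeps
#' the mutation kernel identical across all four variants, which is what
#' makes their risk curves directly comparable.
#'
#' @param p A `crd_params` object.
#' @return The integer 3 (length of the full strategy set minus one).
#' @export
mutation_targets <- function(p) {
  length(CRD_STRATEGIES) - 1L
}

#' Hypergeometric fitness of a strategy
#'
#' Expected payoff of an individual playing strategy `s` in population state
#' `i`: the average of the group payoff of `s` over all draws of `N - 1`
#' co-players from the remaining `Z - 1` individuals (sampling without
#' replacement, i.e. multivariate hypergeometric weights).
#'
#' @param i Population state: named count vector or full 4-column matrix
#'   summing to `p$Z`, with `i[s] >= 1`.
#' @param s Strategy label in the variant's active set.
#' @param p A `crd_params` object.
#' @return Scalar expected payoff.
#' @export
fitness <- function(i, s, p) {
  m <- as_comp(i)
  stopifnot(nrow(m) == 1L, sum(m) == p$Z, s %in% p$active)
  if (m[, s] < 1L) stop("fitness of strategy '", s, "' undefined: no such individual in the state")
  tab <- payoff_table(p)
  w <- choose(m[, s] - 1L, tab$comps[, s])
  for (l in setdiff(p$active, s)) w <- w * choose(m[, l], tab$comps[, l])
  sum(w * tab$pay[, s]) / choose(p$Z - 1, p$N - 1)
}

#' One-step transition probability between adjacent states
#'
#' Probability that one individual switches from `from_s` to `to_s` in one
#' update of state `i`: imitation via the pairwise comparison rule (Fermi
#' function of the fitness difference at selection strength `beta`), plus
#' uniform mutation to each of the other `S - 1` active strategies with
#' total per-individual probability `mu`.
#'
#' @param i Population state with `i[from_s] >= 1`.
#' @param from_s,to_s Distinct strategies in the active set.
#' @param p A `crd_params` object.
#' @return Scalar probability.
#' @export
transition_probability <- function(i, from_s, to_s, p) {
  m <- as_comp(i)
  stopifnot(nrow(m) == 1L, sum(m) == p$Z,
            from_s %in% p$active, to_s %in% p$active, from_s != to_s)
  if (m[, from_s] < 1L) stop("no '", from_s, "' individual available to switch")
  prob <- p$mu * m[, from_s] / (mutation_targets(p) * p$Z)
  if (m[, to_s] >= 1L) {
    df <- fitness(m, to_s, p) - fitness(m, from_s, p)
    fermi <- 1 / (1 + exp(-p$beta * df))
    prob <- prob + (1 - p$mu) * (m[, from_s] / p$Z) *
      (m[, to_s] / (p$Z - 1)) * fermi
  }
  unname(prob)
}

#' Build the selection-mutation transition matrix
#'
#' Enumerates the state space, precomputes the group-payoff table once for
#' the parameter set, computes every state's hypergeometric fitness, and
#' assembles the sparse row-stochastic one-step transition matrix
#' (off-diagonals between states that differ by moving one individual,
#' diagonal completed as one minus the row sum).
#'
#' @param p A `crd_params` object.
#' @param matrix Assemble the sparse `dgCMatrix` (default). Large sweeps
#'   pass `FALSE` to work from the transition triplets directly and skip
#'   the assembly cost; all downstream computations are identical.
#' @return Object of class `crd_chain`: list with `T` (sparse `dgCMatrix`,
#'   rows = source states, or `NULL` when `matrix = FALSE`), `states` (the
#'   [enumerate_states] matrix), `fitness` (M x S matrix, `NA` where the
#'   strategy is absent), `diag` (stay-put probabilities), `moves`
#'   (off-diagonal triplets), and `params`.
#' @export
build_transition_matrix <- function(p, matrix = TRUE) {
  stopifnot(inherits(p, "crd_params"))
  states <- enumerate_states(p)
  tab <- payoff_table(p)
  res <- cpp_build_chain(
    states[, p$active, drop = FALSE], p$Z, p$N, p$mu, p$beta,
    mutation_targets(p), tab$comps[, p$active, drop = FALSE], tab$pay
  )
  if (any(res$diag < -1e-12)) {
    stop("negative diagonal completion: invalid parameter set")
  }
  dg <- pmax(res$diag, 0)
  M <- nrow(states)
  Tm <- if (matrix) {
    Matrix::sparseMatrix(
      i = c(res$from, seq_len(M)), j = c(res$to, seq_len(M)),
      x = c(res$x, dg), dims = c(M, M)
    )
  }
  colnames(res$fitness) <- p$active
  structure(
    list(T = Tm, states = states, fitness = res$fitness, params = p,
         diag = dg,
         moves = list(from = res$from, to = res$to, x = res$x)),
    class = "crd_chain"
  )
}

#' @export
print.crd_chain <- function(x, ...) {
  cat(sprintf("<crd_chain> %s, Z=%d, %d states, %d transitions\n",
              x$params$variant, x$params$Z, nrow(x$states),
              length(x$moves$x)))
  invisible(x)
}

as_chain <- function(x) {
  if (inherits(x, "crd_chain")) return(x)
  if (inherits(x, "crd_params")) return(build_transition_matrix(x, matrix = FALSE))
  if (inherits(x, "crd_stationary")) return(x$chain)
  stop("expected crd_params, crd_chain or crd_stationary")
}

#' Stationary distribution of the selection-mutation chain
#'
#' Solves for the probability vector fixed by the transposed transition
#' matrix (the eigenvector of eigenvalue 1), using a sparse Arnoldi
#' eigensolver with increasing subspace sizes until the L1 residual
#' `||T' p - p||_1` meets `tol`. Requires `mu > 0`; without mutation the
#' homogeneous states are absorbing and the stationary distribution is not
#' unique.
#'
#' @param x A `crd_params` or `crd_chain` object.
#' @param tol Residual tolerance (L1; default `1e-10`).
#' @param warm Optional probability vector over the state index used to
#'   warm-start the solver (typically the stationary distribution of a
#'   nearby parameter set, as in risk sweeps); the refined-Arnoldi path it
#'   enables is usually several times faster than a cold solve.
#' @return Object of class `crd_stationary`: list with `p` (probability
#'   vector over the state index), `residual`, `states`, `chain`, `params`.
#' @export
stationary_distribution <- function(x, tol = 1e-10, warm = NULL) {
  chain <- as_chain(x)
  p <- chain$params
  if (p$mu <= 0) {
    stop("stationary distribution undefined for mu = 0: ",
         "homogeneous states are absorbing and the limit is not unique")
  }
  M <- nrow(chain$states)
  mv <- chain$moves
  res <- NULL
  residual <- Inf
  if (M >= 500L) {
    # grounded-system Krylov solve: the fast path for large chains
    v0 <- if (is.null(warm)) numeric(0) else warm
    res <- cpp_stationary_ground(mv$from, mv$to, mv$x, chain$diag, M,
                                 v0, power_steps = 200L,
                                 maxiter = 5000L, tol = 1e-13)
    pb <- res$p
    residual <- res$residual
    if (!is.null(chain$T)) {
      residual <- sum(abs(as.vector(Matrix::crossprod(chain$T, pb)) - pb))
    }
  }
  if (residual > tol) for (subdim in c(30L, 60L, 150L)) {
    res <- cpp_stationary(mv$from, mv$to, mv$x, chain$diag, M,
                          subdim = subdim, maxiter = 5000L, tol = 1e-13)
    pb <- res$p
    residual <- res$residual
    if (!is.null(chain$T)) {
      residual <- sum(abs(as.vector(Matrix::crossprod(chain$T, pb)) - pb))
    }
    if (residual <= tol) break
  }
  if (residual > tol) {
    stop(sprintf("stationary solve did not reach residual %g (got %g)",
                 tol, residual))
  }
  structure(list(p = pb, residual = residual, states = chain$states,
                 chain = chain, params = p),
            class = "crd_stationary")
}

#' @export
print.crd_stationary <- function(x, ...) {
  top <- order(x$p, decreasing = TRUE)[seq_len(min(3L, length(x$p)))]
  cat(sprintf("<crd_stationary> %s, Z=%d, %d states, residual %.2e\n",
              x$params$variant, x$params$Z, length(x$p), x$residual))
  for (k in top) {
    cat(sprintf("  p = %.4g at (C=%d, P=%d, R=%d, D=%d)\n", x$p[k],
                x$states[k, 1], x$states[k, 2], x$states[k, 3],
                x$states[k, 4]))
  }
  invisible(x)
}

as_stationary <- function(x, tol = 1e-10) {
  if (inherits(x, "crd_stationary")) return(x)
  stationary_distribution(x, tol = tol)
}

#' Gradient of selection at one state
#'
#' The expected one-step drift of each strategy's count: for strategy `k`,
#' the total probability its count increases minus the total probability it
#' decreases. Components sum to zero (every gain is another strategy's
#' loss). Interior zeros of this field mark attractors and repellers of the
#' stochastic dynamics.
#'
#' @param i Population state (named counts or full 4-column row).
#' @param p A `crd_params` object.
#' @return Named numeric vector over the active strategies.
#' @export
gradient_of_selection <- function(i, p) {
  m <- as_comp(i)
  stopifnot(nrow(m) == 1L, sum(m) == p$Z)
  grad <- stats::setNames(numeric(p$S), p$active)
  for (l in p$active) {
    if (m[, l] < 1L) next
    for (k in setdiff(p$active, l)) {
      tr <- transition_probability(m, l, k, p)
      grad[k] <- grad[k] + tr
      grad[l] <- grad[l] - tr
    }
  }
  grad
}

#' Gradient of selection over the whole state space
#'
#' Vectorised version of [gradient_of_selection] reusing the fitness table
#' of a built chain.
#'
#' @param x A `crd_params` or `crd_chain` object.
#' @return Numeric matrix (states x active strategies) of drift components;
#'   rows sum to zero.
#' @export
gradient_field <- function(x) {
  chain <- as_chain(x)
  p <- chain$params
  cnt <- chain$states[, p$active, drop = FALSE]
  Fm <- chain$fitness
  M <- nrow(cnt)
  grad <- matrix(0, M, p$S, dimnames = list(NULL, p$active))
  for (l in seq_len(p$S)) {
    for (k in seq_len(p$S)) {
      if (k == l) next
      prob <- p$mu * cnt[, l] / ((p$S - 1) * p$Z)
      imit <- (1 - p$mu) * (cnt[, l] / p$Z) * (cnt[, k] / (p$Z - 1)) /
        (1 + exp(-p$beta * (Fm[, k] - Fm[, l])))
      imit[cnt[, k] == 0L | cnt[, l] == 0L] <- 0
      prob <- ifelse(cnt[, l] == 0L, 0, prob + imit)
      grad[, k] <- grad[, k] + prob
      grad[, l] <- grad[, l] - prob
    }
  }
  grad
}
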