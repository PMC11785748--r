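chain_csr <- function(chain) {
  # off-diagonal moves in CSR over 0-based ranks, for the sampler
  M <- nrow(chain$states)
  ord <- order(chain$moves$from)
  list(
    rowptr = c(0L, cumsum(tabulate(chain$moves$from, nbins = M))),
    colidx = chain$moves$to[ord] - 1L,
    prob = chain$moves$x[ord]
  )
}

#' Simulate a trajectory of the selection-mutation chain
#'
#' Samples the exact one-step kernel (including the stay-put probability)
#' for `steps` elementary updates, recording the state every `stride` steps.
#' Fully reproducible: the same `(params, i0, steps, stride, seed)` always
#' yields the same trajectory.
#'
#' @param x A `crd_params` or `crd_chain` object (pass a prebuilt chain when
#'   simulating many trajectories).
#' @param i0 Initial state (named counts or full 4-column row). Default:
#'   the all-defector state.
#' @param steps Number of elementary update steps (`>= 1`).
#' @param seed Integer RNG seed, recorded in the result.
#' @param stride Recording interval (default 1: every step).
#' @return Object of class `crd_trajectory`: list with `states` (matrix of
#'   recorded states, columns `C`, `P`, `R`, `D`), `step` (the step index of
#'   each record), `seed`, `stride`, `params`.
#' @export
simulate_trajectory <- function(x, i0 = NULL, steps, seed, stride = 1L) {
  chain <- as_chain(x)
  p <- chain$params
  if (is.null(i0)) {
    i0 <- stats::setNames(c(rep(0L, 3L), p$Z), CRD_STRATEGIES)
  }
  m <- as_comp(i0)
  stopifnot(nrow(m) == 1L, sum(m) == p$Z, steps >= 1L, stride >= 1L)
  start <- state_rank(m, p) - 1L
  csr <- chain_csr(chain)
  set.seed(seed)
  rec <- cpp_simulate(csr$rowptr, csr$colidx, csr$prob, start,
                      as.integer(steps), as.integer(stride))
  structure(
    list(states = state_unrank(rec + 1L, p),
         step = seq(0L, by = as.integer(stride), length.out = length(rec)),
         seed = as.integer(seed), stride = as.integer(stride), params = p),
    class = "crd_trajectory"
  )
}

#' @export
print.crd_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("<crd_trajectory> %d recorded states (stride %d, seed %d)\n",
              n, x$stride, x$seed))
  cat("  start:", paste(sprintf("%s=%d", CRD_STRATEGIES, x$states[1, ]),
                        collapse = " "), "\n")
  cat("  end:  ", paste(sprintf("%s=%d", CRD_STRATEGIES, x$states[n, ]),
                        collapse = " "), "\n")
  invisible(x)
}

#' Classify an evolutionary trajectory
#'
#' Operationalises the distinction between rewarder-led and punisher-led
#' escapes from defection: a trajectory starting near the all-defector
#' configuration "converges" when it first comes within one elementary move
#' (L1 distance <= 2) of the cooperative attractor. Over the segment before
#' convergence, the peak counts of P and R decide the label: `R_LED` when
#' rewarders peaked higher, `P_LED` when punishers did, `MIXED` on a tie,
#' and `NOT_CONVERGED` when the trajectory never reaches the attractor's
#' neighbourhood.
#'
#' @param traj A `crd_trajectory`.
#' @param attractor Cooperative attractor state to converge to (named counts
#'   or full 4-column row), e.g. from [find_attractors].
#' @return Character label.
#' @export
classify_trajectory <- function(traj, attractor) {
  stopifnot(inherits(traj, "crd_trajectory"))
  a <- as_comp(attractor)
  stopifnot(nrow(a) == 1L, sum(a) == traj$params$Z)
  d <- rowSums(abs(sweep(traj$states, 2L, as.integer(a))))
  hit <- which(d <= 2L)
  if (length(hit) == 0L) return("NOT_CONVERGED")
  seg <- traj$states[seq_len(hit[1]), , drop = FALSE]
  p_max <- max(seg[, "P"])
  r_max <- max(seg[, "R"])
  if (r_max > p_max) "R_LED" else if (p_max > r_max) "P_LED" else "MIXED"
}

#' Simulate and classify an ensemble of trajectories
#'
#' Runs `n` independent trajectories from `i0` with per-trajectory seeds
#' derived deterministically from `seed`, classifies each against the
#' cooperative attractor, and tabulates the labels.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of trajectories.
#' @param seed Master seed; per-trajectory seeds are drawn from it.
#' @param attractor Cooperative attractor state; when `NULL` it is located
#'   with [find_attractors] (interior maximum with cooperator plurality).
#' @return Object of class `crd_ensemble`: list with `labels` (per
#'   trajectory), `counts` (table over the four labels), `p_led_fraction`
#'   (`P_LED / (P_LED + R_LED)`, `NaN` if neither occurred), `seed`,
#'   `seeds`, `attractor`, `params`.
#' @export
simulate_ensemble <- function(x, n, steps, seed, i0 = NULL, stride = 50L,
                              attractor = NULL) {
  chain <- as_chain(x)
  p <- chain$params
  if (is.null(attractor)) {
    att <- find_attractors(chain)
    att <- att[att$label == "cooperative", , drop = FALSE]
    if (nrow(att) == 0L) {
      stop("no cooperative attractor found; pass one explicitly")
    }
    # prefer an interior attractor; at small mutation rates the stationary
    # mode usually sits on a boundary face, which serves equally well as
    # the convergence beacon
    if (any(att$interior)) att <- att[att$interior, , drop = FALSE]
    attractor <- unlist(att[1L, CRD_STRATEGIES])
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  labels <- vapply(seq_len(n), function(k) {
    tr <- simulate_trajectory(chain, i0 = i0, steps = steps,
                              seed = seeds[k], stride = stride)
    classify_trajectory(tr, attractor)
  }, character(1))
  counts <- table(factor(labels,
                         levels = c("R_LED", "P_LED", "MIXED",
                                    "NOT_CONVERGED")))
  structure(
    list(labels = labels, counts = counts,
         p_led_fraction = unname(counts[["P_LED"]] /
                                   (counts[["P_LED"]] + counts[["R_LED"]])),
         seed = as.integer(seed), seeds = seeds,
         attractor = as_comp(attractor)[1L, ], params = p),
    class = "crd_ensemble"
  )
}

#' @export
print.crd_ensemble <- function(x, ...) {
  cat(sprintf("<crd_ensemble> %d trajectories (master seed %d)\n",
              length(x$labels), x$seed))
  print(x$counts)
  cat(sprintf("  P-led fraction among converged: %.3f\n", x$p_led_fraction))
  invisible(x)
}
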