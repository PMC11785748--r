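#' Group achievement of a population state
#'
#' Probability that a group of `N` individuals sampled without replacement
#' from population state `i` reaches the contribution threshold `n_pg`
#' (counting C, P and R as contributors).
#'
#' @param i Population state (named counts or full 4-column matrix, rows
#'   summing to `p$Z`).
#' @param p A `crd_params` object.
#' @return Numeric in `[0, 1]` (vectorised over rows of `i`).
#' @export
group_achievement <- function(i, p) {
  m <- as_comp(i)
  stopifnot(all(rowSums(m) == p$Z))
  comps <- group_compositions(p$N, p)
  succ <- as.numeric(comps[, "C"] + comps[, "P"] + comps[, "R"] >= p$n_pg)
  cpp_state_average(m[, p$active, drop = FALSE], p$Z, p$N,
                    comps[, p$active, drop = FALSE], succ)
}

# group achievement for every enumerated state (internal, r-independent)
group_achievement_all <- function(chain) {
  p <- chain$params
  comps <- group_compositions(p$N, p)
  succ <- as.numeric(comps[, "C"] + comps[, "P"] + comps[, "R"] >= p$n_pg)
  cpp_state_average(chain$states[, p$active, drop = FALSE], p$Z, p$N,
                    comps[, p$active, drop = FALSE], succ)
}

#' Population-average group achievement
#'
#' The group achievement averaged over the stationary distribution of the
#' selection-mutation chain: the long-run probability that a randomly
#' sampled group succeeds in the collective risk dilemma. This is the single
#' scalar used to compare institutional designs of different dimensionality.
#'
#' @param x A `crd_params`, `crd_chain` or `crd_stationary` object.
#' @return Numeric in `[0, 1]`.
#' @export
eta_G <- function(x) {
  st <- as_stationary(x)
  sum(st$p * group_achievement_all(st$chain))
}

#' Risk curve
#'
#' Evaluates [eta_G] on a grid of risk values for one variant, holding all
#' other parameters fixed.
#'
#' @param p A `crd_params` object (`p$r` is ignored).
#' @param r Increasing grid of risk values in `[0, 1]`.
#' @param verbose Print progress per grid point.
#' @return Object of class `crd_risk_curve`: data frame with columns `r` and
#'   `eta_G`, with the variant and parameter hash as attributes.
#' @export
risk_curve <- function(p, r = seq(0, 1, by = 0.05), verbose = FALSE) {
  stopifnot(inherits(p, "crd_params"), all(diff(r) > 0),
            all(r >= 0), all(r <= 1))
  aG <- NULL
  warm <- NULL
  eta <- vapply(r, function(ri) {
    chain <- build_transition_matrix(set_params(p, r = ri), matrix = FALSE)
    if (is.null(aG)) aG <<- group_achievement_all(chain)
    st <- stationary_distribution(chain, warm = warm)
    warm <<- st$p
    e <- sum(st$p * aG)
    if (verbose) message(sprintf("r = %.3f  eta_G = %.4f", ri, e))
    e
  }, numeric(1))
  structure(data.frame(r = r, eta_G = eta),
            class = c("crd_risk_curve", "data.frame"),
            variant = p$variant, params_hash = params_hash(p))
}

#' Critical risk
#'
#' The risk value at which the population-average group achievement crosses
#' a target level (default 0.5), located by bisection to an interval of
#' width `tol`. The endpoints of `bracket` are evaluated first; if they do
#' not straddle the target, a structured no-crossing result is returned
#' instead of an error. Bisection relies on the empirically monotone
#' S-shaped profile of `eta_G(r)`.
#'
#' @param p A `crd_params` object (`p$r` is ignored).
#' @param target Level of `eta_G` to cross (default 0.5).
#' @param bracket Risk interval to search (default `c(0, 1)`).
#' @param tol Width of the final bracket (default `1e-3`).
#' @param verbose Print progress per evaluation.
#' @return Object of class `crd_critical_risk`: list with `r_star` (the
#'   bracket midpoint, or `NA` if no crossing), `converged`, `no_crossing`,
#'   `bracket`, `eta_bracket` (the bracketing `eta_G` values), and
#'   `evaluations` (all `(r, eta_G)` pairs computed).
#' @export
critical_risk <- function(p, target = 0.5, bracket = c(0, 1), tol = 1e-3,
                          verbose = FALSE) {
  stopifnot(inherits(p, "crd_params"), length(bracket) == 2L,
            bracket[1] < bracket[2], target >= 0, target <= 1)
  evals <- list()
  aG <- NULL
  warm <- NULL
  f <- function(r) {
    chain <- build_transition_matrix(set_params(p, r = r), matrix = FALSE)
    if (is.null(aG)) aG <<- group_achievement_all(chain)
    st <- stationary_distribution(chain, warm = warm)
    warm <<- st$p
    e <- sum(st$p * aG)
    evals[[length(evals) + 1L]] <<- c(r = r, eta_G = e)
    if (verbose) message(sprintf("r = %.4f  eta_G = %.4f", r, e))
    e
  }
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- f(lo); e_hi <- f(hi)
  done <- function(converged, no_crossing, r_star) {
    structure(list(r_star = r_star, converged = converged,
                   no_crossing = no_crossing, target = target,
                   bracket = c(lo, hi), eta_bracket = c(e_lo, e_hi),
                   evaluations = do.call(rbind.data.frame, evals)),
              class = "crd_critical_risk")
  }
  if (!((e_lo - target) * (e_hi - target) < 0)) {
    return(done(FALSE, TRUE, NA_real_))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    e_mid <- f(mid)
    if ((e_lo - target) * (e_mid - target) < 0) {
      hi <- mid; e_hi <- e_mid
    } else {
      lo <- mid; e_lo <- e_mid
    }
  }
  done(TRUE, FALSE, (lo + hi) / 2)
}

#' @export
print.crd_critical_risk <- function(x, ...) {
  if (x$no_crossing) {
    cat(sprintf("<crd_critical_risk> no crossing of target %.3g in [%.3g, %.3g] (eta_G: %.4g, %.4g)\n",
                x$target, x$bracket[1], x$bracket[2],
                x$eta_bracket[1], x$eta_bracket[2]))
  } else {
    cat(sprintf("<crd_critical_risk> r* = %.4f (target %.3g, bracket [%.4f, %.4f], eta_G %.4f..%.4f)\n",
                x$r_star, x$target, x$bracket[1], x$bracket[2],
                x$eta_bracket[1], x$eta_bracket[2]))
  }
  invisible(x)
}

#' Stationary strategy abundance
#'
#' Expected number of individuals playing each strategy under the stationary
#' distribution.
#'
#' @param x A `crd_params`, `crd_chain` or `crd_stationary` object.
#' @param s Optional single strategy label; default returns all active
#'   strategies.
#' @return Named numeric vector (sums to `Z` over the active set), or a
#'   scalar when `s` is given.
#' @export
stationary_abundance <- function(x, s = NULL) {
  st <- as_stationary(x)
  p <- st$params
  ab <- stats::setNames(
    as.vector(crossprod(st$states[, p$active, drop = FALSE], st$p)),
    p$active)
  if (is.null(s)) ab else { stopifnot(s %in% p$active); ab[[s]] }
}

#' Incidence of institutional incentives
#'
#' Long-run averages of the reward and punishment the institutions hand out,
#' and how often formed institutions end up rewarding, punishing, or split
#' on a tied vote. For each population state, groups are sampled
#' hypergeometrically (as in [group_achievement]); per group, the budget
#' `Delta_RP` goes to rewards when rewarders outnumber punishers, to fines
#' in the opposite case, and half-and-half on a tie. State-level averages
#' are then weighted by the stationary distribution.
#'
#' @param x A `crd_params`, `crd_chain` or `crd_stationary` object whose
#'   variant has at least one taxed strategy (P or R) active.
#' @return List with `avg_reward` and `avg_punishment` (expected per-group
#'   amounts), `frac_reward`, `frac_punish`, `frac_tie` (shares of
#'   institution-bearing groups by electoral outcome; `NaN` when
#'   institutions never form), and `frac_institution` (probability a random
#'   group forms an institution).
#' @export
incidence_of_incentives <- function(x) {
  st <- as_stationary(x)
  p <- st$params
  if (!any(c("P", "R") %in% p$active)) {
    stop("variant '", p$variant, "' has no institution strategies")
  }
  comps <- group_compositions(p$N, p)
  jP <- comps[, "P"]; jR <- comps[, "R"]
  drp <- institution_budget(comps, p)
  inst <- as.numeric(jP + jR >= p$n_I)
  vals <- cbind(
    reward     = drp * electoral_threshold(jR, jP),
    punishment = drp * electoral_threshold(jP, jR),
    inst       = inst,
    v_reward   = inst * (jR > jP),
    v_punish   = inst * (jP > jR),
    v_tie      = inst * (jP == jR)
  )
  act <- st$states[, p$active, drop = FALSE]
  ca <- p$active
  avg <- vapply(colnames(vals), function(nm) {
    sum(st$p * cpp_state_average(act, p$Z, p$N,
                                 comps[, ca, drop = FALSE], vals[, nm]))
  }, numeric(1))
  list(
    avg_reward = avg[["reward"]],
    avg_punishment = avg[["punishment"]],
    frac_reward = avg[["v_reward"]] / avg[["inst"]],
    frac_punish = avg[["v_punish"]] / avg[["inst"]],
    frac_tie = avg[["v_tie"]] / avg[["inst"]],
    frac_institution = avg[["inst"]]
  )
}

#' Locate attractors of the stochastic dynamics
#'
#' Finds the states that are strict local maxima of the stationary
#' distribution over their one-step neighbourhood (all states reachable by
#' moving a single individual between strategies). Each is reported with its
#' stationary probability and the norm of the gradient of selection as
#' corroboration, and labelled `interior` when every active strategy is
#' present, `cooperative` when cooperators are the plurality, and
#' `defective` when defectors are.
#'
#' @param x A `crd_params`, `crd_chain` or `crd_stationary` object.
#' @param min_probability Drop maxima with stationary probability below this
#'   share of the largest maximum (default 0: report all).
#' @return Object of class `crd_attractors`: data frame with columns `C`,
#'   `P`, `R`, `D`, `probability`, `drift_norm`, `interior`, `label`, sorted
#'   by decreasing probability.
#' @export
find_attractors <- function(x, min_probability = 0) {
  st <- as_stationary(x)
  p <- st$params
  chain <- st$chain
  from <- chain$moves$from
  to <- chain$moves$to
  # every one-step neighbour of a state appears among its outgoing moves
  # (mutation gives each move positive probability when mu > 0)
  not_max <- unique(from[st$p[from] <= st$p[to]])
  idx <- setdiff(seq_along(st$p), not_max)
  if (length(idx) == 0L) {
    out <- data.frame(C = integer(), P = integer(), R = integer(),
                      D = integer(), probability = numeric(),
                      drift_norm = numeric(), interior = logical(),
                      label = character())
    return(structure(out, class = c("crd_attractors", "data.frame")))
  }
  states <- st$states[idx, , drop = FALSE]
  grad <- gradient_field(chain)[idx, , drop = FALSE]
  act <- states[, p$active, drop = FALSE]
  plurality <- p$active[apply(act, 1L, which.max)]
  out <- data.frame(
    C = states[, "C"], P = states[, "P"], R = states[, "R"],
    D = states[, "D"],
    probability = st$p[idx],
    drift_norm = sqrt(rowSums(grad^2)),
    interior = apply(act >= 1L, 1L, all),
    label = ifelse(plurality == "C", "cooperative",
                   ifelse(plurality == "D", "defective", "mixed"))
  )
  out <- out[order(out$probability, decreasing = TRUE), , drop = FALSE]
  if (min_probability > 0 && nrow(out) > 0L) {
    out <- out[out$probability >= min_probability * out$probability[1], ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("crd_attractors", "data.frame"))
}
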