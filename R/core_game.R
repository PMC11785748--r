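#' Enumerate integer compositions
#'
#' All ways of writing `n` as an ordered sum of `parts` non-negative
#' integers, in increasing lexicographic order. This is the backbone of both
#' the group-composition and population-state enumerations.
#'
#' @param n Total (non-negative integer).
#' @param parts Number of parts (positive integer).
#' @return Integer matrix with `choose(n + parts - 1, parts - 1)` rows and
#'   `parts` columns; rows sum to `n`.
#' @export
compositions <- function(n, parts) {
  n <- as.integer(n)
  parts <- as.integer(parts)
  stopifnot(n >= 0L, parts >= 1L)
  if (parts == 1L) {
    return(matrix(n, 1L, 1L))
  }
  cpp_compositions(n, parts)
}

#' Enumerate group compositions of a variant
#'
#' All compositions of `size` players over the variant's active strategies,
#' returned as a full 4-column matrix (columns `C`, `P`, `R`, `D`; inactive
#' strategies pinned to 0).
#'
#' @param size Group size to enumerate (use `p$N` for full groups,
#'   `p$N - 1L` for co-player draws).
#' @param p A `crd_params` object (only the variant matters).
#' @return Integer matrix, rows summing to `size`.
#' @export
group_compositions <- function(size, p) {
  stopifnot(inherits(p, "crd_params"))
  act <- compositions(size, p$S)
  full <- matrix(0L, nrow(act), 4L, dimnames = list(NULL, CRD_STRATEGIES))
  full[, p$active] <- act
  full
}

as_comp <- function(j) {
  # accept a named vector/1-row matrix over any subset of C,P,R,D
  if (is.matrix(j)) {
    stopifnot(!is.null(colnames(j)))
    m <- j
  } else {
    stopifnot(!is.null(names(j)))
    m <- matrix(j, 1L, dimnames = list(NULL, names(j)))
  }
  stopifnot(all(colnames(m) %in% CRD_STRATEGIES))
  full <- matrix(0L, nrow(m), 4L, dimnames = list(NULL, CRD_STRATEGIES))
  full[, colnames(m)] <- as.integer(m)
  stopifnot(all(full >= 0L))
  full
}

#' Electoral threshold function
#'
#' Encodes the majority vote that decides the nature of a group's
#' institution: returns 1 when `x > y`, 1/2 on a tie, and 0 when `x < y`.
#' Calling it with the rewarder count first gives the fraction of the
#' institution budget allocated to rewards; with the punisher count first,
#' the fraction allocated to fines.
#'
#' @param x,y Non-negative counts (vectorised).
#' @return Numeric vector with values in `{0, 1/2, 1}`.
#' @examples
#' electoral_threshold(3, 1)  # majority -> 1
#' electoral_threshold(2, 2)  # tie      -> 1/2
#' @export
electoral_threshold <- function(x, y) {
  stopifnot(all(x >= 0), all(y >= 0))
  (x > y) + 0.5 * (x == y)
}

#' Base payoff of the collective risk dilemma
#'
#' Every member of a group keeps the endowment `b` if at least `n_pg` of the
#' `N` members contributed; otherwise the expected payoff is `(1 - r) * b`,
#' reflecting the probability `r` of losing everything.
#'
#' @param j Group composition: named count vector or matrix with columns
#'   among `C`, `P`, `R`, `D`, rows summing to `p$N`.
#' @param p A `crd_params` object.
#' @return Numeric vector (one value per composition row).
#' @examples
#' p <- crd_params(Z = 20, N = 8, n_pg = 6, r = 0.8)
#' base_payoff(c(C = 6, D = 2), p)  # threshold met: 1
#' base_payoff(c(C = 5, D = 3), p)  # missed: (1 - 0.8) * 1
#' @export
base_payoff <- function(j, p) {
  m <- as_comp(j)
  stopifnot(all(rowSums(m) == p$N))
  j_CPR <- m[, "C"] + m[, "P"] + m[, "R"]
  unname(ifelse(j_CPR >= p$n_pg, p$b, (1 - p$r) * p$b))
}

#' Institution budget of a group
#'
#' The taxes of the `j_P + j_R` institution supporters, multiplied by the
#' return factor `delta`, become available only once at least `n_I`
#' supporters are present: `delta * pi_t * (j_P + j_R)` if
#' `j_P + j_R >= n_I`, else 0.
#'
#' @inheritParams base_payoff
#' @return Numeric vector of budgets (one per composition row).
#' @export
institution_budget <- function(j, p) {
  m <- as_comp(j)
  stopifnot(all(rowSums(m) == p$N))
  j_PR <- m[, "P"] + m[, "R"]
  unname(p$delta * p$pi_t * j_PR * (j_PR >= p$n_I))
}

#' Payoff of a strategy in one group
#'
#' Exact payoffs of the four strategies in a group of composition `j`
#' (including the focal player). On top of the base payoff, contributors pay
#' `c * b`; P and R additionally pay the tax `pi_t`. When an institution
#' forms, its budget is shared equally among the pro-socials if rewarders won
#' the vote, levied equally from the defectors if punishers won, and split
#' half-and-half between the two uses on a tie.
#'
#' @param s Strategy label, one of the variant's active strategies.
#' @param j Group composition including the focal player (`j[s] >= 1`),
#'   rows summing to `p$N`.
#' @inheritParams base_payoff
#' @return Numeric vector of payoffs for strategy `s` (one per row of `j`).
#' @examples
#' p <- crd_params(Z = 20, N = 8, n_pg = 6, n_I = 2, r = 0.8)
#' strategy_payoff("C", c(C = 3, P = 2, R = 1, D = 2), p)
#' @export
strategy_payoff <- function(s, j, p) {
  stopifnot(s %in% p$active)
  m <- as_comp(j)
  stopifnot(all(rowSums(m) == p$N), all(m[, s] >= 1L),
            all(m[, setdiff(CRD_STRATEGIES, p$active), drop = FALSE] == 0L))
  pi0 <- base_payoff(m, p)
  drp <- institution_budget(m, p)
  j_CPR <- m[, "C"] + m[, "P"] + m[, "R"]
  if (s == "D") {
    # fine share; divisor N - j_CPR >= 1 because the focal D is in the group
    fine <- ifelse(drp > 0,
                   drp / (p$N - j_CPR) * electoral_threshold(m[, "P"], m[, "R"]),
                   0)
    return(unname(pi0 - fine))
  }
  reward <- ifelse(drp > 0,
                   drp / j_CPR * electoral_threshold(m[, "R"], m[, "P"]),
                   0)
  pay <- pi0 - p$c * p$b + reward
  if (s %in% c("P", "R")) pay <- pay - p$pi_t
  unname(pay)
}

#' Payoff table over all group compositions
#'
#' Precomputes, for each composition of `size` co-players, the payoff each
#' active strategy would earn after joining the group as the focal player.
#' This table is what makes large state spaces tractable: fitness reduces to
#' hypergeometrically weighted sums over its rows.
#'
#' @param p A `crd_params` object.
#' @param size Number of co-players (defaults to `p$N - 1L`).
#' @return List with `comps` (co-player compositions, full 4-column matrix)
#'   and `pay` (numeric matrix, one column per active strategy:
#'   `pay[k, s]` is the payoff of a focal `s` joining co-players `comps[k, ]`).
#' @export
payoff_table <- function(p, size = p$N - 1L) {
  comps <- group_compositions(size, p)
  pay <- matrix(NA_real_, nrow(comps), p$S, dimnames = list(NULL, p$active))
  for (s in p$active) {
    grp <- comps
    grp[, s] <- grp[, s] + 1L
    pay[, s] <- strategy_payoff(s, grp, p)
  }
  list(comps = comps, pay = pay)
}
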