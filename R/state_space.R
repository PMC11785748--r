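#' Number of population states
#'
#' Closed-form size of the discrete simplex: the number of ways `Z`
#' individuals can be split over the `S` active strategies,
#' `choose(Z + S - 1, S - 1)`.
#'
#' @param p A `crd_params` object.
#' @return Integer count.
#' @export
n_states <- function(p) {
  as.integer(choose(p$Z + p$S - 1, p$S - 1))
}

#' Enumerate the population state space
#'
#' All population states for `(Z, variant)` in increasing lexicographic
#' order of the active-strategy counts. The enumeration order is the state
#' index used by the transition matrix, the stationary distribution and all
#' exports.
#'
#' @param p A `crd_params` object.
#' @return Object of class `crd_states`: an integer matrix with columns
#'   `C`, `P`, `R`, `D` (inactive strategies 0) and one row per state.
#' @examples
#' enumerate_states(crd_params(Z = 2, N = 2, n_pg = 1, variant = "none"))
#' @export
enumerate_states <- function(p) {
  stopifnot(inherits(p, "crd_params"))
  act <- compositions(p$Z, p$S)
  full <- matrix(0L, nrow(act), 4L, dimnames = list(NULL, CRD_STRATEGIES))
  full[, p$active] <- act
  structure(full, class = c("crd_states", "matrix", "array"),
            variant = p$variant, Z = p$Z)
}

#' State rank and unrank
#'
#' Bijection between population states and indices `1..M` matching the
#' [enumerate_states] order, via the combinatorial number system (so ranking
#' is O(S) and needs no enumeration). Counts are taken over the active
#' strategies of `p`.
#'
#' @param i A population state: named count vector or full 4-column matrix
#'   (rows summing to `p$Z`).
#' @param k Index in `1..n_states(p)` (vectorised).
#' @param p A `crd_params` object.
#' @return `state_rank`: integer indices; `state_unrank`: a full 4-column
#'   count matrix.
#' @export
state_rank <- function(i, p) {
  m <- as_comp(i)
  stopifnot(all(rowSums(m) == p$Z),
            all(m[, setdiff(CRD_STRATEGIES, p$active), drop = FALSE] == 0L))
  act <- m[, p$active, drop = FALSE]
  S <- p$S
  rank <- rep(0, nrow(act))
  rem <- rep(p$Z, nrow(act))
  if (S > 1L) {
    for (t in seq_len(S - 1L)) {
      parts_left <- S - t  # parts after this coordinate
      ct <- act[, t]
      # states whose t-th coordinate is smaller than ct (hockey-stick sum)
      rank <- rank + choose(rem + parts_left, parts_left) -
        choose(rem - ct + parts_left, parts_left)
      rem <- rem - ct
    }
  }
  as.integer(rank + 1)
}

#' @rdname state_rank
#' @export
state_unrank <- function(k, p) {
  stopifnot(all(k >= 1), all(k <= n_states(p)))
  S <- p$S
  out <- matrix(0L, length(k), S)
  for (row in seq_along(k)) {
    rest <- k[row] - 1
    rem <- p$Z
    for (t in seq_len(max(S - 1L, 0L))) {
      parts_left <- S - t
      v <- 0L
      repeat {
        block <- choose(rem - v + parts_left - 1, parts_left - 1)
        if (rest < block) break
        rest <- rest - block
        v <- v + 1L
      }
      out[row, t] <- v
      rem <- rem - v
    }
    out[row, S] <- rem
  }
  full <- matrix(0L, length(k), 4L, dimnames = list(NULL, CRD_STRATEGIES))
  full[, p$active] <- out
  full
}
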