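# Independent brute-force oracles used to pin down the hypergeometric and
# linear-algebra machinery on small instances. These deliberately avoid the
# package's own code paths: draws are enumerated individual-by-individual
# with combn(), and stationary distributions come from dense base::eigen().

# expand a population state into one label per individual
pop_labels <- function(i) {
  i <- crdelect:::as_comp(i)[1L, ]
  rep(names(i), times = i)
}

# fitness by exhaustive enumeration of all co-player subsets
oracle_fitness <- function(i, s, p) {
  pop <- pop_labels(i)
  focal <- which(pop == s)[1]
  co <- pop[-focal]
  draws <- utils::combn(length(co), p$N - 1L)
  mean(apply(draws, 2L, function(ix) {
    grp <- table(factor(co[ix], levels = CRD_STRATEGIES))
    grp[s] <- grp[s] + 1L
    strategy_payoff(s, stats::setNames(as.integer(grp), names(grp)), p)
  }))
}

# group achievement by exhaustive enumeration of all C(Z, N) groups
oracle_group_achievement <- function(i, p) {
  pop <- pop_labels(i)
  draws <- utils::combn(length(pop), p$N)
  mean(apply(draws, 2L, function(ix) {
    sum(pop[ix] %in% c("C", "P", "R")) >= p$n_pg
  }))
}

# per-group incentive amounts by exhaustive enumeration
oracle_incentives <- function(i, p) {
  pop <- pop_labels(i)
  draws <- utils::combn(length(pop), p$N)
  res <- apply(draws, 2L, function(ix) {
    grp <- table(factor(pop[ix], levels = CRD_STRATEGIES))
    jP <- grp[["P"]]; jR <- grp[["R"]]
    drp <- if (jP + jR >= p$n_I) p$delta * p$pi_t * (jP + jR) else 0
    c(reward = drp * electoral_threshold(jR, jP),
      punishment = drp * electoral_threshold(jP, jR))
  })
  rowMeans(res)
}

# stationary distribution by dense eigendecomposition of t(T)
oracle_stationary <- function(Tm) {
  e <- eigen(t(as.matrix(Tm)))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  stopifnot(all(v > -1e-12))
  pmax(v, 0) / sum(pmax(v, 0))
}

# direct transcription of the one-step update rule for a hand check
oracle_transition <- function(i, from_s, to_s, p) {
  i <- crdelect:::as_comp(i)[1L, ]
  mut <- p$mu * i[[from_s]] / (3 * p$Z)
  if (i[[to_s]] == 0L) return(mut)
  df <- oracle_fitness(i, to_s, p) - oracle_fitness(i, from_s, p)
  mut + (1 - p$mu) * (i[[from_s]] / p$Z) * (i[[to_s]] / (p$Z - 1)) /
    (1 + exp(-p$beta * df))
}
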