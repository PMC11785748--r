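pm <- crd_params(Z = 10, N = 3, n_pg = 2, n_I = 2, b = 1, c = 0.1, r = 0.6,
                 delta = 2, pi_t = 0.03, mu = 0.1, beta = 1)

test_that("fitness equals the exhaustive co-player enumeration oracle", {
  i <- c(C = 5, P = 2, R = 1, D = 2)
  for (s in c("C", "P", "R", "D")) {
    expect_equal(fitness(i, s, pm), oracle_fitness(i, s, pm))
  }
  # homogeneous population: the only group is all-same
  iC <- c(C = 10)
  expect_equal(fitness(iC, "C", pm),
               strategy_payoff("C", c(C = 3), pm))
  expect_error(fitness(c(C = 10), "D", pm))
})

test_that("transition probabilities follow the pairwise comparison rule", {
  # pure mutation: nobody to imitate
  p4 <- crd_params(Z = 4, N = 2, n_pg = 1, mu = 0.1, beta = 3)
  expect_equal(transition_probability(c(C = 4), "C", "P", p4), 1 / 30)
  # no mutation, no role model: impossible move
  p0 <- set_params(pm, mu = 0)
  expect_equal(transition_probability(c(C = 10), "C", "D", p0), 0)
  # neutral selection halves the imitation factor
  pb0 <- set_params(pm, beta = 0, mu = 0)
  i <- c(C = 6, D = 4)
  expect_equal(transition_probability(i, "C", "D", pb0),
               6 * 4 / (2 * 10 * 9))
  expect_error(transition_probability(c(C = 10), "D", "C", pm))
})

test_that("transition matrix rows are stochastic and match a hand-built chain", {
  for (p in list(pm, set_params(pm, variant = "none"),
                 set_params(pm, variant = "reward", beta = 4))) {
    ch <- build_transition_matrix(p)
    expect_lt(max(abs(Matrix::rowSums(ch$T) - 1)), 1e-12)
    expect_true(all(ch$T@x >= 0 & ch$T@x <= 1))
  }
  # 4-state cooperator-defector chain, hand enumeration via the oracle rule
  p3 <- crd_params(Z = 3, N = 2, n_pg = 1, b = 1, c = 0.2, r = 0.7,
                   mu = 0.05, beta = 2, variant = "none")
  ch <- build_transition_matrix(p3)
  Tm <- as.matrix(ch$T)
  states <- ch$states
  for (a in 1:4) {
    for (b in 1:4) {
      if (a == b) next
      d <- states[b, ] - states[a, ]
      expected <- if (sum(abs(d)) == 2 && d[["C"]] + d[["D"]] == 0) {
        from_s <- if (d[["C"]] == -1) "C" else "D"
        to_s <- setdiff(c("C", "D"), from_s)
        if (states[a, from_s] >= 1) oracle_transition(states[a, ], from_s, to_s, p3) else 0
      } else 0
      expect_equal(Tm[a, b], expected, tolerance = 1e-12)
    }
  }
  expect_equal(diag(Tm), 1 - (Matrix::rowSums(ch$T) - diag(Tm)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sparse stationary solve matches the dense eigen oracle", {
  for (p in list(pm,
                 crd_params(Z = 12, N = 4, n_pg = 3, n_I = 2, r = 0.8,
                            mu = 1 / 12, beta = 2, variant = "punish"),
                 crd_params(Z = 12, N = 4, n_pg = 3, r = 0.4, mu = 0.05,
                            beta = 5, variant = "none"))) {
    ch <- build_transition_matrix(p)
    st <- stationary_distribution(ch)
    expect_lte(st$residual, 1e-10)
    expect_equal(sum(st$p), 1, tolerance = 1e-12)
    expect_lt(sum(abs(st$p - oracle_stationary(ch$T))), 1e-8)
  }
})

test_that("stationary distribution requires mutation", {
  expect_error(stationary_distribution(set_params(pm, mu = 0)),
               "mu = 0")
})

test_that("neutral dynamics are symmetric under strategy relabelling", {
  p <- set_params(pm, beta = 0)
  st <- stationary_distribution(p)
  # swapping any two strategy labels permutes states but not probabilities
  states <- st$states
  perm <- states[, c("P", "C", "R", "D")]
  colnames(perm) <- c("C", "P", "R", "D")
  k <- state_rank(perm, p)
  expect_equal(st$p, st$p[k], tolerance = 1e-9)
  ab <- stationary_abundance(st)
  expect_equal(unname(ab), rep(p$Z / p$S, p$S), tolerance = 1e-8)
})

test_that("gradient of selection is conservative and matches the 1-D chain", {
  g <- gradient_of_selection(c(C = 5, P = 2, R = 1, D = 2), pm)
  expect_equal(sum(g), 0, tolerance = 1e-15)
  # neutral, mutation-free drift vanishes identically
  p0 <- set_params(pm, beta = 0, mu = 0)
  expect_equal(unname(gradient_of_selection(c(C = 5, P = 2, R = 1, D = 2), p0)),
               rep(0, 4))
  expect_equal(unname(gradient_of_selection(c(C = 10), set_params(pm, mu = 0))),
               rep(0, 4))
  # two-strategy birth-death rates by hand
  pn <- crd_params(Z = 10, N = 3, n_pg = 2, r = 0.7, mu = 0.02, beta = 1.5,
                   variant = "none")
  i <- c(C = 4, D = 6)
  up <- oracle_transition(i, "D", "C", pn)
  dn <- oracle_transition(i, "C", "D", pn)
  expect_equal(gradient_of_selection(i, pn)[["C"]], up - dn)
  # full-field version agrees with the per-state function
  ch <- build_transition_matrix(pm)
  gf <- gradient_field(ch)
  expect_lt(max(abs(rowSums(gf))), 1e-14)
  k <- state_rank(c(C = 5, P = 2, R = 1, D = 2), pm)
  expect_equal(gf[k, ], g, tolerance = 1e-12)
})
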