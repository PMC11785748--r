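p8 <- crd_params(Z = 20, N = 8, n_pg = 6, n_I = 2, b = 1, c = 0.1, r = 0.8,
                 delta = 2, pi_t = 0.03)

test_that("base payoff follows the threshold rule", {
  expect_equal(base_payoff(c(C = 6, D = 2), p8), 1.0)
  expect_equal(base_payoff(c(C = 5, D = 3), p8), 0.2)
  p0 <- set_params(p8, r = 0)
  for (k in 0:8) {
    expect_equal(base_payoff(c(C = k, D = 8 - k), p0), 1.0)
  }
})

test_that("institution budget needs the participation threshold", {
  expect_equal(institution_budget(c(C = 4, P = 1, R = 1, D = 2), p8), 0.12)
  expect_equal(institution_budget(c(C = 5, P = 0, R = 1, D = 2), p8), 0)
  expect_equal(institution_budget(c(C = 4, P = 1, R = 1, D = 2),
                                  set_params(p8, pi_t = 0)), 0)
  pn <- set_params(p8, variant = "none")
  expect_equal(institution_budget(c(C = 6, D = 2), pn), 0)
})

test_that("electoral threshold encodes majority, tie and minority", {
  expect_equal(electoral_threshold(3, 1), 1)
  expect_equal(electoral_threshold(2, 2), 0.5)
  expect_equal(electoral_threshold(0, 4), 0)
  expect_error(electoral_threshold(-1, 2))
})

test_that("strategy payoffs reproduce worked punisher-majority and tie cases", {
  j <- c(C = 3, P = 2, R = 1, D = 2)  # punishers win the vote
  expect_equal(strategy_payoff("C", j, p8), 0.9)
  expect_equal(strategy_payoff("P", j, p8), 0.87)
  expect_equal(strategy_payoff("R", j, p8), 0.87)
  expect_equal(strategy_payoff("D", j, p8), 1 - 0.18 / 2)

  jt <- c(C = 4, P = 1, R = 1, D = 2)  # tied vote splits the budget
  expect_equal(strategy_payoff("C", jt, p8), 1 - 0.1 + (0.12 / 6) / 2)
  expect_equal(strategy_payoff("D", jt, p8), 1 - (0.12 / 2) / 2)

  pn <- set_params(p8, variant = "none")
  expect_equal(strategy_payoff("C", c(C = 6, D = 2), pn), 0.9)
  expect_equal(strategy_payoff("D", c(C = 6, D = 2), pn), 1.0)
})

test_that("punishers and rewarders always earn identical payoffs", {
  comps <- group_compositions(p8$N, p8)
  both <- comps[, "P"] >= 1 & comps[, "R"] >= 1
  expect_equal(strategy_payoff("P", comps[both, ], p8),
               strategy_payoff("R", comps[both, ], p8))
})

test_that("institution budget is conserved between rewards and fines", {
  comps <- group_compositions(p8$N, p8)
  pi0 <- base_payoff(comps, p8)
  drp <- institution_budget(comps, p8)
  j_CPR <- comps[, "C"] + comps[, "P"] + comps[, "R"]
  j_D <- comps[, "D"]
  has_C <- comps[, "C"] >= 1
  # reconstruct per-head shares from the payoff definitions
  rew <- rep(NA_real_, nrow(comps))
  rew[has_C] <- strategy_payoff("C", comps[has_C, , drop = FALSE], p8) -
    (pi0[has_C] - p8$c * p8$b)
  has_D <- j_D >= 1
  fine <- rep(NA_real_, nrow(comps))
  fine[has_D] <- pi0[has_D] -
    strategy_payoff("D", comps[has_D, , drop = FALSE], p8)
  jP <- comps[, "P"]; jR <- comps[, "R"]
  win_R <- has_C & has_D & jR > jP
  win_P <- has_C & has_D & jP > jR & drp > 0
  tie <- has_C & has_D & jP == jR & drp > 0
  expect_equal(j_CPR[win_R] * rew[win_R], drp[win_R])
  expect_equal(fine[win_R], rep(0, sum(win_R)))
  expect_equal(j_D[win_P] * fine[win_P], drp[win_P])
  expect_equal(rew[win_P], rep(0, sum(win_P)))
  expect_equal(j_CPR[tie] * rew[tie], drp[tie] / 2)
  expect_equal(j_D[tie] * fine[tie], drp[tie] / 2)
})

test_that("without a funded institution all payoffs reduce to the bare CRD", {
  for (pp in list(set_params(p8, pi_t = 0),
                  set_params(p8, n_I = 8))) {
    comps <- group_compositions(pp$N, pp)
    below <- comps[, "P"] + comps[, "R"] < pp$n_I | pp$pi_t == 0
    pi0 <- base_payoff(comps, pp)
    for (s in c("C", "P", "R")) {
      rows <- below & comps[, s] >= 1
      tax <- if (s == "C") 0 else pp$pi_t
      expect_equal(strategy_payoff(s, comps[rows, , drop = FALSE], pp),
                   pi0[rows] - pp$c * pp$b - tax)
    }
    rows <- below & comps[, "D"] >= 1
    expect_equal(strategy_payoff("D", comps[rows, , drop = FALSE], pp),
                 pi0[rows])
  }
})

test_that("reduced variants are exact face restrictions of the electoral model", {
  faces <- list(reward = "P", punish = "R", none = c("P", "R"))
  for (v in names(faces)) {
    pv <- set_params(p8, variant = v)
    comps <- group_compositions(pv$N, pv)
    expect_true(all(comps[, faces[[v]]] == 0L))
    for (s in pv$active) {
      rows <- comps[, s] >= 1
      expect_equal(
        strategy_payoff(s, comps[rows, , drop = FALSE], pv),
        strategy_payoff(s, comps[rows, , drop = FALSE], p8)
      )
    }
  }
})

test_that("payoff contract rejects absent or inactive focal strategies", {
  expect_error(strategy_payoff("P", c(C = 6, D = 2), p8))
  pn <- set_params(p8, variant = "none")
  expect_error(strategy_payoff("R", c(C = 5, R = 1, D = 2), pn))
})
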