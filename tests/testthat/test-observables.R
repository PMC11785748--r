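po <- crd_params(Z = 10, N = 4, n_pg = 3, n_I = 2, b = 1, c = 0.1, r = 0.6,
                 delta = 2, pi_t = 0.03, mu = 0.1, beta = 1)

test_that("group achievement matches exhaustive group enumeration", {
  expect_equal(group_achievement(c(C = 10), po), 1)
  expect_equal(group_achievement(c(D = 10), po), 0)
  i <- c(C = 6, D = 4)
  expect_equal(group_achievement(i, po), oracle_group_achievement(i, po))
  i2 <- c(C = 3, P = 2, R = 2, D = 3)
  expect_equal(group_achievement(i2, po), oracle_group_achievement(i2, po))
})

test_that("group achievement never decreases when a defector turns cooperator", {
  set.seed(7)
  for (k in 1:20) {
    i <- as.vector(stats::rmultinom(1, po$Z, c(0.3, 0.2, 0.2, 0.3)))
    names(i) <- CRD_STRATEGIES
    if (i[["D"]] == 0) next
    j <- i + c(C = 1, P = 0, R = 0, D = -1)
    a_i <- group_achievement(i, po)
    expect_gte(group_achievement(j, po) - a_i, 0)
    expect_true(a_i >= 0 && a_i <= 1)
  }
})

test_that("eta_G lies in [0, 1] and averages a_G over the stationary chain", {
  st <- stationary_distribution(po)
  e <- eta_G(st)
  expect_gte(e, 0); expect_lte(e, 1)
  # seeded Monte Carlo re-estimate from the same stationary distribution
  set.seed(11)
  draws <- sample.int(length(st$p), 4000, replace = TRUE, prob = st$p)
  aG <- group_achievement(st$states[draws, ], po)
  expect_equal(mean(aG), e, tolerance = 0.02)
})

test_that("critical risk brackets the target and honours no-crossing", {
  ps <- crd_params(Z = 24, N = 4, n_pg = 3, r = 0.5, mu = 1 / 24, beta = 2,
                   variant = "none")
  cr <- critical_risk(ps, bracket = c(0, 1))
  expect_true(cr$converged)
  expect_lte(cr$bracket[2] - cr$bracket[1], 1e-3)
  expect_lte(min(cr$eta_bracket), 0.5)
  expect_gte(max(cr$eta_bracket), 0.5)
  # eta_G > 0 everywhere, so a target of 0 can never be crossed
  nc <- critical_risk(ps, target = 0)
  expect_true(nc$no_crossing)
  expect_true(is.na(nc$r_star))
})

test_that("stationary abundances are conserved and neutral-symmetric", {
  ab <- stationary_abundance(po)
  expect_equal(sum(ab), po$Z, tolerance = 1e-9)
  expect_equal(stationary_abundance(po, "C"), ab[["C"]])
  ab0 <- stationary_abundance(set_params(po, beta = 0))
  expect_equal(unname(ab0), rep(po$Z / po$S, po$S), tolerance = 1e-8)
})

test_that("incentive incidence matches exhaustive enumeration and edge cases", {
  st <- stationary_distribution(po)
  inc <- incidence_of_incentives(st)
  # oracle: state-by-state exhaustive group enumeration, stationary-weighted
  amounts <- vapply(seq_len(nrow(st$states)), function(k) {
    oracle_incentives(st$states[k, ], po)
  }, numeric(2))
  expect_equal(inc$avg_reward, sum(st$p * amounts["reward", ]),
               tolerance = 1e-10)
  expect_equal(inc$avg_punishment, sum(st$p * amounts["punishment", ]),
               tolerance = 1e-10)
  expect_equal(inc$frac_reward + inc$frac_punish + inc$frac_tie, 1,
               tolerance = 1e-12)
  # reward-only: fines are impossible
  incR <- incidence_of_incentives(set_params(po, variant = "reward"))
  expect_identical(incR$avg_punishment, 0)
  expect_identical(incR$frac_punish, 0)
  # no tax, no incentives at all
  inc0 <- incidence_of_incentives(set_params(po, pi_t = 0))
  expect_identical(inc0$avg_reward, 0)
  expect_identical(inc0$avg_punishment, 0)
  expect_error(incidence_of_incentives(set_params(po, variant = "none")))
})

test_that("attractor report labels plurality and interior states correctly", {
  at <- find_attractors(po)
  expect_true(all(at$probability > 0))
  expect_true(all(abs(rowSums(at[, c("C", "P", "R", "D")]) - po$Z) == 0))
  expect_true(all(at$label %in% c("cooperative", "defective", "mixed")))
  expect_true(all(at$interior ==
                    (at$C >= 1 & at$P >= 1 & at$R >= 1 & at$D >= 1)))
  # the top attractor is the global mode of the stationary distribution
  st <- stationary_distribution(po)
  expect_equal(at$probability[1], max(st$p))
})
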