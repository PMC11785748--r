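pmc <- crd_params(Z = 12, N = 4, n_pg = 3, n_I = 2, r = 0.7, mu = 0.05,
                  beta = 2)

test_that("trajectories are reproducible and respect one-step moves", {
  ch <- build_transition_matrix(pmc)
  t1 <- simulate_trajectory(ch, steps = 500, seed = 42)
  t2 <- simulate_trajectory(ch, steps = 500, seed = 42)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_trajectory(ch, steps = 500, seed = 43)
  expect_false(identical(t1$states, t3$states))
  # consecutive recorded states differ by at most one individual move
  d <- abs(diff(t1$states))
  expect_lte(max(rowSums(d)), 2)
  expect_true(all(rowSums(t1$states) == pmc$Z))
})

test_that("without mutation a homogeneous population is absorbing", {
  p0 <- set_params(pmc, mu = 0)
  tr <- simulate_trajectory(p0, i0 = c(C = 12), steps = 200, seed = 1)
  expect_true(all(tr$states[, "C"] == 12))
})

test_that("neutral long-run frequencies approach Z/S per strategy", {
  p0 <- set_params(pmc, beta = 0)
  ch <- build_transition_matrix(p0)
  tr <- simulate_trajectory(ch, i0 = c(C = 12), steps = 2e5, seed = 99,
                            stride = 10)
  means <- colMeans(tr$states[-(1:1000), ])
  expect_equal(unname(means[c("C", "P", "R", "D")]), rep(3, 4),
               tolerance = 0.25)
})

test_that("visit frequencies converge to the exact stationary distribution", {
  ch <- build_transition_matrix(pmc)
  st <- stationary_distribution(ch)
  tr <- simulate_trajectory(ch, i0 = c(C = 12), steps = 4e5, seed = 7,
                            stride = 1)
  k <- state_rank(tr$states, pmc)
  emp <- tabulate(k, nbins = length(st$p)) / length(k)
  expect_lt(sum(abs(emp - st$p)), 0.12)
})

test_that("trajectory classification keys on the pre-convergence P and R peaks", {
  att <- c(C = 9, P = 1, R = 1, D = 1)
  mk <- function(mat) {
    structure(list(states = mat, step = seq_len(nrow(mat)) - 1L,
                   seed = 1L, stride = 1L, params = pmc),
              class = "crd_trajectory")
  }
  base <- c(C = 0, P = 0, R = 0, D = 12)
  no_p <- rbind(base, c(2, 0, 3, 7), c(6, 0, 2, 4), c(9, 1, 1, 1))
  colnames(no_p) <- CRD_STRATEGIES
  expect_identical(classify_trajectory(mk(no_p), att), "R_LED")
  no_r <- no_p[, c("C", "R", "P", "D")]
  colnames(no_r) <- CRD_STRATEGIES
  expect_identical(classify_trajectory(mk(no_r), att), "P_LED")
  stuck <- rbind(base, c(1, 1, 1, 9), c(0, 2, 1, 9))
  colnames(stuck) <- CRD_STRATEGIES
  expect_identical(classify_trajectory(mk(stuck), att), "NOT_CONVERGED")
  even <- rbind(base, c(2, 3, 3, 4), c(9, 1, 1, 1))
  colnames(even) <- CRD_STRATEGIES
  expect_identical(classify_trajectory(mk(even), att), "MIXED")
})

test_that("ensembles are reproducible and tabulate all labels", {
  ch <- build_transition_matrix(pmc)
  en <- simulate_ensemble(ch, n = 6, steps = 3e4, seed = 5,
                          attractor = c(C = 9, P = 1, R = 1, D = 1))
  expect_identical(sum(en$counts), 6L)
  en2 <- simulate_ensemble(ch, n = 6, steps = 3e4, seed = 5,
                           attractor = c(C = 9, P = 1, R = 1, D = 1))
  expect_identical(en$labels, en2$labels)
})
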