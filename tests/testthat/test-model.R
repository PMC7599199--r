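test_that("conditional probabilities follow the local-independence product", {
  # dichotomous case over five items a..e: state {a,c,d}, response {a,b,c}
  ks <- polim_structure(
    rbind(rep(0L, 5), c(1L, 0L, 1L, 1L, 0L), rep(1L, 5)),
    n_levels = 2, items = letters[1:5]
  )
  beta <- .1
  eta <- .2
  E <- matrix(c(1 - eta, eta, beta, 1 - beta), 2, byrow = TRUE)
  p <- polim_params(rep(list(E), 5), c(.2, .5, .3), ks)
  got <- conditional_pattern_prob(
    c(1, 1, 1, 0, 0), c(1, 0, 1, 1, 0), p
  )
  # beta_d (1-beta_a)(1-beta_c) eta_b (1-eta_e)
  expect_equal(got, .1 * .9 * .9 * .2 * .8, tolerance = 1e-15)
  expect_equal(got, .01296, tolerance = 1e-12)
})

test_that("single-item models return the bare matrix entry", {
  ks <- polim_structure(rbind(0L, 1L, 2L), n_levels = 3)
  E <- random_stochastic_matrix(3)
  p <- polim_params(list(E), c(.2, .3, .5), ks)
  for (i in 0:2) {
    for (j in 0:2) {
      expect_equal(conditional_pattern_prob(j, i, p), E[i + 1, j + 1])
    }
  }
})

test_that("identity error matrices make responses deterministic", {
  ks <- polim_structure(rbind(c(0, 1), c(2, 2)), n_levels = 3)
  p <- polim_params(list(diag(3), diag(3)), c(.4, .6), ks)
  expect_equal(conditional_pattern_prob(c(0, 1), c(0, 1), p), 1)
  expect_equal(conditional_pattern_prob(c(0, 1), c(2, 2), p), 0)
  expect_equal(marginal_pattern_prob(c(0, 1), p), .4)
  expect_equal(marginal_pattern_prob(c(1, 1), p), 0)
  sim <- simulate_responses(p, 50, seed = 3)
  # with identity errors every simulated pattern equals its latent state
  keys <- apply(sim$data$patterns, 1, paste0, collapse = "")
  expect_true(all(keys %in% c("01", "22")))
  latent_freq <- table(factor(sim$state_index, levels = 1:2))
  obs_freq <- setNames(rep(0, 2), c("01", "22"))
  obs_freq[keys] <- sim$data$freq
  expect_equal(unname(obs_freq), as.vector(latent_freq))
})

test_that("marginals sum to one over the full pattern space", {
  set.seed(11)
  ks <- random_structure(2, 3, 5, seed = 2)
  p <- random_test_params(ks)
  pats <- enumerate_patterns(2, 3)
  expect_equal(sum(marginal_pattern_prob(pats, p)), 1, tolerance = 1e-12)
  # larger space, still exhaustive
  ks2 <- random_structure(4, 3, 12, seed = 9)
  p2 <- random_test_params(ks2)
  expect_equal(
    sum(marginal_pattern_prob(enumerate_patterns(4, 3), p2)), 1,
    tolerance = 1e-10
  )
})

test_that("dichotomous conditionals equal the four-factor product", {
  # oracle: P(R|K) = prod(1-beta over K∩R) prod(beta over K\R)
  #                  prod(eta over R\K) prod(1-eta over complement)
  set.seed(21)
  Q <- 4
  ks <- random_structure(Q, 2, 6, seed = 13)
  beta <- runif(Q, .05, .3)
  eta <- runif(Q, .05, .3)
  eps <- lapply(seq_len(Q), function(q) {
    matrix(c(1 - eta[q], eta[q], beta[q], 1 - beta[q]), 2, byrow = TRUE)
  })
  p <- polim_params(eps, random_simplex(nrow(ks)), ks)
  pats <- enumerate_patterns(Q, 2)
  for (s in seq_len(nrow(ks))) {
    K <- ks[s, ]
    for (r in seq_len(nrow(pats))) {
      R <- pats[r, ]
      oracle <- prod(
        (1 - beta)[K == 1 & R == 1], beta[K == 1 & R == 0],
        eta[K == 0 & R == 1], (1 - eta)[K == 0 & R == 0]
      )
      expect_equal(conditional_pattern_prob(R, K, p), oracle,
        tolerance = 1e-12
      )
    }
  }
})

test_that("log-likelihood is linear in frequencies and matches a naive sum", {
  set.seed(31)
  ks <- random_structure(3, 3, 6, seed = 17)
  p <- random_test_params(ks)
  resp <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
  d1 <- polim_data(resp, n_levels = 3)
  # naive per-respondent oracle
  naive <- sum(vapply(seq_len(10), function(r) {
    log(marginal_pattern_prob(resp[r, ], p))
  }, numeric(1)))
  expect_equal(log_likelihood(d1, p), naive, tolerance = 1e-10)
  d2 <- polim_data(resp, freq = rep(2, 10), n_levels = 3)
  expect_equal(log_likelihood(d2, p), 2 * log_likelihood(d1, p))
  # a single pattern with frequency one is just log P(R)
  d3 <- polim_data(resp[1, , drop = FALSE], n_levels = 3)
  expect_equal(log_likelihood(d3, p), log(marginal_pattern_prob(resp[1, ], p)))
})

test_that("zero-probability patterns are reported by name", {
  ks <- polim_structure(rbind(c(0, 0)), n_levels = 2)
  p <- polim_params(list(diag(2), diag(2)), 1, ks)
  d <- polim_data(rbind(c(1, 1)), n_levels = 2)
  expect_error(log_likelihood(d, p), "11")
})

test_that("free-parameter count follows the closed formula", {
  ks <- random_structure(10, 4, 1000, seed = 5)
  expect_equal(count_free_parameters(ks), 10 * 4 * 3 + 1000 - 1) # 1119
  ks2 <- random_structure(6, 2, 10, seed = 5)
  expect_equal(count_free_parameters(ks2), 2 * 6 + 10 - 1)
  one <- polim_structure(rbind(c(0, 1, 2)), n_levels = 3)
  expect_equal(count_free_parameters(one), 3 * 3 * 2)
})

test_that("simulation matches its generating row frequencies", {
  # point mass on one state: per item, response frequencies approach the
  # corresponding error-matrix row
  ks <- polim_structure(rbind(c(1, 2)), n_levels = 3)
  E1 <- matrix(c(.7, .2, .1, .1, .8, .1, .2, .2, .6), 3, byrow = TRUE)
  E2 <- matrix(c(.6, .3, .1, .05, .9, .05, .1, .1, .8), 3, byrow = TRUE)
  p <- polim_params(list(E1, E2), 1, ks)
  n <- 4000
  sim <- simulate_responses(p, n, seed = 99)
  resp <- sim$data$patterns[rep(seq_len(nrow(sim$data$patterns)),
    sim$data$freq
  ), ]
  for (j in 0:2) {
    phat1 <- mean(resp[, 1] == j)
    se <- sqrt(E1[2, j + 1] * (1 - E1[2, j + 1]) / n)
    expect_lt(abs(phat1 - E1[2, j + 1]), 3 * se + 1e-9)
    phat2 <- mean(resp[, 2] == j)
    se2 <- sqrt(E2[3, j + 1] * (1 - E2[3, j + 1]) / n)
    expect_lt(abs(phat2 - E2[3, j + 1]), 3 * se2 + 1e-9)
  }
  # seeded reproducibility
  sim2 <- simulate_responses(p, 100, seed = 42)
  sim3 <- simulate_responses(p, 100, seed = 42)
  expect_identical(sim2$data$patterns, sim3$data$patterns)
  expect_identical(sim2$data$freq, sim3$data$freq)
})
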