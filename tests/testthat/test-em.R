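test_that("posteriors follow Bayes rule on a hand-computed instance", {
  ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
  E <- matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)
  p <- polim_params(list(E, E), c(.4, .6), ks)
  d <- polim_data(rbind(c(0, 1)))
  # P(01|00) = .8 * .2, P(01|11) = .3 * .7
  num <- c(.4 * .8 * .2, .6 * .3 * .7)
  post <- posterior_states(d, p)
  expect_equal(as.vector(post), num / sum(num), tolerance = 1e-12)
  expect_equal(rowSums(post), 1, ignore_attr = TRUE)

  # identity errors: point mass on the observed pattern
  pid <- polim_params(list(diag(2), diag(2)), c(.4, .6), ks)
  did <- polim_data(rbind(c(1, 1)))
  expect_equal(as.vector(posterior_states(did, pid)), c(0, 1))

  # flat conditionals: posterior equals the prior
  pflat <- polim_params(
    list(matrix(.5, 2, 2), matrix(.5, 2, 2)),
    c(.25, .75), ks
  )
  expect_equal(as.vector(posterior_states(did, pflat)), c(.25, .75))
})

test_that("a single-state structure reduces EM to observed proportions", {
  ks <- polim_structure(rbind(c(1, 2)), n_levels = 3)
  set.seed(8)
  resp <- cbind(
    sample(0:2, 200, replace = TRUE, prob = c(.2, .7, .1)),
    sample(0:2, 200, replace = TRUE, prob = c(.1, .2, .7))
  )
  d <- polim_data(resp, n_levels = 3)
  fit <- em_fit(d, ks, tol = 1e-10)
  expect_equal(fit$params$pi, 1)
  expect_equal(fit$params$epsilon[[1]][2, ],
    tabulate(resp[, 1] + 1, 3) / 200,
    tolerance = 1e-8
  )
  expect_equal(fit$params$epsilon[[2]][3, ],
    tabulate(resp[, 2] + 1, 3) / 200,
    tolerance = 1e-8
  )
})

test_that("the EM log-likelihood never decreases", {
  ks <- random_structure(4, 3, 8, seed = 31)
  truth <- random_test_params(ks)
  sim <- simulate_responses(truth, 300, seed = 32)
  fit <- em_fit(sim$data, ks, tol = 1e-8, max_iter = 300)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  fitr <- em_fit(sim$data, ks, init = "random", seed = 77, tol = 1e-8,
                 max_iter = 300)
  expect_true(all(diff(fitr$loglik_trace) > -1e-8))
  fitc <- em_fit_constrained(sim$data, ks, tol = 1e-8, max_iter = 150)
  expect_true(all(diff(fitc$loglik_trace) > -1e-8))
})

test_that("the truth is a fixed point of EM on exact expected data", {
  set.seed(41)
  # every item attains every level somewhere in the structure, so all
  # error-matrix rows are informed
  ks <- polim_structure(
    rbind(
      c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(0, 1, 2), c(2, 0, 1)
    ),
    n_levels = 3
  )
  E <- dominant_error_matrix(3, 0.85)
  truth <- polim_params(
    list(E, dominant_error_matrix(3, 0.8), dominant_error_matrix(3, 0.9)),
    random_simplex(5), ks
  )
  pats <- enumerate_patterns(3, 3)
  probs <- marginal_pattern_prob(pats, truth)
  exact <- polim_data(pats, freq = probs, n_levels = 3)
  fit <- em_fit(exact, ks, init = truth, tol = -1, max_iter = 2)
  for (q in 1:3) {
    expect_equal(fit$params$epsilon[[q]], truth$epsilon[[q]],
      tolerance = 1e-7
    )
  }
  expect_equal(fit$params$pi, truth$pi, tolerance = 1e-7)
})

test_that("EM recovers generating parameters on a small well-separated model", {
  ks <- random_structure(5, 3, 10, seed = 51)
  E <- dominant_error_matrix(3, 0.9)
  truth <- polim_params(rep(list(E), 5), rep(.1, 10), ks)
  sim <- simulate_responses(truth, 1500, seed = 52)
  fit <- em_fit(sim$data, ks, tol = 1e-7)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$epsilon[[1]] - E)), 0.06)
  expect_lt(max(abs(fit$params$pi - 0.1)), 0.03)
})

test_that("constrained EM iterates stay half-monotone and fit rates", {
  ks <- random_structure(4, 4, 8, seed = 61)
  om <- matrix(NA_real_, 4, 4)
  up <- matrix(NA_real_, 4, 4)
  om[row(om) < col(om)] <- 0.3
  up[row(up) > col(up)] <- 0.25
  rates_true <- rate_parameters(om, up, n_levels = 4)
  eps_true <- rates_to_epsilon(rates_true)
  truth <- polim_params(rep(list(eps_true), 4), rep(1 / 8, 8), ks)
  sim <- simulate_responses(truth, 2000, seed = 62)
  fit <- em_fit_constrained(sim$data, ks, tol = 1e-6, max_iter = 200)
  dm <- manhattan_metric(4)
  for (q in 1:4) {
    expect_true(as.logical(is_delta_half_monotone(fit$params$epsilon[[q]], dm)))
    expect_rowstochastic(fit$params$epsilon[[q]], tol = 1e-9)
    expect_true(attr(fit$rates[[q]], "valid"))
  }
  # recovered rates near the truth at this sample size
  got_om <- sapply(fit$rates, function(r) r$omega[row(om) < col(om)])
  expect_lt(mean(abs(got_om - 0.3)), 0.12)
})

test_that("identifiability check flags symmetric structures and not others", {
  # well-behaved case: a dichotomous structure that is neither forward nor
  # backward graded in any item and has fewer free parameters than
  # response-pattern degrees of freedom
  ks <- polim_structure(
    rbind(c(0, 0, 0, 0), c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 1, 1, 1)),
    n_levels = 2
  )
  E <- matrix(c(.9, .1, .12, .88), 2, byrow = TRUE)
  truth <- polim_params(rep(list(E), 4), c(.3, .25, .25, .2), ks)
  sim <- simulate_responses(truth, 3000, seed = 71)
  chk <- identifiability_check(sim$data, ks,
    n_restarts = 6, seed = 5,
    tol = 1e-10, max_iter = 5000
  )
  expect_lt(chk$max_param_sd, 1e-3)
  expect_gte(chk$n_in_window, 2)

  # over-parameterized counterexample: one dichotomous item with two
  # states has 3 free parameters against 1 degree of freedom, so a ridge
  # of equal-likelihood optima exists and restarts scatter along it
  ks2 <- polim_structure(rbind(0L, 1L), n_levels = 2)
  d2 <- polim_data(rbind(0L, 1L), freq = c(60, 40))
  chk2 <- identifiability_check(d2, ks2,
    n_restarts = 8, seed = 9,
    tol = 1e-10, max_iter = 2000, window = 1e-4
  )
  expect_gt(chk2$max_param_sd, 1e-3)
})
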