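test_that("metric constructors produce the expected distances", {
  dh <- hamming_metric(4)
  expect_equal(diag(dh), rep(0, 4))
  expect_equal(dh[1, 4], 1)
  dm <- manhattan_metric(4)
  expect_equal(dm[1, 2], 1) # delta(a, b)
  expect_equal(dm[1, 3], 2) # delta(a, c)
  expect_equal(dm[1, 4], 3) # delta(a, d)
  expect_equal(diag(dm), rep(0, 4))
  expect_error(level_metric(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(level_metric(matrix(c(1, 1, 1, 1), 2)), "diagonal")
})

test_that("manhattan distance equals the down-set symmetric difference", {
  # |i_downset \ j_downset| + |j_downset \ i_downset| on a 5-chain
  dm <- manhattan_metric(5)
  downset <- function(l) 0:l
  for (i in 0:4) {
    for (j in 0:4) {
      sym <- length(union(
        setdiff(downset(i), downset(j)),
        setdiff(downset(j), downset(i))
      ))
      expect_equal(dm[i + 1, j + 1], sym)
    }
  }
})

test_that("metric axioms are checked exhaustively with witnesses", {
  expect_true(check_metric_axioms(manhattan_metric(5))$triangle)
  expect_true(check_metric_axioms(hamming_metric(4))$triangle)
  ax <- check_metric_axioms(delta1_table())
  expect_false(ax$triangle)
  # delta1(a, d) = 5 > delta1(a, b) + delta1(b, d) = 4
  wit <- ax$triangle_witnesses
  expect_true(any(wit[, "i"] == 0 & wit[, "via"] == 1 & wit[, "j"] == 3))
})

test_that("order-respecting verdicts match the tabulated examples", {
  expect_true(is_order_respecting(manhattan_metric(4)))
  expect_true(is_order_respecting(delta1_table()))
  h <- is_order_respecting(hamming_metric(3))
  expect_false(h) # constant off-diagonal violates strict growth
  expect_gt(nrow(attr(h, "witnesses")), 0)
  # the two 3-level metrics from the order-respecting example
  d1 <- level_metric(matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3))
  d2 <- level_metric(matrix(c(0, 3, 4, 3, 0, 2, 4, 2, 0), 3))
  expect_true(is_order_respecting(d1))
  expect_true(is_order_respecting(d2))
})

test_that("restricted same-side triples have the reference counts", {
  t4 <- restricted_triples(4)
  expect_equal(nrow(t4), 44) # out of the 4^3 = 64 triples
  expect_equal(nrow(restricted_triples(2)), 6)
  # every retained triple has j and k on one side of i
  ok <- apply(t4, 1, function(t) {
    t[1] <= min(t[2], t[3]) || max(t[2], t[3]) < t[1]
  })
  expect_true(all(ok))
  # the printed counterexample triple (c, d, a) is a mixed-side triple
  expect_false(any(t4[, 1] == 2 & t4[, 2] == 3 & t4[, 3] == 0))
})

test_that("the tabulated f1/delta1 pair falsifies monotonicity as printed", {
  v <- is_delta_monotone(f1_table(), delta1_table())
  expect_false(as.logical(v))
  viol <- attr(v, "violations")
  # (c, d, a): delta1(c,d)=1 < delta1(c,a)=3 but f1(c,d)=4 < f1(c,a)=7
  expect_true(any(viol[, 1] == 2 & viol[, 2] == 3 & viol[, 3] == 0))
  expect_equal(attr(v, "n_checked"), 64)
  # half-monotonicity tests the same condition on the 44 same-side triples;
  # the checker reports its finding (the (b,c,d) triple fails there)
  h <- is_delta_half_monotone(f1_table(), delta1_table())
  expect_equal(attr(h, "n_checked"), 44)
  expect_s3_class(h, "monotonicity_check")
})

test_that("partial pair functions: f2 is delta1- but not delta2-monotone", {
  d1 <- level_metric(matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3))
  d2 <- level_metric(matrix(c(0, 3, 4, 3, 0, 2, 4, 2, 0), 3))
  f2 <- matrix(NA_real_, 3, 3)
  f2[2, 1] <- .2 # f2(b, a)
  f2[2, 3] <- .1 # f2(b, c)
  expect_true(as.logical(is_delta_monotone(f2, d1)))
  v2 <- is_delta_monotone(f2, d2)
  expect_false(as.logical(v2))
  expect_gt(attr(v2, "n_skipped"), 0)
})

test_that("hamming-monotonicity coincides with modality", {
  set.seed(99)
  for (rep in 1:50) {
    E <- random_stochastic_matrix(3)
    expect_equal(
      as.logical(is_delta_monotone(E, hamming_metric(3))),
      as.logical(check_modality(E))
    )
  }
  expect_true(check_modality(diag(3) * 0.94 + 0.02))
  tie <- matrix(c(.5, .5, .3, .7), 2, byrow = TRUE)
  expect_false(check_modality(tie)) # strict inequality required
})

test_that("overall error requires the diagonal to dominate the row", {
  row <- c(2, 10, 100, 30, 15) / 157
  E <- matrix(rep(row, 5), 5, byrow = TRUE)
  # the row peaks at level 2: 100/157 > 57/157, so row 2 passes both
  expect_true(attr(check_modality(E), "rows")[3])
  expect_true(attr(check_overall_error(E), "rows")[3])
  expect_false(attr(check_modality(E), "rows")[1])
  low <- matrix(c(.5, .3, .2, .1, .6, .3, .2, .3, .5), 3, byrow = TRUE)
  expect_false(as.logical(check_overall_error(low)))
  hi <- diag(3) * 0.95 + 0.025
  expect_true(as.logical(check_overall_error(hi)))
})

test_that("column view transposes and reproduces dichotomous conditions", {
  E <- matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)
  expect_identical(column_view(column_view(E)), E)
  # dichotomous column monotonicity under the Manhattan metric:
  # beta < 1 - eta and eta < 1 - beta
  dm <- manhattan_metric(2)
  for (beta in c(.1, .45, .6)) {
    for (eta in c(.1, .45, .6)) {
      E2 <- matrix(c(1 - eta, eta, beta, 1 - beta), 2, byrow = TRUE)
      verdict <- as.logical(is_delta_monotone(column_view(E2), dm))
      expect_equal(verdict, beta < 1 - eta && eta < 1 - beta)
    }
  }
})

test_that("monotone implies half-monotone and Proposition-1 holds", {
  set.seed(7)
  for (rep in 1:200) {
    L <- sample(3:6, 1)
    dstar <- random_order_respecting_metric(L)
    dother <- random_order_respecting_metric(L)
    f <- monotone_function_for(dstar)
    expect_true(as.logical(is_delta_monotone(f, dstar)))
    # monotone => half-monotone for the same metric
    expect_true(as.logical(is_delta_half_monotone(f, dstar)))
    # and half-monotone for ANY order-respecting metric
    expect_true(as.logical(is_delta_half_monotone(f, dother)))
  }
})
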