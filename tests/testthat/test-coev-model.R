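# Rate matrix construction, stationary distribution and P(t).

test_that("Coev rate matrix follows the five-rule entry classification", {
  Q <- build_coev_Q(coev_params(s = 2, d = 3, r1 = 4, r2 = 5),
                    c("AA", "CC"), nt)
  expect_equal(Q["AA", "CC"], 0)   # differs at both positions
  expect_equal(Q["AA", "CA"], 2)   # in profile -> out: s
  expect_equal(Q["CA", "CC"], 3)   # out -> in profile: d
  expect_equal(Q["GA", "TA"], 4)   # single position-1 change outside: r1
  expect_equal(Q["GA", "GT"], 5)   # single position-2 change outside: r2
  expect_equal(max(abs(rowSums(Q))), 0)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  # double changes always zero
  toks <- rownames(Q)
  d1 <- outer(substr(toks, 1, 1), substr(toks, 1, 1), "!=")
  d2 <- outer(substr(toks, 2, 2), substr(toks, 2, 2), "!=")
  expect_true(all(Q[d1 & d2] == 0))
})

test_that("independent matrix uses only r1/r2 and has the right dimension", {
  Qi <- build_independent_Q(coev_params(1, 1, 4, 5), nt)
  expect_equal(dim(Qi), c(16, 16))
  expect_equal(Qi["AA", "CA"], 4)
  expect_equal(Qi["AA", "AC"], 5)
  expect_equal(Qi["AA", "CC"], 0)
  Qaa <- build_independent_Q(coev_params(1, 1, 1, 1), aa)
  expect_equal(dim(Qaa), c(400, 400))
  Qaa2 <- build_coev_Q(coev_params(1, 10, 1, 1), c("AA", "TT"), aa)
  expect_equal(dim(Qaa2), c(400, 400))
})

test_that("stationary distribution solves piQ = 0 and responds to d/s", {
  # symmetric independent chain: uniform
  Qi <- build_independent_Q(coev_params(1, 1, 2, 2), nt)
  pi_u <- stationary_distribution(Qi)
  expect_equal(unname(pi_u), rep(1 / 16, 16), tolerance = 1e-10)
  # defining property on an asymmetric coev chain
  Q <- build_coev_Q(coev_params(1, 10, 3, 0.5), c("AA", "CC"), nt)
  pi <- stationary_distribution(Q)
  expect_lt(max(abs(pi %*% Q)), 1e-10)
  expect_equal(sum(pi), 1)
  expect_true(all(pi >= 0))
  # profile occupancy increases with d/s
  occ <- function(ds) {
    Q <- build_coev_Q(coev_params(1, ds, 2, 2), c("AA", "CC"), nt)
    sum(stationary_distribution(Q)[c("AA", "CC")])
  }
  expect_gt(occ(10), occ(1))
  # monotone on a grid
  occs <- vapply(c(1, 2, 5, 10, 50), occ, 0)
  expect_true(all(diff(occs) > 0))
})

test_that("transition matrices are stochastic and consistent", {
  Q <- build_coev_Q(coev_params(1.3, 4, 0.7, 2.1), c("AC", "CA"), nt)
  expect_equal(transition_matrix(Q, 0), diag(16), ignore_attr = TRUE)
  for (t in c(0.1, 1, 10)) {
    P <- transition_matrix(Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_error(transition_matrix(Q, -1), "invalid argument")
  # small-t series: P(t) ~ I + Qt, second-order error (Qt)^2/2; rates of
  # order one keep that term well under the 1e-6 check at t = 1e-4
  Q1 <- build_coev_Q(coev_params(0.5, 1, 0.8, 0.6), c("AC", "CA"), nt)
  P <- transition_matrix(Q1, 1e-4)
  expect_lt(max(abs(P - (diag(16) + Q1 * 1e-4))), 1e-6)
})

test_that("Chapman-Kolmogorov and the left fixed point hold", {
  set.seed(5)
  for (rep in 1:5) {
    params <- coev_params(runif(1, 0.2, 4), runif(1, 0.2, 4),
                          runif(1, 0.2, 4), runif(1, 0.2, 4))
    Q <- build_coev_Q(params, random_profile(nt), nt)
    t1 <- runif(1, 0.05, 2); t2 <- runif(1, 0.05, 2)
    P12 <- transition_matrix(Q, t1) %*% transition_matrix(Q, t2)
    expect_lt(max(abs(P12 - transition_matrix(Q, t1 + t2))), 1e-8)
    pi <- stationary_distribution(Q)
    expect_lt(max(abs(pi %*% transition_matrix(Q, t1) - pi)), 1e-8)
  }
})

test_that("rate parameters must be positive and finite", {
  expect_error(coev_params(0, 1, 1, 1), "strictly positive")
  expect_error(coev_params(1, -2, 1, 1), "strictly positive")
  expect_error(coev_params(1, Inf, 1, 1), "strictly positive")
})
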