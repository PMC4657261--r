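# Simulation of coevolving pairs: root draws, branch evolution, layout.

test_that("root states follow the frequency vector of Q", {
  set.seed(2)
  Qi <- build_independent_Q(coev_params(1, 1, 2, 2), nt)
  draws <- replicate(4000, draw_root_state(Qi))
  cs <- suppressWarnings(chisq.test(table(factor(draws,
                                                 levels = rownames(Qi)))))
  expect_gt(cs$p.value, 0.01)  # uniform stationary by symmetry
  # strong coevolution concentrates the root draw on the profile
  Qc <- build_coev_Q(coev_params(1, 50, 2, 2), c("AA", "CC"), nt)
  in_phi <- mean(replicate(800, draw_root_state(Qc)) %in% c("AA", "CC"))
  Q1 <- build_coev_Q(coev_params(1, 1, 2, 2), c("AA", "CC"), nt)
  in_phi1 <- mean(replicate(800, draw_root_state(Q1)) %in% c("AA", "CC"))
  expect_gt(in_phi, in_phi1)
  set.seed(77); a <- draw_root_state(Qc)
  set.seed(77); b <- draw_root_state(Qc)
  expect_identical(a, b)
})

test_that("zero branch length means no change in either sampler", {
  Q <- build_coev_Q(coev_params(1, 5, 2, 2), c("AA", "CC"), nt)
  expect_identical(evolve_branch_expm("GA", Q, 0), "GA")
  expect_identical(evolve_branch_gillespie("GA", Q, 0), "GA")
})

test_that("expm branch sampler matches its P(t) row", {
  set.seed(12)
  Q <- build_coev_Q(coev_params(1, 4, 1.5, 0.8), c("AA", "CC"), nt)
  P <- transition_matrix(Q, 0.5)
  draws <- replicate(4000, evolve_branch_expm("AA", Q, 0.5))
  cs <- suppressWarnings(
    chisq.test(table(factor(draws, levels = rownames(Q))), p = P["AA", ]))
  expect_gt(cs$p.value, 0.01)
  # double changes are reachable through paths: P(t) entries all positive
  expect_true(all(P > 0))
})

test_that("gillespie and expm samplers agree on the end-state law", {
  set.seed(13)
  Q <- build_coev_Q(coev_params(1, 6, 2, 2), c("AA", "CC"), nt)
  for (t in c(0.1, 1)) {
    a <- replicate(3000, evolve_branch_gillespie("CA", Q, t))
    b <- replicate(3000, evolve_branch_expm("CA", Q, t))
    tab <- rbind(table(factor(a, levels = rownames(Q))),
                 table(factor(b, levels = rownames(Q))))
    cs <- suppressWarnings(chisq.test(tab))
    expect_gt(cs$p.value, 0.01)
  }
})

test_that("strong d pulls trajectories into the profile over time", {
  set.seed(14)
  Q <- build_coev_Q(coev_params(1, 100, 2, 2), c("AA", "CC"), nt)
  frac_in <- function(t)
    mean(replicate(400, evolve_branch_gillespie("GA", Q, t)) %in%
           c("AA", "CC"))
  expect_gt(frac_in(2), frac_in(0.1))
})

test_that("simulate_pairs writes 2 columns per pair with a shared profile", {
  tr <- random_tree(4, mean_bl = 0.3)
  sim <- simulate_pairs(tr, coev_params(1, 10, 2, 2), 15, seed = 20)
  expect_equal(dim(sim$alignment$seqs), c(4, 30))
  expect_equal(sort(sim$alignment$taxa), sort(tr$tip.label))
  expect_length(sim$root_states, 15)
  expect_silent(validate_profile(sim$profile, nt))
  # pair i occupies columns 2i-1, 2i: root states recorded per pair
  expect_true(all(sim$root_states %in% rownames(
    build_coev_Q(sim$params, sim$profile, nt))))
  # determinism under seed
  sim2 <- simulate_pairs(tr, coev_params(1, 10, 2, 2), 15, seed = 20)
  expect_identical(sim$alignment$seqs, sim2$alignment$seqs)
  expect_identical(sim$profile, sim2$profile)
})

test_that("all-zero branch lengths copy the root state to every leaf", {
  tr <- parse_newick("((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulate_pairs(tr, coev_params(1, 5, 2, 2), 3,
                        profile = c("AA", "CC"), seed = 21)
  for (p in 1:3) {
    col <- paste0(sim$alignment$seqs[, 2 * p - 1],
                  sim$alignment$seqs[, 2 * p])
    expect_true(all(col == sim$root_states[p]))
  }
})

test_that("long branches converge to the stationary distribution", {
  set.seed(22)
  Q <- build_coev_Q(coev_params(1, 8, 1.5, 1.5), c("AT", "TA"), nt)
  pi <- stationary_distribution(Q)
  draws <- replicate(3000, evolve_branch_expm("AA", Q, 500))
  cs <- suppressWarnings(
    chisq.test(table(factor(draws, levels = rownames(Q))), p = pi))
  expect_gt(cs$p.value, 0.01)
})

test_that("round-trip: simulated coevolution is detected by the ML path", {
  set.seed(23)
  tr <- random_tree(40)
  sim <- simulate_pairs(tr, coev_params(1, 20, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 24)
  fit <- evaluate_pair_ml(tr, sim$alignment, 1, 2)
  expect_gt(fit$delta_aic, 0)
})
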