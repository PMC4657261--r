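# ML rate optimisation, profile search and the end-to-end evaluation.

test_that("branch-length/rate scale confound is an exact invariance", {
  set.seed(21)
  tr <- random_tree(8)
  sim <- simulate_pairs(tr, coev_params(1, 8, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 4)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  ll <- coevolve:::.make_pair_loglik(tr, pc, c("AA", "CC"), nt)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  ll2 <- coevolve:::.make_pair_loglik(tr2, pc, c("AA", "CC"), nt)
  expect_equal(ll(1, 8, 1.5, 0.7), ll2(0.5, 4, 0.75, 0.35),
               tolerance = 1e-8)
})

test_that("rates are recovered qualitatively from coevolving data", {
  set.seed(31)
  tr <- random_tree(50)
  hits <- 0
  for (r in 1:5) {
    sim <- simulate_pairs(tr, coev_params(1, 10, 1, 1), 1,
                          profile = c("AA", "CC"))
    pc <- extract_pair_column(sim$alignment, tr, 1, 2)
    fit <- optimize_rates(tr, pc, c("AA", "CC"),
                          control = list(mode = "fast", maxit = 200))
    if (fit$params$d / fit$params$s > 1) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("degenerate all-identical data is flagged, not fatal", {
  tr <- random_tree(6)
  pc <- toy_pair_data(setNames(rep("AA", 6), tr$tip.label))
  fit <- optimize_rates(tr, pc, c("AA", "CC"),
                        control = list(mode = "fast", maxit = 150))
  expect_true(fit$flagged)
  expect_true(is.finite(fit$logL))
})

test_that("nucleotide profile search is exhaustive and recovers the truth", {
  set.seed(41)
  tr <- random_tree(40)
  sim <- simulate_pairs(tr, coev_params(1, 20, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 10)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  rank <- search_profiles_nt(tr, pc)
  expect_equal(nrow(rank), 192)
  expect_true(all(c("AA", "CC") %in%
                    parse_profile(rank$profile[1], nt)))
  expect_true(!is.unsorted(rev(rank$logL)))
})

test_that("amino-acid candidate generation respects injectivity and caps", {
  # observed pairs sharing a position-1 letter cannot form a profile
  d1 <- toy_pair_data(setNames(rep(c("AA", "AT"), 3), paste0("t", 1:6)), aa)
  cands <- coevolve:::.candidate_profiles_aa(d1, aa)
  expect_length(cands, 0)
  # half AA / half TT: {AA, TT} is a candidate
  d2 <- toy_pair_data(setNames(rep(c("AA", "TT"), 5), paste0("t", 1:10)), aa)
  cands2 <- coevolve:::.candidate_profiles_aa(d2, aa)
  expect_true(any(vapply(cands2, identical, TRUE, c("AA", "TT"))))
  # cap respected
  d3 <- toy_pair_data(
    setNames(paste0(aa$letters[1:10], rev(aa$letters[1:10])),
             paste0("t", 1:10)), aa)
  expect_lte(length(coevolve:::.candidate_profiles_aa(d3, aa, 50)), 50)
})

test_that("amino-acid search ranks the generating profile first", {
  set.seed(51)
  tr <- random_tree(12, mean_bl = 0.3)
  # exit routes from a profile state scale with the alphabet (2(n-1) = 38
  # for amino acids), so maintaining occupancy needs a much larger d/s
  # than the nucleotide case
  sim <- simulate_pairs(tr, coev_params(1, 300, 0.5, 0.5), 1,
                        profile = c("AA", "TT"), alphabet = aa, seed = 3)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  rank <- search_profiles_aa(tr, pc)
  expect_true(all(c("AA", "TT") %in% parse_profile(rank$profile[1], aa)))
})

test_that("end-to-end ML evaluation is deterministic and complete", {
  set.seed(61)
  tr <- random_tree(12)
  sim <- simulate_pairs(tr, coev_params(1, 15, 1, 1), 2,
                        profile = c("AA", "CC"), seed = 8)
  fit1 <- evaluate_pair_ml(tr, sim$alignment, 1, 2)
  fit2 <- evaluate_pair_ml(tr, sim$alignment, 1, 2)
  expect_equal(fit1$delta_aic, fit2$delta_aic)
  expect_equal(fit1$profile, fit2$profile)
  # delta_aic is re-derivable from the stored log-likelihoods
  expect_equal(fit1$delta_aic,
               (2 * fit1$k_indep - 2 * fit1$logL_indep) -
                 (2 * fit1$k_coev - 2 * fit1$logL_coev))
  # errors carry the stage name
  expect_error(evaluate_pair_ml(tr, sim$alignment, 1, 1), "extraction")
})

test_that("fit results serialise to a one-row TSV", {
  set.seed(71)
  tr <- random_tree(8)
  sim <- simulate_pairs(tr, coev_params(1, 10, 1, 1), 1,
                        profile = c("AA", "GG"), seed = 2)
  fit <- evaluate_pair_ml(tr, sim$alignment, 1, 2,
                          config = list(control = list(rank_maxit = 60,
                                                       n_refine = 1)))
  f <- tempfile(fileext = ".tsv")
  write_fit_tsv(fit, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$delta_aic, fit$delta_aic)
  expect_equal(tab$ds_ratio, fit$params$d / fit$params$s)
})
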