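# Metropolis-Hastings sampler and the Tracer log format.

test_that("sampling schedule places records at burnin + k * sample_freq", {
  set.seed(1)
  tr <- random_tree(4)
  sim <- simulate_pairs(tr, coev_params(1, 5, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 1)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  trace <- run_mcmc(tr, pc, iterations = 10000, burnin = 1000,
                    sample_freq = 1000, seed = 5)
  expect_equal(nrow(trace), 9)
  expect_equal(trace$state, seq(2000, 10000, by = 1000))
  expect_error(run_mcmc(tr, pc, iterations = 100, burnin = 200,
                        sample_freq = 10), "invalid schedule")
})

test_that("identical seeds give identical traces", {
  tr <- random_tree(4, mean_bl = 0.5)
  sim <- simulate_pairs(tr, coev_params(1, 5, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 2)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  t1 <- run_mcmc(tr, pc, 2000, burnin = 100, sample_freq = 100, seed = 42)
  t2 <- run_mcmc(tr, pc, 2000, burnin = 100, sample_freq = 100, seed = 42)
  expect_identical(t1, t2)
})

test_that("prior-only sampling recovers the exponential prior", {
  tr <- random_tree(3)
  pc <- toy_pair_data(setNames(c("AA", "CC", "AA"), tr$tip.label))
  trace <- run_mcmc(tr, pc, iterations = 60000, burnin = 2000,
                    sample_freq = 25, seed = 9, use_likelihood = FALSE)
  # sample mean of s within 3 batch-means standard errors of the prior mean
  s <- trace$s
  batches <- tapply(s, rep(seq_len(40), each = length(s) / 40)[seq_along(s)],
                    mean)
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(s) - 10), 3 * se + 1)
  # KS against Exponential(mean 10) on thinned draws
  thin <- s[seq(1, length(s), by = 8)]
  expect_gt(suppressWarnings(ks.test(thin, "pexp", 1 / 10))$p.value, 0.01)
})

test_that("posterior concentrates on d/s > 1 for strongly coevolving data", {
  set.seed(8)
  tr <- random_tree(30)
  sim <- simulate_pairs(tr, coev_params(1, 20, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 13)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  trace <- run_mcmc(tr, pc, iterations = 6000, burnin = 1000,
                    sample_freq = 10, seed = 14)
  expect_gt(mean(trace$ds_ratio > 1), 0.9)
})

test_that("profile neighbour moves preserve validity and reversibility", {
  set.seed(4)
  for (i in 1:20) {
    phi <- random_profile(nt)
    nb <- coevolve:::.profile_neighbours(phi, nt)
    for (phi2 in nb) {
      expect_silent(validate_profile(phi2, nt))
      # reverse reachability
      back <- coevolve:::.profile_neighbours(phi2, nt)
      expect_true(any(vapply(back, identical, TRUE, phi)))
    }
  }
})

test_that("tracer log is tab-delimited numeric with a profile sidecar", {
  tr <- random_tree(4)
  sim <- simulate_pairs(tr, coev_params(1, 5, 1, 1), 1,
                        profile = c("AA", "CC"), seed = 3)
  pc <- extract_pair_column(sim$alignment, tr, 1, 2)
  trace <- run_mcmc(tr, pc, 3000, burnin = 500, sample_freq = 500, seed = 6)
  txt <- write_tracer_log(trace)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1],
               "state\tposterior\tlikelihood\tprior\ts\td\tr1\tr2\tds_ratio")
  expect_equal(length(lines), nrow(trace) + 1)
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(vapply(fields, function(f)
    all(is.finite(as.numeric(f))), TRUE)))
  # file + sidecar
  f <- tempfile(fileext = ".log")
  write_tracer_log(trace, f)
  expect_true(file.exists(f))
  side <- read.delim(paste0(f, ".profiles.tsv"))
  expect_equal(nrow(side), nrow(trace))
  expect_true(all(grepl("^[A-Z]{2}(,[A-Z]{2})+$", side$profile)))
})
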