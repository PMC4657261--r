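# Metropolis-Hastings sampler over (s, d, r1, r2, profile).
#
# Priors: independent Exponential(mean 10) on each rate; uniform over all
# profiles of the alphabet (nucleotides) or over the observation-driven
# candidate set (amino acids). Per iteration one move is picked uniformly
# from five: a log-scale multiplier update of one of the four rates (tuning
# factor 1.5, Jacobian included in the acceptance ratio) or a profile move.
# Profile moves propose uniformly from the neighbour set of the current
# profile -- swap one member's position-2 letter with an unused letter, add
# a member pair, or remove one (size >= 3 only) -- with the |N(phi)|/|N(phi')|
# Hastings correction; for amino acids the proposal is an independence draw
# from the candidate set. The first recorded sample sits at iteration
# burnin + sample_freq, then every sample_freq iterations.

.profile_neighbours <- function(profile, alphabet) {
  n <- alphabet$n
  f <- substr(profile, 1, 1)
  s <- substr(profile, 2, 2)
  un1 <- setdiff(alphabet$letters, f)
  un2 <- setdiff(alphabet$letters, s)
  out <- list()
  canon <- function(tok) tok[order(pair_state_index(tok, alphabet))]
  # swap one member's position-2 letter with an unused position-2 letter
  for (i in seq_along(profile)) for (l in un2) {
    tok <- profile
    tok[i] <- paste0(f[i], l)
    out[[length(out) + 1L]] <- canon(tok)
  }
  # add a pair on unused letters
  if (length(profile) < n) {
    for (a in un1) for (b in un2)
      out[[length(out) + 1L]] <- canon(c(profile, paste0(a, b)))
  }
  # remove a member (keep size >= 2)
  if (length(profile) > 2) {
    for (i in seq_along(profile))
      out[[length(out) + 1L]] <- profile[-i]
  }
  out
}

#' Bayesian evaluation of a pair by Metropolis-Hastings MCMC
#'
#' Samples (s, d, r1, r2, profile) from the posterior given the pair-column
#' data on a fixed tree. See the package vignette for the priors, proposal
#' kernels and schedule conventions. Recommended production settings are
#' 1e6 iterations with burn-in 1000 and sampling frequency 1000.
#'
#' @inheritParams prune_loglik
#' @param iterations Total Metropolis-Hastings iterations (> `burnin`).
#' @param burnin Iterations discarded before sampling starts (>= 0).
#' @param sample_freq Thinning interval (>= 1); states are recorded at
#'   iterations `burnin + sample_freq`, `burnin + 2*sample_freq`, ...
#' @param seed Optional integer seed (sets R's RNG for reproducibility).
#' @param prior_mean Mean of the Exponential prior on each rate.
#' @param tuning Multiplier tuning factor for rate proposals.
#' @param profile_init Optional starting profile (default: random draw for
#'   nucleotides, most frequent candidate for amino acids).
#' @param use_likelihood Internal switch; `FALSE` samples the prior only
#'   (for validation).
#' @param max_candidates Amino-acid candidate cap (see
#'   [search_profiles_aa()]).
#' @return Object of class `coev_trace`: a data.frame with columns `state`
#'   (iteration), `posterior`, `likelihood`, `prior`, `s`, `d`, `r1`, `r2`,
#'   `ds_ratio` and `profile` (string form), plus an `acceptance` attribute.
#' @export
run_mcmc <- function(tree, data, iterations, burnin = 1000,
                     sample_freq = 1000, seed = NULL, prior_mean = 10,
                     tuning = 1.5, profile_init = NULL,
                     use_likelihood = TRUE, max_candidates = 500) {
  if (burnin < 0 || iterations <= burnin || sample_freq < 1)
    stop("invalid schedule: need iterations > burnin >= 0, sample_freq >= 1")
  if (!is.null(seed)) set.seed(seed)
  validate_tree(tree)
  alphabet <- if (inherits(data, "pair_column_data")) data$alphabet
  else coev_alphabet("nucleotide")
  is_nt <- alphabet$n <= 8
  candidates <- NULL
  if (!is_nt) {
    candidates <- .candidate_profiles_aa(data, alphabet, max_candidates)
    if (length(candidates) == 0)
      stop("no valid amino-acid candidate profiles for this pair")
  }
  profile <- if (!is.null(profile_init))
    validate_profile(profile_init, alphabet)
  else if (is_nt) random_profile(alphabet) else candidates[[1]]

  ll_cache <- new.env(parent = emptyenv())
  get_llfun <- function(prof) {
    key <- profile_string(prof)
    if (is.null(ll_cache[[key]]))
      ll_cache[[key]] <- .make_pair_loglik(tree, data, prof, alphabet)
    ll_cache[[key]]
  }
  loglik <- function(th, prof) {
    if (!use_likelihood) return(0)
    get_llfun(prof)(th[1], th[2], th[3], th[4])
  }
  logprior <- function(th) sum(stats::dexp(th, 1 / prior_mean, log = TRUE))

  th <- rep(prior_mean, 4)
  ll <- loglik(th, profile)
  lp <- logprior(th)
  n_rec <- floor((iterations - burnin) / sample_freq)
  rec <- vector("list", n_rec)
  rec_i <- 0L
  accepted <- 0L
  for (it in seq_len(iterations)) {
    move <- sample.int(5L, 1L)
    if (move <= 4L) {
      u <- tuning^stats::runif(1, -1, 1)
      th2 <- th
      th2[move] <- th2[move] * u
      ll2 <- loglik(th2, profile)
      lp2 <- logprior(th2)
      if (is.finite(ll2) &&
          log(stats::runif(1)) < (ll2 + lp2) - (ll + lp) + log(u)) {
        th <- th2; ll <- ll2; lp <- lp2; accepted <- accepted + 1L
      }
    } else {
      if (is_nt) {
        nb <- .profile_neighbours(profile, alphabet)
        prof2 <- nb[[sample.int(length(nb), 1L)]]
        hastings <- log(length(nb)) -
          log(length(.profile_neighbours(prof2, alphabet)))
      } else {
        prof2 <- candidates[[sample.int(length(candidates), 1L)]]
        hastings <- 0
      }
      ll2 <- loglik(th, prof2)
      if (is.finite(ll2) && log(stats::runif(1)) < (ll2 - ll) + hastings) {
        profile <- prof2; ll <- ll2; accepted <- accepted + 1L
      }
    }
    if (it > burnin && (it - burnin) %% sample_freq == 0) {
      rec_i <- rec_i + 1L
      rec[[rec_i]] <- data.frame(
        state = it, posterior = ll + lp, likelihood = ll, prior = lp,
        s = th[1], d = th[2], r1 = th[3], r2 = th[4],
        ds_ratio = th[2] / th[1], profile = profile_string(profile),
        stringsAsFactors = FALSE)
    }
  }
  trace <- do.call(rbind, rec[seq_len(rec_i)])
  attr(trace, "acceptance") <- accepted / iterations
  class(trace) <- c("coev_trace", "data.frame")
  trace
}

#' Write an MCMC trace as a Tracer-readable log
#'
#' Tracer needs purely numeric columns, so the profile column goes to a
#' sidecar file `<file>.profiles.tsv` (columns `state`, `profile`). The log
#' itself is tab-delimited with header
#' `state posterior likelihood prior s d r1 r2 ds_ratio`.
#'
#' @param trace A `coev_trace` from [run_mcmc()].
#' @param file Optional output path; the text is returned (invisibly when
#'   writing to a file).
#' @export
write_tracer_log <- function(trace, file = NULL) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  num_cols <- c("state", "posterior", "likelihood", "prior",
                "s", "d", "r1", "r2", "ds_ratio")
  header <- paste(num_cols, collapse = "\t")
  rows <- apply(as.data.frame(trace)[num_cols], 1, function(r)
    paste(formatC(r, format = "g", digits = 12), collapse = "\t"))
  txt <- paste(c(header, rows), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    utils::write.table(as.data.frame(trace)[c("state", "profile")],
                       paste0(file, ".profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(txt))
  }
  txt
}
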