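# Maximum-likelihood fitting of the Coev rates and profile search.
#
# Rates are optimised in log space by Nelder-Mead inside the box
# [1e-4, 1e3]^4 (out-of-box points are pushed back by a penalty). Starting
# points come from a fixed 3x3 grid over (d/s, r1) with s anchored at 1 and
# r2 = r1; "full" mode runs a local search from every grid point, "fast"
# mode from the best-scoring grid point only. Everything is deterministic:
# same inputs and control give the same fit.

.rate_bounds <- log(c(1e-4, 1e3))

.default_control <- function(control = list()) {
  utils::modifyList(list(
    mode = "full",        # "full" = all 9 starts, "fast" = best start only
    maxit = 400,
    rank_maxit = 150,     # budget of the per-profile ranking phase
    n_refine = 3,         # top profiles refitted in full mode
    reltol = 1e-9,
    grid_ratios = c(0.5, 2, 20),
    grid_r = c(0.2, 1, 5)
  ), control)
}

# Closure returning the log-likelihood as a function of (s, d, r1, r2),
# with the state space (reduced by exact lumping when possible), masks and
# postorder traversal precomputed. Root distribution is the stationary
# distribution of the current Q ("the model being scored").
.make_pair_loglik <- function(tree, data, profile, alphabet, reduce = TRUE) {
  alphabet <- coev_alphabet(alphabet)
  states <- if (inherits(data, "pair_column_data")) data$states else data
  tip_tokens <- states[tree$tip.label]
  if (anyNA(tip_tokens))
    stop("data missing for leaves: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  space <- if (reduce)
    reduced_state_space(unique(tip_tokens), profile, alphabet)
  else .full_state_space(alphabet, profile)
  tip_idx <- match(tip_tokens, space$tokens)
  po <- stats::reorder(tree, "postorder")
  edge <- matrix(as.integer(po$edge), ncol = 2)
  elen <- as.numeric(po$edge.length)
  n_tip <- length(tree$tip.label)
  root <- as.integer(n_tip + 1L)
  function(s, d, r1, r2) {
    Q <- .space_Q(space, s, d, r1, r2)
    # empty root_dist: the kernel solves for the stationary distribution
    .prune_loglik_cpp(unclass(Q), edge, elen, as.integer(tip_idx),
                      numeric(0), n_tip, root)
  }
}

# Minimise -loglik over log-rates with a soft box penalty.
.fit_rates <- function(llfun, free = c("s", "d", "r1", "r2"),
                       control = .default_control(), maxit = control$maxit,
                       mode = control$mode) {
  nms <- c("s", "d", "r1", "r2")
  fixed <- setdiff(nms, free)
  obj <- function(par) {
    if (any(par < .rate_bounds[1]) || any(par > .rate_bounds[2]))
      return(1e9 + sum(pmax(0, par - .rate_bounds[2]) +
                         pmax(0, .rate_bounds[1] - par)) * 1e6)
    th <- exp(par)
    full <- stats::setNames(rep(1, 4), nms)
    full[free] <- th
    if ("d" %in% fixed) full["d"] <- full["s"]       # tied null, if ever used
    ll <- llfun(full["s"], full["d"], full["r1"], full["r2"])
    if (!is.finite(ll)) return(1e9)
    -ll
  }
  starts <- list()
  if (identical(free, c("r1", "r2"))) {
    for (r in control$grid_r) starts[[length(starts) + 1L]] <- log(c(r, r))
  } else {
    for (ratio in control$grid_ratios) for (r in control$grid_r)
      starts[[length(starts) + 1L]] <- log(c(1, ratio, r, r))[
        match(free, nms)]
  }
  vals <- vapply(starts, obj, 0)
  run_from <- if (identical(mode, "fast")) which.min(vals) else seq_along(starts)
  best <- NULL
  for (i in run_from) {
    fit <- stats::optim(starts[[i]], obj, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       reltol = control$reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- exp(best$par)
  names(th) <- free
  flagged <- best$convergence != 0 ||
    any(th < 2e-4) || any(th > 0.9e3)
  list(theta = th, logL = -best$value, convergence = best$convergence,
       flagged = flagged)
}

#' Maximum-likelihood rates for a fixed profile
#'
#' Maximises the pruning log-likelihood over (s, d, r1, r2) in the box
#' `[1e-4, 1e3]^4` by Nelder-Mead in log space, started from a fixed 3x3
#' grid over (d/s, r1) with s = 1 and r2 = r1. Deterministic given
#' `control`. Note the likelihood only identifies rates relative to the
#' branch-length unit (doubling all branch lengths and halving all rates
#' leaves it unchanged); the ratio d/s is scale-free.
#'
#' @inheritParams prune_loglik
#' @param profile The coevolution profile to condition on.
#' @param alphabet Alphabet of the data (defaults to the data's own tag).
#' @param control List of optimiser settings, see source; `mode` is
#'   `"full"` (local search from all 9 grid starts) or `"fast"` (best
#'   start only), `maxit` the Nelder-Mead iteration cap.
#' @return List with `params` (a [coev_params()]), `logL`, `convergence`
#'   (0 = converged) and `flagged` (`TRUE` when the optimum sits at the
#'   box boundary or the optimiser did not converge).
#' @export
optimize_rates <- function(tree, data, profile, alphabet = NULL,
                           control = list()) {
  control <- .default_control(control)
  if (is.null(alphabet) && inherits(data, "pair_column_data"))
    alphabet <- data$alphabet
  alphabet <- coev_alphabet(alphabet)
  profile <- validate_profile(profile, alphabet)
  llfun <- .make_pair_loglik(tree, data, profile, alphabet)
  fit <- .fit_rates(llfun, control = control)
  list(params = coev_params(fit$theta["s"], fit$theta["d"],
                            fit$theta["r1"], fit$theta["r2"]),
       logL = fit$logL, convergence = fit$convergence,
       flagged = fit$flagged)
}

#' Maximum-likelihood fit of the independent (null) model
#'
#' Fits r1 and r2 of [build_independent_Q()] by the same bounded
#' Nelder-Mead scheme (3 starts with r1 = r2).
#'
#' @inheritParams optimize_rates
#' @return List with `r1`, `r2`, `logL`, `convergence`, `flagged`.
#' @export
fit_independent <- function(tree, data, alphabet = NULL, control = list()) {
  control <- .default_control(control)
  if (is.null(alphabet) && inherits(data, "pair_column_data"))
    alphabet <- data$alphabet
  alphabet <- coev_alphabet(alphabet)
  llfun <- .make_pair_loglik(tree, data, NULL, alphabet)
  fit <- .fit_rates(llfun, free = c("r1", "r2"), control = control)
  list(r1 = unname(fit$theta["r1"]), r2 = unname(fit$theta["r2"]),
       logL = fit$logL, convergence = fit$convergence, flagged = fit$flagged)
}

.rank_profiles <- function(tree, data, profiles, alphabet, control) {
  res <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    llfun <- .make_pair_loglik(tree, data, profiles[[i]], alphabet)
    fit <- .fit_rates(llfun, control = control,
                      maxit = control$rank_maxit, mode = "fast")
    res[[i]] <- c(logL = fit$logL, fit$theta)
  }
  logL <- vapply(res, function(x) x[["logL"]], 0)
  sizes <- lengths(profiles)
  ord <- order(-logL, sizes, seq_along(profiles))
  out <- data.frame(
    profile = vapply(profiles, profile_string, "")[ord],
    size = sizes[ord],
    logL = logL[ord],
    s = vapply(res, function(x) x[["s"]], 0)[ord],
    d = vapply(res, function(x) x[["d"]], 0)[ord],
    r1 = vapply(res, function(x) x[["r1"]], 0)[ord],
    r2 = vapply(res, function(x) x[["r2"]], 0)[ord],
    stringsAsFactors = FALSE)
  # refine the top profiles with the full multi-start budget
  n_ref <- min(control$n_refine, nrow(out))
  for (i in seq_len(n_ref)) {
    prof <- parse_profile(out$profile[i], alphabet)
    fit <- optimize_rates(tree, data, prof, alphabet,
                          control = utils::modifyList(control,
                                                      list(mode = "full")))
    if (fit$logL >= out$logL[i]) {
      out$logL[i] <- fit$logL
      out$s[i] <- fit$params$s; out$d[i] <- fit$params$d
      out$r1[i] <- fit$params$r1; out$r2[i] <- fit$params$r2
    }
  }
  ord2 <- order(-out$logL, out$size, seq_len(nrow(out)))
  out[ord2, , drop = FALSE]
}

#' Exhaustive nucleotide profile search
#'
#' Runs [optimize_rates()] for every one of the 192 nucleotide profiles and
#' ranks them by log-likelihood (ties: smaller profile first, then
#' enumeration order). The per-profile search uses the fast single-start
#' budget; the top-ranked profiles are then refitted with the full 3x3
#' multi-start before the final ranking.
#'
#' @inheritParams optimize_rates
#' @return A data.frame with one row per profile: `profile` (string form),
#'   `size`, `logL`, `s`, `d`, `r1`, `r2`, best first.
#' @export
search_profiles_nt <- function(tree, data, control = list()) {
  control <- .default_control(control)
  alphabet <- coev_alphabet("nucleotide")
  profiles <- enumerate_profiles(alphabet)
  .rank_profiles(tree, data, profiles, alphabet, control)
}

# Observation-driven amino-acid candidate profiles: injective subsets of the
# pair-states seen at the leaves, prioritised by member frequency.
.candidate_profiles_aa <- function(data, alphabet, max_candidates = 500,
                                   k_max = 6) {
  states <- if (inherits(data, "pair_column_data")) data$states else data
  tab <- sort(table(states), decreasing = TRUE)
  toks <- names(tab)
  # keep the enumeration tractable: only the most frequent distinct pairs
  toks <- toks[seq_len(min(length(toks), 12))]
  freq <- as.numeric(tab[toks])
  cands <- list()
  prio <- numeric(0)
  key <- character(0)
  for (k in 2:min(k_max, length(toks))) {
    if (length(toks) < k) break
    sets <- utils::combn(length(toks), k)
    for (cix in seq_len(ncol(sets))) {
      sel <- sets[, cix]
      tok <- toks[sel]
      ok <- !anyDuplicated(substr(tok, 1, 1)) &&
        !anyDuplicated(substr(tok, 2, 2))
      if (!ok) next
      prof <- tok[order(pair_state_index(tok, alphabet))]
      cands[[length(cands) + 1L]] <- prof
      prio <- c(prio, sum(freq[sel]))
      key <- c(key, profile_string(prof))
    }
  }
  if (length(cands) == 0) return(list())
  ord <- order(-prio, key)
  cands[ord][seq_len(min(length(cands), max_candidates))]
}

#' Heuristic amino-acid profile search
#'
#' The amino-acid profile space (~1e21 profiles) cannot be enumerated;
#' candidates are instead built from the pair-states actually observed at
#' the leaves: all injective subsets of the observed pairs of size 2 up to
#' `k_max`, prioritised by how frequently their members occur, capped at
#' `max_candidates`, then ranked exactly as in the nucleotide search.
#'
#' @inheritParams optimize_rates
#' @param max_candidates Cap on the number of candidate profiles (default
#'   500); priority is deterministic (most frequent observed pairs first).
#' @param k_max Largest candidate profile size considered.
#' @return As [search_profiles_nt()]. If no two observed pair-states are
#'   injective-compatible the returned data.frame has zero rows and an
#'   attribute `"explanation"`.
#' @export
search_profiles_aa <- function(tree, data, max_candidates = 500, k_max = 6,
                               control = list()) {
  control <- .default_control(control)
  alphabet <- if (inherits(data, "pair_column_data")) data$alphabet
  else coev_alphabet("aa")
  cands <- .candidate_profiles_aa(data, alphabet, max_candidates, k_max)
  if (length(cands) == 0) {
    out <- data.frame(profile = character(0), size = integer(0),
                      logL = numeric(0), s = numeric(0), d = numeric(0),
                      r1 = numeric(0), r2 = numeric(0))
    attr(out, "explanation") <-
      "no valid profile: fewer than 2 injective-compatible observed pair-states"
    return(out)
  }
  .rank_profiles(tree, data, cands, alphabet, control)
}

#' Full maximum-likelihood evaluation of a pair of positions
#'
#' The complete pipeline of the ML path: curate the alignment, map the
#' user's (original-coordinate) positions, extract the pair column, search
#' profiles (exhaustively for nucleotides, heuristically for amino acids),
#' fit the independent null and report the \eqn{\Delta AIC}.
#'
#' @param tree A rooted binary [ape::phylo] tree.
#' @param alignment A [coev_alignment()], uncurated (curation is applied
#'   here; positions refer to the original columns).
#' @param pos1,pos2 1-based positions on the original alignment.
#' @param config Optional list: `k_coev`, `k_indep` (AIC parameter counts,
#'   defaults 4 and 3), `max_candidates`, `k_max` (amino-acid search), and
#'   any [optimize_rates()] `control` entries under `control`.
#' @return Object of class `coev_fit`: list with `pos1`, `pos2`, `params`
#'   (fitted [coev_params()]), `profile`, `logL_coev`, `indep` (fitted null
#'   rates), `logL_indep`, `delta_aic`, `ranking` (the profile search
#'   table) and `curation` (the report).
#' @export
evaluate_pair_ml <- function(tree, alignment, pos1, pos2, config = list()) {
  cfg <- utils::modifyList(list(k_coev = 4, k_indep = 3,
                                max_candidates = 500, k_max = 6,
                                control = list()), config)
  cur <- tryCatch(curate_alignment(alignment),
                  error = function(e) stop("curation: ", conditionMessage(e)))
  data <- tryCatch(
    extract_pair_column(cur$alignment, tree, pos1, pos2, cur$report),
    error = function(e) stop("extraction: ", conditionMessage(e)))
  is_nt <- identical(alignment$alphabet$label, "nucleotide")
  ranking <- tryCatch({
    if (is_nt) search_profiles_nt(tree, data, control = cfg$control)
    else search_profiles_aa(tree, data, max_candidates = cfg$max_candidates,
                            k_max = cfg$k_max, control = cfg$control)
  }, error = function(e) stop("profile search: ", conditionMessage(e)))
  if (nrow(ranking) == 0)
    stop("profile search: ", attr(ranking, "explanation"))
  indep <- tryCatch(fit_independent(tree, data, control = cfg$control),
                    error = function(e) stop("independent fit: ",
                                             conditionMessage(e)))
  top <- ranking[1, ]
  structure(list(
    pos1 = pos1, pos2 = pos2,
    params = coev_params(top$s, top$d, top$r1, top$r2),
    profile = parse_profile(top$profile, alignment$alphabet),
    logL_coev = top$logL,
    indep = list(r1 = indep$r1, r2 = indep$r2),
    logL_indep = indep$logL,
    delta_aic = delta_aic(top$logL, indep$logL,
                          k_coev = cfg$k_coev, k_indep = cfg$k_indep),
    k_coev = cfg$k_coev, k_indep = cfg$k_indep,
    ranking = ranking, curation = cur$report),
    class = "coev_fit")
}

#' @export
print.coev_fit <- function(x, ...) {
  cat("Coev ML fit for positions (", x$pos1, ", ", x$pos2, ")\n", sep = "")
  cat("  best profile : ", profile_string(x$profile), "\n", sep = "")
  cat(sprintf("  s = %.4g  d = %.4g  r1 = %.4g  r2 = %.4g  (d/s = %.3g)\n",
              x$params$s, x$params$d, x$params$r1, x$params$r2,
              x$params$d / x$params$s))
  cat(sprintf("  logL(Coev) = %.4f   logL(indep) = %.4f\n",
              x$logL_coev, x$logL_indep))
  cat(sprintf("  delta AIC = %.4f  (positive favours coevolution)\n",
              x$delta_aic))
  invisible(x)
}

#' Write a fit result as a one-row TSV
#'
#' Columns: pos1, pos2, s, d, r1, r2, ds_ratio, profile, logL_coev,
#' logL_indep, delta_aic.
#'
#' @param fit A `coev_fit` from [evaluate_pair_ml()].
#' @param file Output path.
#' @export
write_fit_tsv <- function(fit, file) {
  df <- data.frame(pos1 = fit$pos1, pos2 = fit$pos2,
                   s = fit$params$s, d = fit$params$d,
                   r1 = fit$params$r1, r2 = fit$params$r2,
                   ds_ratio = fit$params$d / fit$params$s,
                   profile = profile_string(fit$profile),
                   logL_coev = fit$logL_coev, logL_indep = fit$logL_indep,
                   delta_aic = fit$delta_aic)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
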