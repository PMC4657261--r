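# Desk-scale scripted experiments: the subtree-swap design relating
# double-substitution lineages to delta-AIC, and the d/s sweep of the
# proportion of simulated in-profile end states.

#' Random rooted binary tree with Normal branch lengths
#'
#' Topology from recursive random splitting (via [ape::rtree()]); branch
#' lengths drawn from Normal(`mean_bl`, `mean_bl / 5`), clamped below at
#' `1e-6`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mean_bl Mean branch length (default 0.5).
#' @param sd_bl Branch-length standard deviation (default `mean_bl / 5`).
#' @return A rooted binary [ape::phylo] tree with `2 * n_leaves - 2` edges.
#' @export
random_tree <- function(n_leaves, mean_bl = 0.5, sd_bl = mean_bl / 5) {
  stopifnot(n_leaves >= 2)
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  tree$edge.length <- pmax(stats::rnorm(nrow(tree$edge), mean_bl, sd_bl),
                           1e-6)
  validate_tree(tree)
}

# join two subtrees under a new root with fresh connecting branch lengths
.join_subtrees <- function(t1, t2, mean_bl = 0.5) {
  b <- pmax(stats::rnorm(2, mean_bl, mean_bl / 5), 1e-6)
  nk1 <- sub(";$", "", ape::write.tree(t1))
  nk2 <- sub(";$", "", ape::write.tree(t2))
  parse_newick(sprintf("(%s:%g,%s:%g);", nk1, b[1], nk2, b[2]))
}

# Fitch parsimony count of change edges for a two-state leaf colouring
.double_substitution_count <- function(tree, combo_of_leaf) {
  x <- matrix(combo_of_leaf[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, NULL))
  dat <- phangorn::phyDat(x, type = "USER", levels = unique(combo_of_leaf))
  phangorn::parsimony(tree, dat)
}

#' Subtree-swap experiment: double substitutions versus delta-AIC
#'
#' Builds a tree of two random subtrees of `m_per_subtree` leaves each,
#' assigns one pair-state combination to all leaves of the first subtree
#' and another (differing at both positions) to the second, then repeatedly
#' exchanges the combinations of one leaf from each side. After each swap
#' the number of lineages with double substitutions (the Fitch parsimony
#' change count of the two-colouring) and the ML \eqn{\Delta AIC} of the
#' two-column data are recorded. Under the model, \eqn{\Delta AIC} grows
#' with the number of double-substitution lineages. Swapped leaves are
#' chosen cyclically, so with more swaps than leaves per subtree later
#' steps undo earlier ones; the (count, delta-AIC) pairs remain valid.
#'
#' @param m_per_subtree Leaves per subtree (>= 2; default 10).
#' @param n_swaps Number of swap steps after the initial state (default 20).
#' @param combos Character vector of two pair-state tokens differing at
#'   both positions; defaults to `c("AA", "TT")` for both alphabets.
#' @param alphabet `"nucleotide"` or `"aa"`.
#' @param seed Optional integer seed.
#' @param mean_bl Mean branch length of the random tree.
#' @param config Passed to [evaluate_pair_ml()].
#' @return A data.frame with one row per step: `swap_count`,
#'   `double_substitution_lineages`, `delta_aic`.
#' @export
subtree_swap_experiment <- function(m_per_subtree = 10, n_swaps = 20,
                                    combos = c("AA", "TT"),
                                    alphabet = "nucleotide", seed = NULL,
                                    mean_bl = 0.5, config = list()) {
  stopifnot(m_per_subtree >= 2)
  alphabet <- coev_alphabet(alphabet)
  if (length(combos) != 2 ||
      substr(combos[1], 1, 1) == substr(combos[2], 1, 1) ||
      substr(combos[1], 2, 2) == substr(combos[2], 2, 2))
    stop("combos must be two pair-states differing at both positions")
  pair_state_index(combos, alphabet)  # validates letters
  if (!is.null(seed)) set.seed(seed)
  t1 <- random_tree(m_per_subtree, mean_bl)
  t2 <- random_tree(m_per_subtree, mean_bl)
  t1$tip.label <- paste0("s1_", seq_len(m_per_subtree))
  t2$tip.label <- paste0("s2_", seq_len(m_per_subtree))
  tree <- .join_subtrees(t1, t2, mean_bl)
  combo_of <- stats::setNames(
    rep(combos, each = m_per_subtree),
    c(t1$tip.label, t2$tip.label))
  out <- vector("list", n_swaps + 1)
  for (step in 0:n_swaps) {
    if (step > 0) {
      i <- ((step - 1) %% m_per_subtree) + 1
      a <- paste0("s1_", i); b <- paste0("s2_", i)
      tmp <- combo_of[a]; combo_of[a] <- combo_of[b]; combo_of[b] <- tmp
    }
    seqs <- cbind(substr(combo_of, 1, 1), substr(combo_of, 2, 2))
    rownames(seqs) <- names(combo_of)
    aln <- coev_alignment(seqs, alphabet)
    fit <- evaluate_pair_ml(tree, aln, 1, 2, config = config)
    out[[step + 1]] <- data.frame(
      swap_count = step,
      double_substitution_lineages =
        .double_substitution_count(tree, combo_of),
      delta_aic = fit$delta_aic)
  }
  do.call(rbind, out)
}

#' d/s sweep: proportion of simulated end states inside the profile
#'
#' For every combination of branch length and d/s ratio, and `n_reps`
#' replicates each: draw r1 and r2 uniformly from the range 1 to 100, set s = 1 and
#' d = ratio, build the Coev matrix for the profile (default `{AA, CC}`),
#' draw `n_draws` root states from its frequency vector, evolve each along
#' a single branch via \eqn{P(t)}, and record the fraction of end states
#' that belong to the profile. Larger d/s concentrates end states in the
#' profile at every branch length.
#'
#' @param branch_lengths Branch lengths to test (default 0.1, 0.5, 1, 5).
#' @param ds_ratios d/s ratios to test (default 1, 5, 20, 100).
#' @param n_reps Replicates per cell (default 20).
#' @param n_draws Root/end-state draws per replicate (default 1000).
#' @param profile Profile tracked (default `c("AA", "CC")`).
#' @param alphabet Alphabet (default nucleotide).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `branch_length`, `ds_ratio`,
#'   `replicate`, `r1`, `r2`, `proportion_in_profile`.
#' @export
ds_sweep_experiment <- function(branch_lengths = c(0.1, 0.5, 1, 5),
                                ds_ratios = c(1, 5, 20, 100),
                                n_reps = 20, n_draws = 1000,
                                profile = c("AA", "CC"),
                                alphabet = "nucleotide", seed = NULL) {
  stopifnot(all(branch_lengths > 0), all(ds_ratios > 0))
  alphabet <- coev_alphabet(alphabet)
  profile <- validate_profile(profile, alphabet)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (bl in branch_lengths) for (ratio in ds_ratios) {
    for (rep_i in seq_len(n_reps)) {
      r1 <- stats::runif(1, 1, 100)
      r2 <- stats::runif(1, 1, 100)
      Q <- build_coev_Q(coev_params(1, ratio, r1, r2), profile, alphabet)
      pi <- stationary_distribution(Q)
      P <- transition_matrix(Q, bl)
      roots <- sample.int(nrow(Q), n_draws, replace = TRUE, prob = pi)
      ends <- integer(n_draws)
      for (rs in unique(roots)) {
        sel <- roots == rs
        ends[sel] <- sample.int(nrow(Q), sum(sel), replace = TRUE,
                                prob = P[rs, ])
      }
      rows[[length(rows) + 1]] <- data.frame(
        branch_length = bl, ds_ratio = ratio, replicate = rep_i,
        r1 = r1, r2 = r2,
        proportion_in_profile =
          mean(rownames(Q)[ends] %in% profile))
    }
  }
  do.call(rbind, rows)
}
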