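# Pair-column likelihood under a coupled rate matrix on a fixed tree.

#' Assemble the pair-states observed at the leaves for two columns
#'
#' @param alignment A [coev_alignment()] (curated if `report` is `NULL`).
#' @param tree An [ape::phylo] tree whose leaf set must equal the alignment
#'   taxa exactly.
#' @param pos1,pos2 1-based column positions. If `report` is supplied they
#'   are positions on the original (pre-curation) alignment and are mapped
#'   through it; otherwise they index `alignment` directly.
#' @param report Optional `curation_report` from [curate_alignment()].
#' @return Object of class `pair_column_data`: list with `states` (named
#'   character vector, leaf label -> pair-state token), `pos1`, `pos2` (the
#'   positions as given) and `alphabet`.
#' @export
extract_pair_column <- function(alignment, tree, pos1, pos2, report = NULL) {
  stopifnot(inherits(alignment, "coev_alignment"))
  validate_tree(tree)
  if (pos1 == pos2) stop("pos1 and pos2 must differ (got ", pos1, " twice)")
  missing_in_aln <- setdiff(tree$tip.label, alignment$taxa)
  extra_in_aln <- setdiff(alignment$taxa, tree$tip.label)
  if (length(missing_in_aln) || length(extra_in_aln))
    stop("alignment taxa and tree leaves must match exactly; ",
         if (length(missing_in_aln))
           paste0("missing from alignment: ",
                  paste(missing_in_aln, collapse = ", "), "; ") else "",
         if (length(extra_in_aln))
           paste0("not in tree: ", paste(extra_in_aln, collapse = ", ")) else "")
  i1 <- if (is.null(report)) pos1 else map_position(report, pos1)
  i2 <- if (is.null(report)) pos2 else map_position(report, pos2)
  if (i1 < 1 || i1 > ncol(alignment$seqs) || i2 < 1 || i2 > ncol(alignment$seqs))
    stop("position out of range: alignment has ", ncol(alignment$seqs),
         " columns")
  states <- paste0(alignment$seqs[, i1], alignment$seqs[, i2])
  names(states) <- alignment$taxa
  structure(list(states = states, pos1 = pos1, pos2 = pos2,
                 alphabet = alignment$alphabet),
            class = "pair_column_data")
}

#' Pair-column log-likelihood by Felsenstein pruning
#'
#' Propagates partial likelihoods from the leaves to the root (each leaf
#' carries an indicator vector on its observed pair-state; each edge applies
#' \eqn{P(t) = e^{Qt}}) and sums over root states weighted by `root_dist`.
#' The default root distribution is the stationary distribution of `Q`,
#' mirroring the simulator's root draw.
#'
#' @param tree A rooted binary [ape::phylo] tree with branch lengths.
#' @param data A [extract_pair_column()] result (or a named character vector
#'   of pair-state tokens).
#' @param Q A rate matrix whose rownames cover the observed pair-states.
#' @param root_dist Optional probability vector over the states of `Q`.
#' @return The log-likelihood (a single number; `-Inf` if the data are
#'   impossible under the model).
#' @export
prune_loglik <- function(tree, data, Q, root_dist = NULL) {
  validate_tree(tree)
  states <- if (inherits(data, "pair_column_data")) data$states else data
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  if (abs(sum(root_dist) - 1) > 1e-8)
    stop("root_dist must sum to 1")
  tip_tokens <- states[tree$tip.label]
  if (anyNA(tip_tokens))
    stop("data missing for leaves: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  tip_idx <- match(tip_tokens, rownames(Q))
  if (anyNA(tip_idx))
    stop("observed pair-states absent from the state space: ",
         paste(unique(tip_tokens[is.na(tip_idx)]), collapse = ", "))
  po <- stats::reorder(tree, "postorder")
  .prune_loglik_cpp(unclass(Q),
                    matrix(as.integer(po$edge), ncol = 2),
                    as.numeric(po$edge.length),
                    as.integer(tip_idx),
                    as.numeric(root_dist),
                    length(tree$tip.label),
                    as.integer(length(tree$tip.label) + 1L))
}

#' Brute-force pair-column log-likelihood (test oracle)
#'
#' Sums explicitly over every assignment of states to the internal nodes:
#' \eqn{\sum_a \pi(a_{root}) \prod_e P_e(a_{parent}, a_{child})}, with each
#' edge's transition matrix computed by [transition_matrix()] (Pade
#' scaling-and-squaring). Exponential in the number of internal nodes, so
#' restricted to trees with at most 6 leaves; exists as an independent
#' cross-check of [prune_loglik()].
#'
#' @inheritParams prune_loglik
#' @return Log-likelihood.
#' @export
brute_force_loglik <- function(tree, data, Q, root_dist = NULL) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip > 6)
    stop("brute-force enumeration is limited to trees with <= 6 leaves")
  states <- if (inherits(data, "pair_column_data")) data$states else data
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  m <- nrow(Q)
  tip_idx <- match(states[tree$tip.label], rownames(Q))
  n_internal <- tree$Nnode
  internal_ids <- n_tip + seq_len(n_internal)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n_internal)))
  assign_of <- function(node) {
    if (node <= n_tip) rep(tip_idx[node], nrow(grid))
    else grid[, node - n_tip]
  }
  root <- n_tip + 1L
  lik <- root_dist[grid[, 1]]  # root is the first internal node in ape
  for (e in seq_len(nrow(tree$edge))) {
    P <- transition_matrix(Q, tree$edge.length[e])
    pa <- assign_of(tree$edge[e, 1])
    ch <- assign_of(tree$edge[e, 2])
    lik <- lik * P[cbind(pa, ch)]
  }
  log(sum(lik))
}

#' AIC difference between the independent and Coev fits
#'
#' \eqn{\Delta AIC = AIC_{indep} - AIC_{Coev}} with \eqn{AIC = 2k - 2\log L};
#' positive values favour the coevolution model, and the larger the value the
#' stronger the support. Default parameter counts are 4 for Coev (s, d, r1,
#' r2; the discrete profile is treated as model structure, not penalised) and
#' 3 for the independent model.
#'
#' @param logL_coev,logL_indep Maximised log-likelihoods.
#' @param k_coev,k_indep Parameter counts (defaults 4 and 3).
#' @return The \eqn{\Delta AIC} value.
#' @examples
#' delta_aic(-100, -110)  # 18
#' @export
delta_aic <- function(logL_coev, logL_indep, k_coev = 4, k_indep = 3) {
  stopifnot(k_coev > 0, k_indep > 0)
  (2 * k_indep - 2 * logL_indep) - (2 * k_coev - 2 * logL_coev)
}
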