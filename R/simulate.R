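# Simulation of coevolving pairs along a tree under the Coev model.
#
# A root pair-state is drawn from the stationary distribution of Q and
# evolved pre-order down every branch, either by drawing the child state
# from the corresponding row of P(t) = exp(Qt) ("expm" mode) or by
# event-driven Gillespie sampling of the embedded jump chain with
# exponential waiting times ("gillespie" mode, the default). Both sample
# the same CTMC.

#' Draw a root pair-state from the frequency vector of Q
#'
#' @param Q A rate matrix.
#' @return A pair-state token, drawn from [stationary_distribution()]`(Q)`.
#' @export
draw_root_state <- function(Q) {
  pi <- stationary_distribution(Q)
  sample(rownames(Q), 1, prob = pi)
}

#' Evolve a state along one branch via the transition matrix
#'
#' Draws the end state from row `state` of \eqn{P(t) = e^{Qt}}.
#'
#' @param state Starting pair-state token.
#' @param Q A rate matrix.
#' @param t Branch length (>= 0).
#' @return The end pair-state token.
#' @export
evolve_branch_expm <- function(state, Q, t) {
  P <- transition_matrix(Q, t)
  sample(colnames(Q), 1, prob = P[state, ])
}

#' Evolve a state along one branch by Gillespie simulation
#'
#' Waiting times between substitutions are Exponential with rate
#' \eqn{-Q[i,i]}; when a substitution occurs the arrival state is drawn
#' from the jump-chain row \eqn{Q[i,j]/(-Q[i,i])}. Events accumulate until
#' the branch length is exhausted.
#'
#' @inheritParams evolve_branch_expm
#' @return The end pair-state token.
#' @export
evolve_branch_gillespie <- function(state, Q, t) {
  if (t < 0) stop("invalid argument: branch length t must be >= 0")
  tokens <- rownames(Q)
  i <- match(state, tokens)
  if (is.na(i)) stop("unknown state: ", state)
  time <- 0
  repeat {
    rate <- -Q[i, i]
    if (rate <= 0) break                      # absorbing (cannot happen here)
    time <- time + stats::rexp(1, rate)
    if (time > t) break
    p <- Q[i, ]
    p[i] <- 0
    i <- sample.int(length(tokens), 1, prob = p / rate)
  }
  tokens[i]
}

#' Simulate coevolving pairs of positions along a tree
#'
#' Simulates `n_pairs` pairs of columns under the Coev model, all sharing
#' one coevolution profile (drawn by [random_profile()] when not supplied).
#' Each pair independently draws a root state from the stationary
#' distribution of Q and evolves it pre-order down the tree; pair `i`
#' occupies alignment columns `2i - 1` and `2i`.
#'
#' @param tree A rooted binary [ape::phylo] tree with branch lengths.
#' @param params A [coev_params()].
#' @param n_pairs Number of pairs to simulate (>= 1).
#' @param profile Optional profile; default a shared random draw.
#' @param alphabet Alphabet of the simulation (default nucleotide).
#' @param seed Optional integer seed.
#' @param mode `"gillespie"` (default) or `"expm"`.
#' @return Object of class `coev_sim`: list with `alignment` (a
#'   [coev_alignment()] of the tree's leaves, `2 * n_pairs` columns),
#'   `profile`, `params`, `root_states` (per pair), `mode`, `seed`.
#' @export
simulate_pairs <- function(tree, params, n_pairs, profile = NULL,
                           alphabet = "nucleotide", seed = NULL,
                           mode = c("gillespie", "expm")) {
  mode <- match.arg(mode)
  validate_tree(tree)
  params <- .as_params(params)
  alphabet <- coev_alphabet(alphabet)
  if (!is.numeric(n_pairs) || n_pairs < 1 || n_pairs != floor(n_pairs))
    stop("n_pairs must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile)) profile <- random_profile(alphabet)
  else profile <- validate_profile(profile, alphabet)
  Q <- build_coev_Q(params, profile, alphabet)
  pi <- stationary_distribution(Q)
  tokens <- rownames(Q)
  n_tip <- length(tree$tip.label)
  # pre-order traversal; cache P(t) per edge for expm mode
  edges <- stats::reorder(tree, "cladewise")$edge
  elens <- stats::reorder(tree, "cladewise")$edge.length
  P_cache <- if (mode == "expm")
    lapply(elens, function(t) transition_matrix(Q, t)) else NULL
  n_node <- n_tip + tree$Nnode
  leaf_states <- matrix("", n_tip, n_pairs)
  root_states <- character(n_pairs)
  for (p in seq_len(n_pairs)) {
    node_state <- character(n_node)
    root <- n_tip + 1L
    node_state[root] <- sample(tokens, 1, prob = pi)
    root_states[p] <- node_state[root]
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      node_state[child] <- if (mode == "expm") {
        sample(tokens, 1, prob = P_cache[[e]][node_state[parent], ])
      } else {
        evolve_branch_gillespie(node_state[parent], Q, elens[e])
      }
    }
    leaf_states[, p] <- node_state[seq_len(n_tip)]
  }
  seqs <- matrix("", n_tip, 2 * n_pairs,
                 dimnames = list(tree$tip.label, NULL))
  seqs[, seq(1, 2 * n_pairs, by = 2)] <- substr(leaf_states, 1, 1)
  seqs[, seq(2, 2 * n_pairs, by = 2)] <- substr(leaf_states, 2, 2)
  structure(list(alignment = coev_alignment(seqs, alphabet),
                 profile = profile, params = params,
                 root_states = root_states, mode = mode, seed = seed),
            class = "coev_sim")
}

#' @export
print.coev_sim <- function(x, ...) {
  cat("coev_sim: ", length(x$root_states), " pairs on ",
      length(x$alignment$taxa), " leaves (mode ", x$mode, ")\n", sep = "")
  cat("  shared profile: ", profile_string(x$profile), "\n", sep = "")
  cat(sprintf("  s = %.4g d = %.4g r1 = %.4g r2 = %.4g\n",
              x$params$s, x$params$d, x$params$r1, x$params$r2))
  invisible(x)
}
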