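# The Coev instantaneous rate matrix on the coupled pair-state space.
#
# For states i != j the off-diagonal entry is
#   0   if i and j differ at both positions,
#   s   if i is in the profile and j is not   (leaving the profile),
#   d   if i is not in the profile and j is   (entering the profile),
#   r1  if neither is in the profile and they differ at position 1,
#   r2  if neither is in the profile and they differ at position 2.
# Two profile members always differ at both positions, so the first rule
# covers profile-to-profile moves. The diagonal makes rows sum to zero.
# No normalisation to one expected substitution per unit time is applied:
# branch lengths are read in Q's natural time units (simulator and evaluator
# share the convention, and d/s is scale-free).

#' Rate parameters of the Coev model
#'
#' @param s Rate of substitutions leaving the profile (> 0).
#' @param d Rate of substitutions entering the profile (> 0); `d/s` measures
#'   the strength of coevolution (`d/s = 1` means none).
#' @param r1 Rate of single position-1 substitutions outside the profile.
#' @param r2 Rate of single position-2 substitutions outside the profile.
#' @return A list of class `coev_params`.
#' @export
coev_params <- function(s, d, r1, r2) {
  p <- c(s = s, d = d, r1 = r1, r2 = r2)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all rates (s, d, r1, r2) must be strictly positive and finite")
  structure(as.list(p), class = "coev_params")
}

.as_params <- function(params) {
  if (inherits(params, "coev_params")) return(params)
  coev_params(params[["s"]], params[["d"]], params[["r1"]], params[["r2"]])
}

# A "state space" bundles everything the Q builder needs. For the full space,
# weights are all 1; a reduced (lumped) space carries wildcard letters with
# multiplicity weights (see reduced_state_space).
.full_state_space <- function(alphabet, profile = NULL) {
  alphabet <- coev_alphabet(alphabet)
  .make_state_space(alphabet$letters, rep(1, alphabet$n),
                    alphabet$letters, rep(1, alphabet$n),
                    profile, alphabet)
}

.make_state_space <- function(l1, w1, l2, w2, profile, alphabet) {
  n1 <- length(l1); n2 <- length(l2)
  first <- rep(seq_len(n1), each = n2)
  second <- rep(seq_len(n2), times = n1)
  tokens <- paste0(l1[first], l2[second])
  inphi <- if (is.null(profile)) rep(FALSE, n1 * n2) else tokens %in% profile
  diff1 <- outer(first, first, "!=")
  diff2 <- outer(second, second, "!=")
  single1 <- diff1 & !diff2
  single2 <- !diff1 & diff2
  # multiplicity of the target letter that changed (wildcards lump m letters)
  mult <- matrix(1, n1 * n2, n1 * n2)
  mult[single1] <- w1[first[col(mult)[single1]]]
  mult[single2] <- w2[second[col(mult)[single2]]]
  single <- single1 | single2
  i_in <- matrix(inphi, nrow = length(inphi), ncol = length(inphi))
  j_in <- t(i_in)
  # linear index sets of the four rate classes, precomputed once so that
  # assembling Q for new rates is four scalar assignments
  list(tokens = tokens, inphi = inphi,
       single1 = single1, single2 = single2, mult = mult,
       idx_s = which(single & i_in & !j_in),
       idx_d = which(single & !i_in & j_in),
       idx_r1 = which(single1 & !i_in & !j_in),
       idx_r2 = which(single2 & !i_in & !j_in),
       profile = profile, alphabet = alphabet,
       l1 = l1, w1 = w1, l2 = l2, w2 = w2)
}

.space_Q <- function(space, s, d, r1, r2) {
  m <- length(space$tokens)
  Q <- matrix(0, m, m)
  Q[space$idx_s] <- s
  Q[space$idx_d] <- d
  Q[space$idx_r1] <- r1
  Q[space$idx_r2] <- r2
  Q <- Q * space$mult
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(space$tokens, space$tokens)
  attr(Q, "alphabet") <- space$alphabet
  attr(Q, "profile") <- space$profile
  Q
}

#' Build the Coev instantaneous rate matrix
#'
#' Returns the \eqn{n^2 \times n^2} generator of the coupled pair chain for
#' the given rates and coevolution profile (16x16 for nucleotides, 400x400
#' for amino acids). Rows and columns are labelled with pair-state tokens in
#' row-major (position-1 letter major) order.
#'
#' @param params A [coev_params()] (or a list with s, d, r1, r2).
#' @param profile A profile valid for `alphabet` (see [validate_profile()]).
#' @inheritParams pair_states
#' @return Rate matrix with zero row sums; attributes `alphabet`, `profile`.
#' @examples
#' Q <- build_coev_Q(coev_params(1, 10, 2, 2), c("AA", "CC"), "nucleotide")
#' Q["AA", "CC"]  # 0: differs at both positions
#' Q["AA", "CA"]  # s: leaving the profile
#' Q["CA", "CC"]  # d: entering the profile
#' @export
build_coev_Q <- function(params, profile, alphabet) {
  alphabet <- coev_alphabet(alphabet)
  params <- .as_params(params)
  profile <- validate_profile(profile, alphabet)
  space <- .full_state_space(alphabet, profile)
  .space_Q(space, params$s, params$d, params$r1, params$r2)
}

#' Build the independent (null) rate matrix
#'
#' The null of the coevolution test: positions substitute independently, with
#' single position-1 changes at rate `r1`, single position-2 changes at rate
#' `r2` and no simultaneous double changes. Equivalent to the Coev matrix
#' with an empty-effect profile; `s` and `d` do not appear in the entries.
#'
#' @inheritParams build_coev_Q
#' @return Rate matrix with zero row sums.
#' @export
build_independent_Q <- function(params, alphabet) {
  alphabet <- coev_alphabet(alphabet)
  params <- .as_params(params)
  space <- .full_state_space(alphabet, NULL)
  .space_Q(space, params$s, params$d, params$r1, params$r2)
}

#' Stationary distribution of a rate matrix
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} by least squares on the
#' transposed generator augmented with the normalisation row. Used as the
#' root-state frequency vector for both simulation and likelihood scoring.
#'
#' @param Q A rate matrix (rows summing to zero).
#' @return Probability vector named by the states of `Q`.
#' @export
stationary_distribution <- function(Q) {
  m <- nrow(Q)
  A <- rbind(t(Q), rep(1, m))
  pi <- qr.solve(A, c(rep(0, m), 1))
  resid <- max(abs(as.vector(pi %*% Q)))
  if (resid > 1e-8 || any(pi < -1e-8))
    stop("rate matrix does not have a unique stationary distribution ",
         "(chain not irreducible?)")
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q A rate matrix.
#' @param t Branch length (time), >= 0.
#' @return Stochastic matrix (rows sum to 1) with attribute `t`.
#' @export
transition_matrix <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("invalid argument: branch length t must be a single number >= 0")
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  attr(P, "t") <- t
  P
}

#' Write a matrix to tab-separated text (debugging aid)
#'
#' @param m A matrix with dimnames.
#' @param file Path to write to.
#' @export
write_matrix_tsv <- function(m, file) {
  utils::write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

# ---- exact state lumping --------------------------------------------------
#
# For likelihood work only the letters observed at the leaves and the letters
# in the profile are distinguishable; all remaining letters at a position are
# exchangeable under the Coev rates (same r1/r2/s/d classification regardless
# of which unused letter is involved), so the chain is strongly lumpable onto
# the space where they are aggregated into one wildcard letter ("?") with a
# multiplicity weight. The lumped generator gives the identical likelihood
# for the observed data at a fraction of the 400x400 amino-acid cost.

.reduced_letters <- function(observed, profile_letters, alphabet) {
  keep <- alphabet$letters[alphabet$letters %in%
                             union(observed, profile_letters)]
  m <- alphabet$n - length(keep)
  if (m > 0) {
    list(letters = c(keep, "?"), weights = c(rep(1, length(keep)), m))
  } else {
    list(letters = keep, weights = rep(1, length(keep)))
  }
}

reduced_state_space <- function(observed_tokens, profile, alphabet) {
  alphabet <- coev_alphabet(alphabet)
  o1 <- unique(substr(observed_tokens, 1, 1))
  o2 <- unique(substr(observed_tokens, 2, 2))
  p1 <- if (is.null(profile)) character(0) else substr(profile, 1, 1)
  p2 <- if (is.null(profile)) character(0) else substr(profile, 2, 2)
  r1 <- .reduced_letters(o1, p1, alphabet)
  r2 <- .reduced_letters(o2, p2, alphabet)
  .make_state_space(r1$letters, r1$weights, r2$letters, r2$weights,
                    profile, alphabet)
}
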