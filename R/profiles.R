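# Coevolution profiles: sets of >= 2 pair-states forming an injective matching
# between position-1 and position-2 letters. Represented as character vectors
# of pair-state tokens in canonical (index-sorted) order.

# --- tiny exact integer arithmetic (base 1e7 little-endian digit vectors) ---
# The profile count for n = 20 (~1e21) overflows exact double arithmetic, and
# no big-integer package is assumed; sums/products here stay exact.

.big_base <- 1e7

.big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% .big_base)
    x <- x %/% .big_base
    if (x == 0) break
  }
  d
}

.big_mul_small <- function(a, m) {
  # m a non-negative integer-valued double < 2^26 so products stay exact
  stopifnot(m >= 0, m == floor(m), m < 2^26)
  carry <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    v <- a[i] * m + carry
    out[i] <- v %% .big_base
    carry <- v %/% .big_base
  }
  while (carry > 0) {
    out <- c(out, carry %% .big_base)
    carry <- carry %/% .big_base
  }
  out
}

.big_add <- function(a, b) {
  k <- max(length(a), length(b))
  a <- c(a, numeric(k - length(a)))
  b <- c(b, numeric(k - length(b)))
  out <- numeric(k)
  carry <- 0
  for (i in seq_len(k)) {
    v <- a[i] + b[i] + carry
    out[i] <- v %% .big_base
    carry <- v %/% .big_base
  }
  if (carry > 0) out <- c(out, carry)
  out
}

.big_to_string <- function(a) {
  a <- rev(a)
  paste0(sub("^0+(?=.)", "", paste0(
    formatC(a[1], format = "d"),
    paste(formatC(a[-1], width = 7, flag = "0", format = "d"), collapse = "")
  ), perl = TRUE))
}

.big_to_num <- function(a) sum(a * .big_base^(seq_along(a) - 1))

# Exact count of size-k profiles: C(n,k)^2 * k!
.profile_size_count_big <- function(n, k) {
  ch <- choose(n, k)            # exact in double for n <= 20
  b <- .big_from_num(ch * ch)   # <= C(20,10)^2 ~ 3.4e10, exact
  for (j in seq_len(k)) if (j > 1) b <- .big_mul_small(b, j)
  b
}

#' Count coevolution profiles for an alphabet of size n
#'
#' A profile of size \eqn{k} picks \eqn{k} position-1 letters, \eqn{k}
#' position-2 letters and a bijection between them, with order inside the set
#' irrelevant, giving \eqn{\binom{n}{k}^2 k!} profiles of size \eqn{k} and
#' \deqn{\sum_{k=2}^{n} \left[\frac{n!}{(n-k)!}\right]^2 \frac{1}{k!}
#'   = \sum_{k=2}^{n} \binom{n}{k}^2 k!}
#' profiles in total. The sum is computed in exact integer arithmetic; the
#' exact decimal representation is attached as attribute `"exact"` (the
#' numeric return value is its closest double, relevant only for n > 14).
#'
#' @param n Alphabet size, an integer >= 2.
#' @return Numeric count with attribute `"exact"` (decimal string) and
#'   `"by_size"` (numeric vector of per-size counts, names `2:n`).
#' @examples
#' count_profiles(4)   # 192 (nucleotides)
#' count_profiles(20)  # ~1e21 (amino acids)
#' @export
count_profiles <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n != floor(n) || n < 2)
    stop("invalid argument: n must be a single integer >= 2")
  total <- .big_from_num(0)
  by_size <- numeric(0)
  for (k in 2:n) {
    b <- .profile_size_count_big(n, k)
    by_size <- c(by_size, .big_to_num(b))
    total <- .big_add(total, b)
  }
  names(by_size) <- as.character(2:n)
  structure(.big_to_num(total),
            exact = .big_to_string(total),
            by_size = by_size)
}

# all permutations of 1:k, lexicographic
.perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

#' Enumerate every coevolution profile of a small alphabet
#'
#' Exhaustive enumeration is only sensible for small alphabets (the count is
#' 192 for n = 4 but of order 1e21 for n = 20); alphabets larger than 8
#' letters are refused — use [count_profiles()] and [random_profile()] there.
#'
#' @inheritParams pair_states
#' @return List of profiles (character vectors of pair-state tokens in
#'   canonical order), ordered by profile size then lexicographically by
#'   sorted pair-state indices.
#' @examples
#' length(enumerate_profiles(coev_alphabet("nucleotide")))  # 192
#' enumerate_profiles(coev_alphabet(c("A", "B")))
#' @export
enumerate_profiles <- function(alphabet) {
  alphabet <- coev_alphabet(alphabet)
  n <- alphabet$n
  if (n > 8)
    stop("profile enumeration is limited to alphabets of size <= 8 ",
         "(got n = ", n, "); use count_profiles()/random_profile() instead")
  profiles <- list()
  keys <- character(0)
  sizes <- integer(0)
  for (k in 2:n) {
    sets <- utils::combn(n, k)
    pm <- .perms(k)
    for (a in seq_len(ncol(sets))) {
      for (b in seq_len(ncol(sets))) {
        l1 <- alphabet$letters[sets[, a]]
        for (p in seq_len(nrow(pm))) {
          l2 <- alphabet$letters[sets[, b]][pm[p, ]]
          tok <- paste0(l1, l2)
          idx <- sort(pair_state_index(tok, alphabet))
          key <- paste(idx, collapse = ",")
          if (!(key %in% keys)) {
            keys <- c(keys, key)
            sizes <- c(sizes, k)
            profiles[[length(profiles) + 1L]] <-
              pair_states(alphabet)[idx]
          }
        }
      }
    }
  }
  ord <- order(sizes, vapply(
    strsplit(keys, ","),
    function(v) paste(formatC(as.integer(v), width = 4, flag = "0"),
                      collapse = ""),
    ""))
  profiles[ord]
}

#' Validate a coevolution profile
#'
#' Checks the defining invariants: at least two member pair-states, all
#' position-1 letters distinct, all position-2 letters distinct (an injective
#' matching) and — a consequence asserted explicitly — any two members differ
#' at both positions.
#'
#' @param profile Character vector of pair-state tokens.
#' @inheritParams pair_states
#' @return The profile in canonical (index-sorted) order, invisibly usable.
#' @export
validate_profile <- function(profile, alphabet) {
  alphabet <- coev_alphabet(alphabet)
  if (length(profile) < 2)
    stop("a profile needs at least 2 pair-states")
  idx <- pair_state_index(profile, alphabet)  # also checks letters
  if (anyDuplicated(idx)) stop("duplicate pair-states in profile")
  f <- substr(profile, 1, 1)
  s <- substr(profile, 2, 2)
  if (anyDuplicated(f))
    stop("profile position-1 letters must be distinct")
  if (anyDuplicated(s))
    stop("profile position-2 letters must be distinct")
  for (i in seq_along(profile)) for (j in seq_along(profile)) {
    if (i < j && (f[i] == f[j] || s[i] == s[j]))
      stop("profile members must differ at both positions")
  }
  profile[order(idx)]
}

#' Draw a profile uniformly over all profiles of an alphabet
#'
#' The draw is uniform over the full profile space: first the size k is drawn
#' with probability proportional to the number of size-k profiles
#' (\eqn{\binom{n}{k}^2 k!}), then k position-1 letters, k position-2 letters
#' and a bijection are drawn uniformly. Uses R's global random number stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @inheritParams pair_states
#' @return A profile (canonical character vector of pair-state tokens).
#' @export
random_profile <- function(alphabet) {
  alphabet <- coev_alphabet(alphabet)
  n <- alphabet$n
  w <- attr(count_profiles(n), "by_size")
  k <- as.integer(sample(names(w), 1, prob = w))
  l1 <- alphabet$letters[sort(sample.int(n, k))]
  l2 <- alphabet$letters[sample.int(n, k)]  # random order = random bijection
  tok <- paste0(l1, l2)
  tok[order(pair_state_index(tok, alphabet))]
}

#' Is a pair-state a member of a profile?
#'
#' @param state A two-character pair-state token.
#' @param profile Character vector of pair-state tokens.
#' @return Logical.
#' @examples
#' is_member("AA", c("AA", "CC"))  # TRUE
#' is_member("CA", c("AA", "CC"))  # FALSE
#' @export
is_member <- function(state, profile) {
  state %in% profile
}

#' Serialise / parse the compact profile text form
#'
#' Profiles travel through logs and the command line as comma-separated
#' two-letter tokens, e.g. `"AA,CC"`.
#'
#' @param profile Character vector of pair-state tokens.
#' @return `profile_string()`: a single string; `parse_profile()`: a
#'   validated profile in canonical order.
#' @export
profile_string <- function(profile) paste(profile, collapse = ",")

#' @rdname profile_string
#' @param text A string such as `"AA,CC"`.
#' @inheritParams pair_states
#' @export
parse_profile <- function(text, alphabet) {
  tok <- strsplit(trimws(text), ",")[[1]]
  tok <- toupper(trimws(tok))
  if (any(nchar(tok) != 2))
    stop("profile tokens must be two-letter pair-states, got: ",
         paste(tok[nchar(tok) != 2], collapse = ", "))
  validate_profile(tok, alphabet)
}
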