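#' Sequence alphabets for the coupled pair-state space
#'
#' An alphabet is an ordered set of distinct single-character symbols. Two
#' built-ins cover the common cases: `"nucleotide"` (A, C, G, T) and `"aa"`
#' (the 20 standard amino acids in one-letter code). A custom alphabet can be
#' given as a character vector of distinct single characters.
#'
#' @param x Either `"nucleotide"` (aliases `"nt"`, `"dna"`), `"aa"` (aliases
#'   `"protein"`, `"amino"`), or a character vector of distinct
#'   single-character symbols.
#' @return An object of class `coev_alphabet`: a list with elements
#'   `letters` (ordered symbols), `n` (alphabet size) and `label`.
#' @examples
#' coev_alphabet("nucleotide")$n  # 4
#' coev_alphabet("aa")$n          # 20
#' coev_alphabet(c("A", "B"))     # a 2-letter toy alphabet
#' @export
coev_alphabet <- function(x = "nucleotide") {
  if (inherits(x, "coev_alphabet")) return(x)
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1 && tolower(x) %in% c("nucleotide", "nt", "dna")) {
    letters <- c("A", "C", "G", "T")
    label <- "nucleotide"
  } else if (length(x) == 1 &&
             tolower(x) %in% c("aa", "protein", "amino", "aminoacid")) {
    letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    label <- "aa"
  } else {
    letters <- toupper(x)
    if (anyDuplicated(letters))
      stop("alphabet letters must be unique")
    if (any(nchar(letters) != 1L))
      stop("alphabet letters must be single characters")
    label <- "custom"
  }
  structure(list(letters = letters, n = length(letters), label = label),
            class = "coev_alphabet")
}

#' @export
print.coev_alphabet <- function(x, ...) {
  cat("coev_alphabet (", x$label, "): n = ", x$n, " {",
      paste(x$letters, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Pair-state tokens of the coupled state space
#'
#' The coupled chain runs on ordered pairs of letters; a pair-state is written
#' as a two-character token, e.g. `"AC"` = A at position 1, C at position 2.
#' States are indexed row-major (position-1 letter major), so token `i` has
#' 1-based index `(rank(first) - 1) * n + rank(second)`.
#'
#' @param alphabet A [coev_alphabet()] (or something coercible to one).
#' @return Character vector of the `n^2` pair-state tokens in index order.
#' @examples
#' pair_states(coev_alphabet(c("A", "B")))  # "AA" "AB" "BA" "BB"
#' @export
pair_states <- function(alphabet) {
  alphabet <- coev_alphabet(alphabet)
  n <- alphabet$n
  paste0(rep(alphabet$letters, each = n), rep(alphabet$letters, times = n))
}

#' Index of a pair-state token (1-based, row-major)
#'
#' @param token Character vector of two-character pair-state tokens.
#' @inheritParams pair_states
#' @return Integer vector of 1-based indices into [pair_states()].
#' @export
pair_state_index <- function(token, alphabet) {
  alphabet <- coev_alphabet(alphabet)
  i1 <- match(substr(token, 1, 1), alphabet$letters)
  i2 <- match(substr(token, 2, 2), alphabet$letters)
  if (anyNA(i1) || anyNA(i2))
    stop("pair-state token contains letters outside the alphabet: ",
         paste(token[is.na(i1) | is.na(i2)], collapse = ", "))
  (i1 - 1L) * alphabet$n + i2
}
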