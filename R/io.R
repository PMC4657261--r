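# Tree and alignment I/O plus the alignment-curation filters.
#
# Trees are ape "phylo" objects, required rooted and strictly binary with a
# branch length on every edge. Alignments are kept as a plain character
# matrix (taxa x sites) tagged with the alphabet.

#' Parse a rooted binary Newick tree
#'
#' Wraps [ape::read.tree()] and enforces the model's requirements: rooted,
#' strictly binary (every internal node has exactly two children), unique
#' leaf labels and a branch length on every edge.
#'
#' @param text Newick text, or a path to a file containing it.
#' @return An [ape::phylo] tree.
#' @examples
#' parse_newick("((a:0.1,b:0.2):0.3,(c:0.1,d:0.4):0.2);")
#' @export
parse_newick <- function(text) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("Newick syntax error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick syntax error: could not parse input")
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param tree An [ape::phylo] object to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  kids <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  internal <- sort(unique(tree$edge[, 1]))
  bad <- internal[kids[internal] != 2]
  if (length(bad) > 0)
    stop("tree is not strictly binary (rooted): node(s) ",
         paste(bad, collapse = ", "), " have ",
         paste(kids[bad], collapse = ", "), " children")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("every edge needs a branch length; missing on edge(s) ",
         if (is.null(tree$edge.length)) "all" else
           paste(which(is.na(tree$edge.length)), collapse = ", "))
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and >= 0 on every edge; offending ",
         "edge(s): ",
         paste(which(is.na(tree$edge.length) | tree$edge.length < 0),
               collapse = ", "))
  tree
}

#' Write a tree as Newick text
#'
#' @param tree An [ape::phylo] tree.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    invisible(file)
  } else txt
}

#' Construct an alignment object
#'
#' @param seqs Character matrix (taxa in rows, sites in columns) or a named
#'   character vector of equal-length sequence strings.
#' @param alphabet Alphabet tag, see [coev_alphabet()].
#' @return Object of class `coev_alignment`: list with `taxa`, `seqs`
#'   (character matrix) and `alphabet`.
#' @export
coev_alignment <- function(seqs, alphabet = "nucleotide") {
  alphabet <- coev_alphabet(alphabet)
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "))
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- toupper(seqs)
  }
  if (is.null(rownames(seqs))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(seqs)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(seqs)[duplicated(rownames(seqs))]),
               collapse = ", "))
  structure(list(taxa = rownames(seqs), seqs = seqs, alphabet = alphabet),
            class = "coev_alignment")
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat("coev_alignment: ", length(x$taxa), " taxa x ", ncol(x$seqs),
      " sites (", x$alphabet$label, ")\n", sep = "")
  invisible(x)
}

#' Read / write FASTA alignments
#'
#' `read_fasta()` accepts raw FASTA text or a file path; sequences are
#' case-folded to upper case and must all have the same length.
#' `write_fasta()` emits standard two-line-per-record FASTA.
#'
#' @param text FASTA text (a string containing `>` headers) or a file path.
#' @param alphabet Alphabet tag for the resulting alignment.
#' @return `read_fasta()`: a [coev_alignment()]; `write_fasta()`: the text,
#'   invisibly if written to a file.
#' @export
read_fasta <- function(text, alphabet = "nucleotide") {
  if (length(text) == 1 && !startsWith(trimws(text)[1], ">") &&
      file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], ">"))
    stop("not FASTA: first non-empty line must start with '>'")
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(names_), function(i)
    paste(lines[!hdr & id == i], collapse = ""), "")
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence: ",
                               paste(names_[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- names_
  coev_alignment(seqs, alphabet)
}

#' @rdname read_fasta
#' @param alignment A [coev_alignment()].
#' @param file Optional output path.
#' @export
write_fasta <- function(alignment, file = NULL) {
  stopifnot(inherits(alignment, "coev_alignment"))
  txt <- paste0(">", alignment$taxa, "\n",
                apply(alignment$seqs, 1, paste, collapse = ""))
  txt <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    invisible(file)
  } else txt
}

#' Curate an alignment for coevolution scoring
#'
#' The model cannot use columns with gaps, columns with symbols outside the
#' declared alphabet (ambiguity codes such as N, R, Y or X count as such),
#' or fully conserved columns. `curate_alignment()` removes them, recording
#' for every original column whether it was kept and, if not, the first
#' matching reason in the order `gap`, `non-alphabet`, `conserved`.
#'
#' @param alignment A [coev_alignment()].
#' @return List with `alignment` (the filtered [coev_alignment()]) and
#'   `report`, a `curation_report`: list with `kept` (original 1-based
#'   indices), `removed` (data.frame original_index/reason) and `map`
#'   (original index -> filtered index, `NA` when removed).
#' @export
curate_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "coev_alignment"))
  m <- alignment$seqs
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty alignment")
  letters_ok <- alignment$alphabet$letters
  has_gap <- apply(m, 2, function(col) any(col == "-"))
  non_alpha <- apply(m, 2, function(col) any(!(col %in% c(letters_ok, "-"))))
  conserved <- apply(m, 2, function(col) length(unique(col)) == 1)
  reason <- rep(NA_character_, ncol(m))
  reason[conserved] <- "conserved"
  reason[non_alpha] <- "non-alphabet"
  reason[has_gap] <- "gap"                     # highest precedence last
  kept <- which(is.na(reason))
  map <- rep(NA_integer_, ncol(m))
  map[kept] <- seq_along(kept)
  removed <- data.frame(original_index = which(!is.na(reason)),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  filtered <- coev_alignment(m[, kept, drop = FALSE], alignment$alphabet)
  report <- structure(list(kept = kept, removed = removed, map = map,
                           n_original = ncol(m)),
                      class = "curation_report")
  list(alignment = filtered, report = report)
}

#' Map an original column position through a curation report
#'
#' @param report A `curation_report` from [curate_alignment()].
#' @param original_pos 1-based column index on the original alignment.
#' @return The 1-based index in the filtered alignment; an error naming the
#'   removal reason if the column was filtered out.
#' @export
map_position <- function(report, original_pos) {
  stopifnot(inherits(report, "curation_report"))
  if (!is.numeric(original_pos) || length(original_pos) != 1 ||
      original_pos != floor(original_pos) ||
      original_pos < 1 || original_pos > report$n_original)
    stop("position out of range: must be in 1..", report$n_original)
  idx <- report$map[original_pos]
  if (is.na(idx)) {
    why <- report$removed$reason[report$removed$original_index == original_pos]
    stop("position ", original_pos, " was removed during curation (reason: ",
         why, ")")
  }
  idx
}

#' Write a curation report as TSV
#'
#' @param report A `curation_report`.
#' @param file Output path.
#' @export
write_curation_report <- function(report, file) {
  status <- ifelse(is.na(report$map), "removed", "kept")
  reason <- rep("", report$n_original)
  reason[report$removed$original_index] <- report$removed$reason
  utils::write.table(
    data.frame(original_index = seq_len(report$n_original),
               status = status, reason = reason),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
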