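#' Default patterns recognising unplaced contig names
#'
#' Assemblies differ in how unlocalised sequence is named; these defaults
#' cover the common dialects (names beginning `chrUn`, or containing
#' `scaffold`). Any name that matches none of these but also lacks the
#' canonical `chr1`--`chr38` / `chrX` form is still classified as unplaced.
#'
#' @return Character vector of regular expressions.
#' @export
default_unplaced_patterns <- function() {
  c("^chrUn", "scaffold")
}

# canonical assembled-chromosome names: chr1-chr38 and chrX
.chromosome_pattern <- "^chr([1-9]|[12][0-9]|3[0-8]|X)$"

#' Classify a sequence name as assembled chromosome or unplaced contig
#'
#' Numt summaries are stratified by whether a sequence is an assembled
#' nuclear chromosome (`chr1`--`chr38`, `chrX`) or an unplaced contig.
#' Classification is purely name-based and configurable per assembly
#' naming dialect.
#'
#' @param name Character vector of sequence names.
#' @param unplaced_patterns Regular expressions that force the `unplaced`
#'   label. Names matching none of them must still match
#'   `chromosome_pattern` to be called a chromosome.
#' @param chromosome_pattern Single regular expression for canonical
#'   chromosome names.
#' @return Character vector, each element `"chromosome"` or `"unplaced"`.
#' @examples
#' classify_role(c("chr34", "chrX", "chrUn_JAAHUQ010000987v1"))
#' @export
classify_role <- function(name,
                          unplaced_patterns = default_unplaced_patterns(),
                          chromosome_pattern = .chromosome_pattern) {
  stopifnot(is.character(name))
  unplaced <- rep(FALSE, length(name))
  for (p in unplaced_patterns) {
    unplaced <- unplaced | grepl(p, name)
  }
  ifelse(!unplaced & grepl(chromosome_pattern, name), "chromosome", "unplaced")
}

normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Construct a sequence record table
#'
#' @param name Sequence name(s).
#' @param seq DNA string(s); uppercased, non-ACGTN characters mapped to N.
#' @param role Optional role label; derived from `name` when `NULL`.
#' @param unplaced_patterns Passed to [classify_role()].
#' @return A tibble with columns `name`, `seq`, `width`, `role`.
#' @export
seq_record <- function(name, seq, role = NULL,
                       unplaced_patterns = default_unplaced_patterns()) {
  seq <- unname(normalize_sequence(seq))
  name <- unname(name)
  if (any(!nzchar(seq))) stop("sequence must be non-empty")
  if (is.null(role)) role <- classify_role(name, unplaced_patterns)
  tibble(name = name, seq = seq, width = nchar(seq), role = role)
}

#' Read a FASTA file into a sequence record table
#'
#' Sequences are uppercased and any IUPAC ambiguity (or other non-ACGTN)
#' character is mapped to `N`. Plain or gzip-compressed FASTA is accepted.
#'
#' @param path Path to a FASTA file.
#' @param unplaced_patterns Passed to [classify_role()].
#' @return A tibble with one row per record: `name`, `seq`, `width`, `role`.
#' @export
read_fasta <- function(path, unplaced_patterns = default_unplaced_patterns()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) {
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  }
  if (!startsWith(first, ">")) {
    stop("FASTA format error in ", path, ": line 1 does not start with '>'")
  }
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seq_record(nm, as.character(ss), unplaced_patterns = unplaced_patterns)
}

#' Write a sequence record table to FASTA
#'
#' @param records Tibble with `name` and `seq` columns.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(setNames(records$seq, records$name))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
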