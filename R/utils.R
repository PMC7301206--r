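# Internal helpers: DNA string utilities, IUPAC matching, error conditions.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide codes -> the set of concrete bases matched.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

bescan_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "bescan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the A/C/G/T/N alphabet (other
#' letters are complemented via the full IUPAC map).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Normalise a raw sequence: uppercase; U -> T; any IUPAC letter outside
# A/C/G/T/N -> N (one warning per contig); anything else is an error.
normalise_sequence <- function(seq, contig_id = "?") {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(chars(gsub("[ACGTN]", "", seq)))
    not_iupac <- setdiff(bad, names(IUPAC_SETS))
    if (length(not_iupac) > 0) {
      bescan_abort(
        sprintf("contig '%s': non-nucleotide characters: %s",
                contig_id, paste(not_iupac, collapse = ", ")),
        "bescan_format_error"
      )
    }
    warning(sprintf(
      "contig '%s': ambiguity codes %s normalised to N",
      contig_id, paste(bad, collapse = ", ")
    ), call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

# Does each concrete base (A/C/G/T; N matches nothing) match the IUPAC
# pattern character at the same position?  Vectorised over equal-length
# character vectors.
iupac_char_match <- function(text_chars, pattern_chars) {
  mapply(function(tc, pc) {
    tc %in% IUPAC_SETS[[pc]]
  }, text_chars, pattern_chars, USE.NAMES = FALSE)
}

# TRUE if the concrete sequence `x` (string) matches IUPAC pattern `pat`.
iupac_match <- function(x, pat) {
  if (nchar(x) != nchar(pat)) return(FALSE)
  all(iupac_char_match(chars(x), chars(pat)))
}

# Translate an IUPAC pattern into a regular expression over A/C/G/T
# (N in the text matches nothing, so character classes only contain ACGT).
iupac_regex <- function(pat) {
  paste0(vapply(chars(pat), function(p) {
    set <- IUPAC_SETS[[p]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

assert_dna_pattern <- function(pattern, what = "pattern") {
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern) ||
      nchar(pattern) < 1) {
    bescan_abort(sprintf("%s must be a non-empty string", what),
                 "bescan_argument_error")
  }
  if (grepl("[^ACGT]", pattern)) {
    bescan_abort(sprintf("%s must contain only A/C/G/T", what),
                 "bescan_argument_error")
  }
  invisible(pattern)
}

# Standard genetic code, codon -> one-letter amino acid ('*' for stop).
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", unname(aa))
}
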