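# Suffix-array index over both strands of every contig.
#
# The index text is the concatenation of each contig's forward sequence and
# its reverse complement, every segment followed by its own sentinel symbol.
# Sentinels are unique per segment and ordered below the DNA alphabet, and a
# final 0 terminator closes the text, so suffix comparisons are well defined
# and no match can span a segment boundary (sentinel codes never equal a
# pattern code).  Construction is SA-IS (linear time); queries descend over
# suffix-array intervals, costing O(|pattern| * log |text|) per explored
# path.  N bases in the text carry their own code: they never match a
# pattern base and therefore always count as a mismatch.

# Symbol layout: 0 = terminator, 1..m = per-segment sentinels,
# m+1..m+5 = A, C, G, N, T (byte order).
BASE_ORDER <- c("A", "C", "G", "N", "T")

#' Build a suffix-array index over a genome
#'
#' @param records list of [genome_record()] objects.
#' @return an object of class `SuffixIndex`.
#' @export
build_suffix_index <- function(records) {
  if (length(records) == 0) {
    bescan_abort("cannot index an empty genome", "bescan_argument_error")
  }
  segs <- list()
  for (r in records) {
    if (r$length == 0) next
    segs[[length(segs) + 1L]] <- list(contig_id = r$contig_id, strand = "+",
                                      seq = r$sequence, len = r$length)
    segs[[length(segs) + 1L]] <- list(contig_id = r$contig_id, strand = "-",
                                      seq = revcomp(r$sequence), len = r$length)
  }
  if (length(segs) == 0) {
    bescan_abort("cannot index an empty genome", "bescan_argument_error")
  }
  m <- length(segs)

  base_codes <- setNames(m + seq_along(BASE_ORDER), BASE_ORDER)
  codes <- integer(0)
  offsets <- integer(m)
  pos <- 0L
  pieces <- vector("list", m)
  for (i in seq_len(m)) {
    offsets[i] <- pos
    sc <- utf8ToInt(segs[[i]]$seq)
    # map A,C,G,N,T byte codes -> ranks 1..5 (byte order is alphabetical)
    rank <- match(sc, utf8ToInt(paste(BASE_ORDER, collapse = "")))
    pieces[[i]] <- c(as.integer(m + rank), i)
    pos <- pos + segs[[i]]$len + 1L
  }
  codes <- c(unlist(pieces), 0L)

  sa <- .sais_build(codes, m + 6L)

  structure(
    list(
      codes = codes,
      sa = sa,
      segments = data.frame(
        contig_id = vapply(segs, `[[`, "", "contig_id"),
        strand = vapply(segs, `[[`, "", "strand"),
        offset = offsets,
        len = vapply(segs, function(s) as.integer(s$len), integer(1)),
        stringsAsFactors = FALSE
      ),
      n_segments = m,
      base_codes = base_codes
    ),
    class = "SuffixIndex"
  )
}

#' @export
print.SuffixIndex <- function(x, ...) {
  cat(sprintf("SuffixIndex: %d contig(s), both strands, text length %d\n",
              x$n_segments / 2L, length(x$codes)))
  invisible(x)
}

#' Suffix array of a single string
#'
#' Low-level access to the SA-IS construction: returns the 0-based suffix
#' array of `text` (any character string; symbols compare in byte order).
#' Mostly useful for testing the construction against a generic sort.
#'
#' @param text a single string.
#' @return integer vector, the 0-based starting positions of the suffixes of
#'   `text` in lexicographic order.
#' @export
suffix_array <- function(text) {
  if (!is.character(text) || length(text) != 1 || nchar(text) == 0) {
    bescan_abort("text must be a non-empty string", "bescan_argument_error")
  }
  bytes <- utf8ToInt(text)
  codes <- c(match(bytes, sort(unique(bytes))), 0L)
  sa <- .sais_build(codes, length(unique(bytes)) + 1L)
  sa[-1L]  # drop the appended terminator suffix
}

encode_pattern <- function(index, pattern) {
  unname(index$base_codes[chars(pattern)])
}

# Map text offsets of w-long matches back to (contig, strand, forward start).
map_hits <- function(index, pos, mm, w) {
  if (length(pos) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  seg <- findInterval(pos, index$segments$offset)
  local <- pos - index$segments$offset[seg]
  len <- index$segments$len[seg]
  strand <- index$segments$strand[seg]
  stopifnot(all(local + w <= len))  # sentinel codes make spanning impossible
  start <- ifelse(strand == "+", local, len - local - w)
  df <- data.frame(
    contig_id = index$segments$contig_id[seg],
    strand = strand,
    start = as.integer(start),
    mismatches = as.integer(mm),
    stringsAsFactors = FALSE
  )
  df[order(df$contig_id, df$strand, df$start), , drop = FALSE]
}

#' Exact pattern search over both strands
#'
#' Every occurrence of `pattern` on either strand is reported once, in
#' forward (plus-strand) coordinates with a strand tag.
#'
#' @param index a [build_suffix_index()] object.
#' @param pattern DNA string (A/C/G/T only).
#' @return data frame with columns `contig_id`, `strand`, `start` (0-based
#'   forward position of the match start) and `mismatches` (all 0).
#' @export
find_exact <- function(index, pattern) {
  assert_dna_pattern(pattern)
  find_with_mismatches(index, pattern, max_mismatches = 0L)
}

#' Bounded-mismatch pattern search over both strands
#'
#' Finds every genomic window (both strands) within Hamming distance
#' `max_mismatches` of `pattern` (substitutions only).  Each hit is reported
#' once, labelled with its minimal mismatch count; N in the genome never
#' matches a pattern base and always costs a mismatch.
#'
#' @inheritParams find_exact
#' @param max_mismatches maximum Hamming distance (0 or more; off-target
#'   scanning uses 0..3).
#' @return data frame as in [find_exact()], `mismatches` in
#'   `0..max_mismatches`.
#' @export
find_with_mismatches <- function(index, pattern, max_mismatches) {
  assert_dna_pattern(pattern)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0) {
    bescan_abort("max_mismatches must be >= 0", "bescan_argument_error")
  }
  p <- encode_pattern(index, pattern)
  res <- .sa_search(index$codes, index$sa, p, max_mismatches,
                    sort(unname(index$base_codes)))
  map_hits(index, res$pos, res$mm, nchar(pattern))
}

#' Off-target mismatch histogram of a seed sequence
#'
#' Counts genomic positions (both strands) whose minimal Hamming distance to
#' `pattern` is exactly `k`, for `k = 0..d_max`.
#'
#' @inheritParams find_exact
#' @param d_max maximum distance (default 3).
#' @return integer vector of length `d_max + 1`, named `"0".."d_max"`.
#' @export
mismatch_histogram <- function(index, pattern, d_max = 3L) {
  hits <- find_with_mismatches(index, pattern, d_max)
  counts <- tabulate(hits$mismatches + 1L, nbins = d_max + 1L)
  setNames(as.integer(counts), as.character(0:d_max))
}
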