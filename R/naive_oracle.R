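# Intentionally naive reference implementations (quadratic scans, regex PAM
# matching, direct codon translation).  These share no code with the
# suffix-array path or the guide pipeline and exist so that fixture truth
# tables and test expectations can be verified independently.

#' Naive suffix array by generic sorting
#'
#' Sorts all suffixes of `text` with R's radix (byte-order) sort.  Quadratic
#' work; testing oracle for [suffix_array()].
#'
#' @param text a single string.
#' @return 0-based suffix array.
#' @export
oracle_suffix_array <- function(text) {
  n <- nchar(text)
  order(substring(text, 1:n, n), method = "radix") - 1L
}

#' Naive bounded-Hamming scan of both strands
#'
#' Slides `pattern` over the forward and reverse-complement sequence of
#' every record, counting character mismatches (N never matches a pattern
#' base).  Testing oracle for [find_with_mismatches()].
#'
#' @param records list of [genome_record()] objects.
#' @param pattern DNA string (A/C/G/T).
#' @param d_max maximum Hamming distance.
#' @return data frame with `contig_id`, `strand`, `start` (forward 0-based),
#'   `mismatches`, ordered as [find_with_mismatches()] output.
#' @export
oracle_hamming_hits <- function(records, pattern, d_max) {
  w <- nchar(pattern)
  p <- chars(pattern)
  out <- list()
  for (r in records) {
    for (s in c("+", "-")) {
      sseq <- if (s == "+") r$sequence else revcomp(r$sequence)
      n <- nchar(sseq)
      if (n < w) next
      cs <- chars(sseq)
      idx <- seq_len(n - w + 1L)
      mm <- integer(length(idx))
      for (j in seq_len(w)) mm <- mm + (cs[idx + j - 1L] != p[j])
      hit <- which(mm <= d_max)
      if (length(hit) == 0) next
      local <- hit - 1L
      start <- if (s == "+") local else n - local - w
      out[[length(out) + 1L]] <- data.frame(
        contig_id = r$contig_id, strand = s, start = as.integer(start),
        mismatches = as.integer(mm[hit]), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$contig_id, df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Naive off-target histogram
#'
#' @inheritParams oracle_hamming_hits
#' @return integer vector of length `d_max + 1` (counts at exactly
#'   0..`d_max` mismatches).
#' @export
oracle_mismatch_histogram <- function(records, pattern, d_max = 3L) {
  hits <- oracle_hamming_hits(records, pattern, d_max)
  setNames(tabulate(hits$mismatches + 1L, nbins = d_max + 1L),
           as.character(0:d_max))
}

#' Naive IUPAC PAM scan by regular expression
#'
#' Overlapping regex matching of the PAM pattern over both strands; testing
#' oracle for [find_pam_sites()].
#'
#' @param records list of [genome_record()] objects.
#' @param pam_pattern IUPAC string, e.g. `"NGG"`.
#' @param region a [target_region()].
#' @return data frame as produced by [find_pam_sites()].
#' @export
oracle_pam_scan <- function(records, pam_pattern, region) {
  L <- nchar(pam_pattern)
  rx <- paste0("(?=(", iupac_regex(pam_pattern), "))")
  rec <- get_record(records, region$contig_id)
  len <- rec$length
  out <- list()
  for (s in c("+", "-")) {
    sseq <- if (s == "+") rec$sequence else revcomp(rec$sequence)
    m <- gregexpr(rx, sseq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    local <- as.integer(m) - 1L
    fwd_start <- if (s == "+") local else len - local - L
    keep <- fwd_start >= region$start & fwd_start + L <= region$end
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      contig_id = rec$contig_id, strand = s,
      pam_start = fwd_start[keep], pam_end = fwd_start[keep] + L,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      pam_start = integer(0), pam_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$pam_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Naive end-to-end guide truth
#'
#' A from-scratch, loop-and-substring re-derivation of the whole pipeline:
#' regex PAM scan, spacer extraction, naive off-target histograms with
#' self-exclusion, simultaneous window editing and codon translation.  Used
#' to verify fixture truth tables and pipeline output.
#'
#' @param records list of [genome_record()] objects.
#' @param region a [target_region()].
#' @param pam_pattern IUPAC PAM (default `"NGG"`).
#' @param spacer_length,seed_length as in the main pipeline.
#' @param conversion `"C_to_T"` or `"A_to_G"`.
#' @param window_min,window_max edit window bounds (bases upstream of PAM).
#' @return data frame, one row per guide: `contig_id`, `strand`,
#'   `pam_start`, `spacer_seq`, `off_0..off_3`, `can_edit`,
#'   `introduces_stop`.
#' @export
oracle_guide_truth <- function(records, region, pam_pattern = "NGG",
                               spacer_length = 20L, seed_length = 13L,
                               conversion = "C_to_T",
                               window_min = 13L, window_max = 20L) {
  sites <- oracle_pam_scan(records, pam_pattern, region)
  rec <- get_record(records, region$contig_id)
  len <- rec$length
  src <- if (conversion == "C_to_T") "C" else "A"
  tgt <- if (conversion == "C_to_T") "T" else "G"
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites$strand[i]
    lp <- if (s == "+") sites$pam_start[i] else len - sites$pam_end[i]
    if (lp < spacer_length) next
    sseq <- if (s == "+") rec$sequence else revcomp(rec$sequence)
    spacer <- substr(sseq, lp - spacer_length + 1L, lp)
    if (grepl("N", spacer, fixed = TRUE)) next
    seed <- substr(spacer, spacer_length - seed_length + 1L, spacer_length)

    hist <- oracle_mismatch_histogram(list(rec), seed, 3L)
    hist["0"] <- hist["0"] - 1L  # remove the on-target occurrence

    # simultaneous edit of all source bases in the window (strand-local
    # positions lp-window_max .. lp-window_min), applied to the forward seq
    wl <- c(lp - window_max, lp - window_min + 1L)
    edited <- rec$sequence
    ed_fwd <- integer(0)
    if (wl[1] >= 0) {
      for (q in wl[1]:(wl[2] - 1L)) {
        if (substr(sseq, q + 1L, q + 1L) == src) {
          fq <- if (s == "+") q else len - 1L - q
          ed_fwd <- c(ed_fwd, fq)
          newb <- if (s == "+") tgt else comp_base(tgt)
          substr(edited, fq + 1L, fq + 1L) <- newb
        }
      }
    }
    can_edit <- FALSE
    introduces_stop <- FALSE
    if (length(ed_fwd) > 0) {
      for (f in rec$features) {
        gpos <- unlist(lapply(seq_len(nrow(f$intervals)), function(k) {
          seq.int(f$intervals[k, 1], f$intervals[k, 2] - 1L)
        }))
        if (!any(ed_fwd %in% gpos)) next
        take <- function(sq) {
          cc <- chars(sq)[gpos + 1L]
          if (f$strand == "-") cc <- comp_base(rev(cc))
          cc <- cc[(f$codon_start_offset + 1L):length(cc)]
          cc
        }
        rc <- take(rec$sequence)
        ac <- take(edited)
        nc <- length(rc) %/% 3L
        for (k in seq_len(nc)) {
          r3 <- paste(rc[(3L * k - 2L):(3L * k)], collapse = "")
          a3 <- paste(ac[(3L * k - 2L):(3L * k)], collapse = "")
          if (r3 == a3) next
          raa <- translate_codon(r3)
          aaa <- translate_codon(a3)
          if (raa != aaa) can_edit <- TRUE
          if (aaa == "*" && raa != "*") introduces_stop <- TRUE
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = rec$contig_id, strand = s, pam_start = sites$pam_start[i],
      spacer_seq = spacer,
      off_0 = unname(hist["0"]), off_1 = unname(hist["1"]),
      off_2 = unname(hist["2"]), off_3 = unname(hist["3"]),
      can_edit = can_edit, introduces_stop = introduces_stop,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      pam_start = integer(0), spacer_seq = character(0),
                      off_0 = integer(0), off_1 = integer(0),
                      off_2 = integer(0), off_3 = integer(0),
                      can_edit = logical(0), introduces_stop = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$pam_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
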