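# Spacer+PAM candidate enumeration and off-target seed counting.
#
# PAM sites are located through the suffix index: the longest non-degenerate
# suffix of the PAM pattern (the "anchor", "GG" for NGG) is looked up
# exactly, and degenerate positions are then validated against the genome.
# Off-target specificity is measured on the seed -- the PAM-proximal
# `seed_length` (default 13) bases of the spacer -- as a histogram of
# genome-wide matches at 0..3 mismatches, with the candidate's own locus
# removed from the 0-mismatch bin.

#' PAM specification
#'
#' @param pattern IUPAC PAM pattern, 5'->3' on the protospacer strand
#'   (default `"NGG"`, *S. pyogenes* Cas9).
#' @param spacer_length spacer length in bases (default 20).
#' @return an object of class `PamSpec`.  The `anchor` element holds the
#'   longest non-degenerate suffix of `pattern`, used for indexed lookup.
#' @export
pam_spec <- function(pattern = "NGG", spacer_length = 20L) {
  pattern <- toupper(pattern)
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) < 1 ||
      grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"),
            pattern)) {
    bescan_abort("PAM pattern must be a non-empty IUPAC string",
                 "bescan_argument_error")
  }
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 1) {
    bescan_abort("spacer_length must be a positive integer",
                 "bescan_argument_error")
  }
  cs <- chars(pattern)
  concrete <- cs %in% DNA_BASES
  anchor_from <- {
    run <- rev(cumprod(rev(concrete)))  # 1 while suffix is all-concrete
    which(run == 1)[1]
  }
  anchor <- if (is.na(anchor_from)) "" else
    substr(pattern, anchor_from, nchar(pattern))
  structure(list(pattern = pattern, spacer_length = spacer_length,
                 anchor = anchor),
            class = "PamSpec")
}

# Strand-local <-> forward interval conversion for one contig of length len.
local_to_fwd <- function(strand, local_start, local_end, len) {
  if (strand == "+") c(local_start, local_end)
  else c(len - local_end, len - local_start)
}

#' Find PAM sites inside a target region
#'
#' Reports every position on either strand where the full IUPAC PAM pattern
#' matches concrete genome bases (N in the genome matches nothing) and the
#' PAM lies entirely inside `region`.  Located by exact anchor lookup in the
#' suffix index followed by validation of the degenerate positions; when the
#' pattern has no concrete suffix the region is scanned directly.
#'
#' @param index a [build_suffix_index()] object built from `records`.
#' @param records the genome records.
#' @param pam a [pam_spec()].
#' @param region a [target_region()].
#' @return data frame with columns `contig_id`, `strand`, `pam_start`,
#'   `pam_end` (forward 0-based half-open), ordered by position then strand.
#' @export
find_pam_sites <- function(index, records, pam, region) {
  L <- nchar(pam$pattern)
  rec <- get_record(records, region$contig_id)
  len <- rec$length
  fwd <- rec$sequence
  rcs <- revcomp(fwd)

  cand <- NULL  # strand-local PAM starts per strand
  if (nchar(pam$anchor) > 0) {
    a_len <- nchar(pam$anchor)
    a_off <- L - a_len
    hits <- find_exact(index, pam$anchor)
    hits <- hits[hits$contig_id == region$contig_id, , drop = FALSE]
    if (nrow(hits) > 0) {
      local_anchor <- ifelse(hits$strand == "+", hits$start,
                             len - hits$start - a_len)
      cand <- data.frame(strand = hits$strand,
                         local = as.integer(local_anchor - a_off),
                         stringsAsFactors = FALSE)
    }
  } else {
    # fully degenerate pattern: every in-bounds position is a candidate
    cand <- rbind(
      data.frame(strand = "+", local = 0:(len - L)),
      data.frame(strand = "-", local = 0:(len - L))
    )
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      pam_start = integer(0), pam_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  cand <- cand[cand$local >= 0 & cand$local + L <= len, , drop = FALSE]

  keep <- logical(nrow(cand))
  pam_fwd <- matrix(0L, nrow(cand), 2)
  pat_chars <- chars(pam$pattern)
  for (i in seq_len(nrow(cand))) {
    s <- cand$strand[i]
    lo <- cand$local[i]
    sseq <- if (s == "+") fwd else rcs
    site <- substr(sseq, lo + 1L, lo + L)
    keep[i] <- all(iupac_char_match(chars(site), pat_chars))
    pam_fwd[i, ] <- local_to_fwd(s, lo, lo + L, len)
  }
  inside <- pam_fwd[, 1] >= region$start & pam_fwd[, 2] <= region$end
  keep <- keep & inside
  out <- data.frame(
    contig_id = rep(region$contig_id, sum(keep)),
    strand = cand$strand[keep],
    pam_start = pam_fwd[keep, 1],
    pam_end = pam_fwd[keep, 2],
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

#' Extract spacer+PAM guide candidates from PAM sites
#'
#' One candidate is produced per PAM site with at least `spacer_length`
#' bases available 5' of the PAM on its strand within the contig; candidates
#' whose spacer contains N are discarded.  All sequences are reported 5'->3'
#' on the protospacer strand; coordinates are forward 0-based half-open.
#'
#' @param records the genome records.
#' @param pam_sites data frame from [find_pam_sites()].
#' @param pam a [pam_spec()].
#' @param seed_length seed region length, the PAM-proximal bases of the
#'   spacer used for off-target counting (default 13).
#' @return a `guide_set` data frame, one row per candidate, with columns
#'   `contig_id`, `strand`, `spacer_start`, `spacer_end`, `pam_start`,
#'   `pam_end`, `spacer_seq`, `pam_seq`, `seed_seq`.
#' @export
extract_candidates <- function(records, pam_sites, pam, seed_length = 13L) {
  seed_length <- as.integer(seed_length)
  sl <- pam$spacer_length
  if (seed_length < 1 || seed_length > sl) {
    bescan_abort("seed_length must be in 1..spacer_length",
                 "bescan_argument_error")
  }
  rows <- vector("list", nrow(pam_sites))
  for (i in seq_len(nrow(pam_sites))) {
    ct <- pam_sites$contig_id[i]
    s <- pam_sites$strand[i]
    rec <- get_record(records, ct)
    len <- rec$length
    L <- pam_sites$pam_end[i] - pam_sites$pam_start[i]
    local_pam <- if (s == "+") pam_sites$pam_start[i] else
      len - pam_sites$pam_end[i]
    if (local_pam < sl) next  # not enough upstream bases for a full spacer
    sseq <- strand_seq(rec, s)
    spacer_local <- c(local_pam - sl, local_pam)
    spacer_seq <- substr(sseq, spacer_local[1] + 1L, spacer_local[2])
    if (grepl("N", spacer_seq, fixed = TRUE)) next
    pam_seq <- substr(sseq, local_pam + 1L, local_pam + L)
    seed_seq <- substr(spacer_seq, sl - seed_length + 1L, sl)
    spacer_fwd <- local_to_fwd(s, spacer_local[1], spacer_local[2], len)
    rows[[i]] <- data.frame(
      contig_id = ct, strand = s,
      spacer_start = spacer_fwd[1], spacer_end = spacer_fwd[2],
      pam_start = pam_sites$pam_start[i], pam_end = pam_sites$pam_end[i],
      spacer_seq = spacer_seq, pam_seq = pam_seq, seed_seq = seed_seq,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    data.frame(contig_id = character(0), strand = character(0),
               spacer_start = integer(0), spacer_end = integer(0),
               pam_start = integer(0), pam_end = integer(0),
               spacer_seq = character(0), pam_seq = character(0),
               seed_seq = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("guide_set", "data.frame")
  out
}

# Forward 0-based start of a candidate's seed occurrence on its own strand.
seed_fwd_start <- function(guides, records) {
  vapply(seq_len(nrow(guides)), function(i) {
    if (guides$strand[i] == "+") {
      guides$pam_start[i] - nchar(guides$seed_seq[i])
    } else {
      guides$pam_end[i]
    }
  }, integer(1))
}

#' Attach off-target seed histograms to guide candidates
#'
#' For each candidate, counts genome-wide matches of its seed sequence on
#' both strands at 0..`d_max` mismatches and removes the candidate's own
#' genomic occurrence from the 0-mismatch bin (exactly once).  With
#' `require_pam = TRUE` only off-target loci that are themselves immediately
#' 5' of a matching PAM are counted (stricter than the default genome-wide
#' uniqueness count).
#'
#' @param index a [build_suffix_index()] object over the same genome.
#' @param guides a `guide_set` from [extract_candidates()].
#' @param d_max maximum mismatch count (default 3).
#' @param require_pam require PAM adjacency at off-target loci.
#' @param pam,records needed when `require_pam = TRUE`.
#' @return `guides` with integer columns `off_0` .. `off_<d_max>` added.
#' @export
attach_offtargets <- function(index, guides, d_max = 3L, require_pam = FALSE,
                              pam = NULL, records = NULL) {
  d_max <- as.integer(d_max)
  counts <- matrix(0L, nrow(guides), d_max + 1L)
  if (require_pam && (is.null(pam) || is.null(records))) {
    bescan_abort("require_pam needs 'pam' and 'records'",
                 "bescan_argument_error")
  }
  self_start <- if (nrow(guides)) seed_fwd_start(guides, records = NULL)
  for (i in seq_len(nrow(guides))) {
    seed <- guides$seed_seq[i]
    w <- nchar(seed)
    hits <- find_with_mismatches(index, seed, d_max)
    is_self <- hits$contig_id == guides$contig_id[i] &
      hits$strand == guides$strand[i] &
      hits$start == self_start[i] &
      hits$mismatches == 0L
    if (sum(is_self) != 1L) {
      bescan_abort(
        sprintf("guide %s:%d(%s): on-target seed occurrence not found",
                guides$contig_id[i], guides$pam_start[i], guides$strand[i]),
        "bescan_internal_error"
      )
    }
    hits <- hits[!is_self, , drop = FALSE]
    if (require_pam && nrow(hits) > 0) {
      ok <- vapply(seq_len(nrow(hits)), function(j) {
        rec <- get_record(records, hits$contig_id[j])
        len <- rec$length
        local <- if (hits$strand[j] == "+") hits$start[j] else
          len - hits$start[j] - w
        pl <- local + w
        if (pl + nchar(pam$pattern) > len) return(FALSE)
        sseq <- strand_seq(rec, hits$strand[j])
        iupac_match(substr(sseq, pl + 1L, pl + nchar(pam$pattern)),
                    pam$pattern)
      }, logical(1))
      hits <- hits[ok, , drop = FALSE]
    }
    counts[i, ] <- tabulate(hits$mismatches + 1L, nbins = d_max + 1L)
  }
  for (k in 0:d_max) guides[[paste0("off_", k)]] <- counts[, k + 1L]
  guides
}
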