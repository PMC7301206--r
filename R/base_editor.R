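# Base-editor (CRISPR-BEST style) deamination simulation.
#
# A cytidine (C->T) or adenine (A->G) deaminase fused to a Cas9 nickase
# converts source bases on the protospacer strand -- the strand carrying
# spacer+PAM, which is displaced as single-stranded DNA during R-loop
# formation -- within a window counted upstream from the PAM.  With the
# defaults (window 13..20 bases upstream of the PAM on a 20-nt spacer) the
# window is spacer positions 1-8 from the 5' end.  All source bases in the
# window are converted simultaneously; each changed codon of an overlapping
# CDS is reported as one outcome under the standard genetic code.

#' Base editor specification
#'
#' @param conversion `"C_to_T"` (cytidine deaminase, CRISPR-cBEST) or
#'   `"A_to_G"` (adenine deaminase, CRISPR-aBEST).
#' @param window_min,window_max edit window bounds as distances in bases
#'   upstream of the PAM, inclusive; base 1 is immediately PAM-proximal.
#'   Defaults 13 and 20.
#' @return an object of class `EditorSpec`.
#' @export
editor_spec <- function(conversion = c("C_to_T", "A_to_G"),
                        window_min = 13L, window_max = 20L) {
  conversion <- match.arg(conversion)
  window_min <- as.integer(window_min)
  window_max <- as.integer(window_max)
  if (is.na(window_min) || is.na(window_max) || window_min < 1 ||
      window_min > window_max) {
    bescan_abort("need 1 <= window_min <= window_max",
                 "bescan_argument_error")
  }
  structure(list(conversion = conversion, window_min = window_min,
                 window_max = window_max),
            class = "EditorSpec")
}

empty_outcomes <- function() {
  data.frame(
    feature_ref = character(0), codon_index = integer(0),
    ref_codon = character(0), alt_codon = character(0),
    ref_aa = character(0), alt_aa = character(0),
    is_stop_gain = logical(0), is_synonymous = logical(0),
    stringsAsFactors = FALSE
  )
}

editor_source_base <- function(editor) {
  if (editor$conversion == "C_to_T") "C" else "A"
}
editor_target_base <- function(editor) {
  if (editor$conversion == "C_to_T") "T" else "G"
}

#' Genomic interval of a guide's edit window
#'
#' @param guide one-row slice of a `guide_set`.
#' @param editor an [editor_spec()].
#' @param records the genome records (for contig lengths).
#' @return integer vector `c(window_start, window_end)`, forward 0-based
#'   half-open.
#' @export
compute_edit_window <- function(guide, editor, records) {
  sl <- guide$spacer_end - guide$spacer_start
  if (editor$window_max > sl) {
    bescan_abort("edit window extends past the spacer",
                 "bescan_argument_error")
  }
  rec <- get_record(records, guide$contig_id)
  len <- rec$length
  local_pam <- if (guide$strand == "+") guide$pam_start else
    len - guide$pam_end
  local <- c(local_pam - editor$window_max,
             local_pam - editor$window_min + 1L)
  local_to_fwd(guide$strand, local[1], local[2], len)
}

#' Editable base positions of a guide
#'
#' Forward 0-based positions inside the edit window whose
#' protospacer-strand base equals the editor's source base (so, on a minus
#' strand guide, forward positions carrying the complement).
#'
#' @inheritParams compute_edit_window
#' @return integer vector of forward positions (possibly empty).
#' @export
editable_positions <- function(guide, editor, records) {
  win <- compute_edit_window(guide, editor, records)
  rec <- get_record(records, guide$contig_id)
  if (win[1] >= win[2]) return(integer(0))
  fwd_slice <- chars(substr(rec$sequence, win[1] + 1L, win[2]))
  want <- if (guide$strand == "+") editor_source_base(editor) else
    comp_base(editor_source_base(editor))
  win[1] + which(fwd_slice == want) - 1L
}

# Spliced coding sequence of a feature plus the forward genomic position of
# every coding base, in coding (5'->3' on the coding strand) order.
feature_coding_map <- function(record, feature) {
  gpos <- unlist(lapply(seq_len(nrow(feature$intervals)), function(k) {
    seq.int(feature$intervals[k, 1], feature$intervals[k, 2] - 1L)
  }))
  fwd_chars <- chars(record$sequence)[gpos + 1L]
  if (feature$strand == "-") {
    gpos <- rev(gpos)
    fwd_chars <- comp_base(rev(fwd_chars))
  }
  list(gpos = gpos, coding = fwd_chars)
}

#' Simulate the deamination outcome of one guide
#'
#' All editable positions in the edit window are converted simultaneously on
#' the protospacer strand (the complementary strand observes the
#' complementary change).  For every CDS whose spliced sequence contains at
#' least one edited base, each changed codon yields one outcome row under
#' the standard genetic code; edits outside any CDS yield no outcome.  An
#' incomplete terminal codon is skipped with a warning if edited.
#'
#' @inheritParams compute_edit_window
#' @return data frame with one row per changed codon: `feature_ref`,
#'   `codon_index` (0-based within the CDS), `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `is_stop_gain`, `is_synonymous`.
#' @export
simulate_edits <- function(guide, editor, records) {
  empty <- empty_outcomes()
  pos <- editable_positions(guide, editor, records)
  if (length(pos) == 0) return(empty)
  rec <- get_record(records, guide$contig_id)

  # forward-strand replacement base at the edited positions
  fwd_new <- if (guide$strand == "+") editor_target_base(editor) else
    comp_base(editor_target_base(editor))

  out <- list()
  for (fi in seq_along(rec$features)) {
    f <- rec$features[[fi]]
    cm <- feature_coding_map(rec, f)
    hit <- match(pos, cm$gpos)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) next
    alt <- cm$coding
    # an edit on the coding strand keeps the base identity; on the opposite
    # strand the coding sequence sees the complement change
    alt[hit] <- if (f$strand == guide$strand) editor_target_base(editor) else
      comp_base(editor_target_base(editor))
    off <- f$codon_start_offset
    if (length(cm$coding) <= off) next
    ref_cds <- cm$coding[(off + 1L):length(cm$coding)]
    alt_cds <- alt[(off + 1L):length(alt)]
    n_codon <- length(ref_cds) %/% 3L
    rem <- length(ref_cds) %% 3L
    if (rem > 0L) {
      tail_idx <- (n_codon * 3L + 1L):length(ref_cds)
      if (any(ref_cds[tail_idx] != alt_cds[tail_idx])) {
        warning(sprintf(
          "feature '%s': edited base in incomplete terminal codon skipped",
          feature_ref(f, fi)), call. = FALSE)
      }
    }
    if (n_codon == 0L) next
    ref_codons <- vapply(seq_len(n_codon), function(k) {
      paste(ref_cds[(3L * k - 2L):(3L * k)], collapse = "")
    }, character(1))
    alt_codons <- vapply(seq_len(n_codon), function(k) {
      paste(alt_cds[(3L * k - 2L):(3L * k)], collapse = "")
    }, character(1))
    changed <- which(ref_codons != alt_codons)
    for (k in changed) {
      ref_aa <- translate_codon(ref_codons[k])
      alt_aa <- translate_codon(alt_codons[k])
      out[[length(out) + 1L]] <- data.frame(
        feature_ref = feature_ref(f, fi),
        codon_index = k - 1L,
        ref_codon = ref_codons[k], alt_codon = alt_codons[k],
        ref_aa = ref_aa, alt_aa = alt_aa,
        is_stop_gain = (alt_aa == "*" && ref_aa != "*"),
        is_synonymous = (ref_aa == alt_aa),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Classify a guide from its simulated outcomes
#'
#' @param outcomes data frame from [simulate_edits()].
#' @return list with logical elements `can_edit` (at least one
#'   amino-acid-changing outcome; guides whose edits are all synonymous --
#'   "conservative" -- are flagged `FALSE` rather than removed) and
#'   `introduces_stop` (at least one stop-gain outcome).
#' @export
classify_guide <- function(outcomes) {
  list(
    can_edit = nrow(outcomes) > 0 && any(outcomes$ref_aa != outcomes$alt_aa),
    introduces_stop = nrow(outcomes) > 0 && any(outcomes$is_stop_gain)
  )
}

#' Annotate a guide set with base-editor outcomes
#'
#' Adds edit-window coordinates, editable positions, per-codon outcomes and
#' the `can_edit` / `introduces_stop` flags to every candidate.  With
#' `editor = NULL` (plain CRISPR mode) the columns are added empty/false.
#'
#' @param guides a `guide_set` from [extract_candidates()].
#' @param records the genome records.
#' @param editor an [editor_spec()], or `NULL` for no base-editor annotation.
#' @return `guides` with columns `window_start`, `window_end`,
#'   `editable_pos` (list), `outcomes` (list of data frames), `can_edit`,
#'   `introduces_stop` added.
#' @export
annotate_guides <- function(guides, records, editor) {
  n <- nrow(guides)
  ws <- we <- rep(NA_integer_, n)
  ep <- vector("list", n)
  oc <- vector("list", n)
  can <- stop_ <- logical(n)
  for (i in seq_len(n)) {
    g <- guides[i, , drop = FALSE]
    if (is.null(editor)) {
      ep[[i]] <- integer(0)
      oc[[i]] <- empty_outcomes()
      next
    }
    win <- compute_edit_window(g, editor, records)
    ws[i] <- win[1]; we[i] <- win[2]
    ep[[i]] <- editable_positions(g, editor, records)
    oc[[i]] <- simulate_edits(g, editor, records)
    cls <- classify_guide(oc[[i]])
    can[i] <- cls$can_edit
    stop_[i] <- cls$introduces_stop
  }
  guides$window_start <- ws
  guides$window_end <- we
  guides$editable_pos <- ep
  guides$outcomes <- oc
  guides$can_edit <- can
  guides$introduces_stop <- stop_
  guides
}
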