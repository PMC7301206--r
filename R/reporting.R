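# Filtering, ranking and CSV export of annotated guides.

#' Filter annotated guides by editing capability
#'
#' @param guides an annotated `guide_set` (see [annotate_guides()]).
#' @param mode `"all"` (no filter), `"edit"` (guides causing at least one
#'   amino acid change) or `"stop"` (guides introducing a STOP codon).
#' @return the filtered `guide_set`; always `stop` ⊆ `edit` ⊆ `all`.
#' @export
filter_guides <- function(guides, mode = c("all", "edit", "stop")) {
  if (length(mode) != 1 || !mode %in% c("all", "edit", "stop")) {
    bescan_abort("mode must be one of 'all', 'edit', 'stop'",
                 "bescan_argument_error")
  }
  keep <- switch(mode,
    all = rep(TRUE, nrow(guides)),
    edit = guides$can_edit,
    stop = guides$introduces_stop
  )
  guides[keep, , drop = FALSE]
}

#' Restrict guides to those editing one gene
#'
#' Keeps guides whose edit window overlaps any interval of the named feature
#' (gene name, locus tag or protein ID); a single base of overlap counts.
#'
#' @param guides an annotated `guide_set`.
#' @param records the genome records.
#' @param feature_query feature identifier.
#' @return the restricted `guide_set`.
#' @export
restrict_to_gene <- function(guides, records, feature_query) {
  if (grepl("^([^:]+:)?[0-9,]+-[0-9,]+$", trimws(feature_query))) {
    bescan_abort("restrict_to_gene expects a feature query, not a range",
                 "bescan_argument_error")
  }
  region <- resolve_target(records, feature_query)
  # all intervals of the matched feature
  rec <- get_record(records, region$contig_id)
  iv <- NULL
  for (f in rec$features) {
    if (isTRUE(f$gene_name == feature_query) ||
        isTRUE(f$locus_tag == feature_query) ||
        isTRUE(f$protein_id == feature_query)) {
      iv <- f$intervals
      break
    }
  }
  keep <- vapply(seq_len(nrow(guides)), function(i) {
    if (guides$contig_id[i] != region$contig_id) return(FALSE)
    ws <- guides$window_start[i]; we <- guides$window_end[i]
    if (is.na(ws)) return(FALSE)
    any(iv[, 1] < we & iv[, 2] > ws)
  }, logical(1))
  guides[keep, , drop = FALSE]
}

#' Sort guides by off-target specificity
#'
#' Ascending lexicographic order on the off-target histogram
#' `(off_0, off_1, off_2, off_3)` -- fewest exact off-targets first, then
#' fewest 1-mismatch neighbours, and so on -- with ties broken by
#' `(contig_id, spacer_start, strand)`.
#'
#' @param guides a `guide_set` with off-target counts attached.
#' @return the same rows, reordered.
#' @export
sort_guides <- function(guides) {
  o <- order(guides$off_0, guides$off_1, guides$off_2, guides$off_3,
             guides$contig_id, guides$spacer_start, guides$strand)
  guides[o, , drop = FALSE]
}

#' Flatten annotated guides into a report table
#'
#' One row per guide with 1-based inclusive spacer coordinates, the
#' off-target histogram, the edited genes and the amino acid changes in
#' `REF<codon>ALT` notation (1-based codon position, `*` for stop), e.g.
#' `"Q74*"`.
#'
#' @param guides an annotated `guide_set`.
#' @return plain data frame with the fixed column set `contig`, `start`,
#'   `end`, `strand`, `spacer`, `pam`, `offtargets_0` .. `offtargets_3`,
#'   `genes`, `aa_changes`, `introduces_stop`.
#' @export
guides_report <- function(guides) {
  n <- nrow(guides)
  genes <- character(n)
  changes <- character(n)
  for (i in seq_len(n)) {
    oc <- guides$outcomes[[i]]
    if (!is.null(oc) && nrow(oc) > 0) {
      genes[i] <- paste(unique(oc$feature_ref), collapse = ";")
      changes[i] <- paste(
        sprintf("%s%d%s", oc$ref_aa, oc$codon_index + 1L, oc$alt_aa),
        collapse = ";"
      )
    }
  }
  data.frame(
    contig = guides$contig_id,
    start = guides$spacer_start + 1L,
    end = guides$spacer_end,
    strand = guides$strand,
    spacer = guides$spacer_seq,
    pam = guides$pam_seq,
    offtargets_0 = guides$off_0,
    offtargets_1 = guides$off_1,
    offtargets_2 = guides$off_2,
    offtargets_3 = guides$off_3,
    genes = genes,
    aa_changes = changes,
    introduces_stop = if (n) guides$introduces_stop else logical(0),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a guide report as CSV
#'
#' RFC 4180 style CSV with a header line; byte output is deterministic for a
#' fixed input.
#'
#' @param rows data frame from [guides_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_guides_csv <- function(rows, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) {
                    bescan_abort(sprintf("cannot write '%s': %s", path,
                                         conditionMessage(e)),
                                 "bescan_io_error")
                  })
  on.exit(close(con))
  write.csv(rows, con, row.names = FALSE, quote = TRUE, eol = "\r\n")
  invisible(path)
}
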