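# Shared helpers: tiny hand-written GenBank fixtures and hit normalisation.

# Canonical form for hit/site data frames so set comparisons are stable.
canon <- function(df) {
  df <- as.data.frame(df)
  class(df) <- "data.frame"
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# A minimal hand-written GenBank record (written without write_genbank so
# parser tests do not depend on the writer).
gb_text_single_cds <- function(contig = "tcontig", locus_tag = "TST_0001",
                               location = "1..30") {
  seq60 <- "atgaaacccgggtttacgtacgtacgttaa"
  c(
    sprintf("LOCUS       %s 30 bp    DNA     linear   BCT 01-JAN-2026", contig),
    "DEFINITION  hand-written parser fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    sprintf("     CDS             %s", location),
    sprintf("                     /locus_tag=\"%s\"", locus_tag),
    "                     /gene=\"actVA\"",
    "                     /protein_id=\"TSTP0001.1\"",
    "                     /codon_start=1",
    "ORIGIN",
    sprintf("%9d %s", 1L, seq60),
    "//"
  )
}

write_gb_tmp <- function(lines) {
  path <- tempfile(fileext = ".gbk")
  writeLines(lines, path)
  path
}

# Build a one-row guide_set entry by hand (for base-editor unit tests that
# do not need the PAM scanner).
manual_guide <- function(contig_id, strand, pam_start, pam_end,
                         spacer_start, spacer_end) {
  g <- data.frame(
    contig_id = contig_id, strand = strand,
    spacer_start = as.integer(spacer_start),
    spacer_end = as.integer(spacer_end),
    pam_start = as.integer(pam_start), pam_end = as.integer(pam_end),
    spacer_seq = NA_character_, pam_seq = NA_character_,
    seed_seq = NA_character_, stringsAsFactors = FALSE
  )
  class(g) <- c("guide_set", "data.frame")
  g
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
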