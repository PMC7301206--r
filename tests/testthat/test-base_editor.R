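test_that("editor_spec validates the window geometry", {
  e <- editor_spec()
  expect_equal(e$conversion, "C_to_T")
  expect_equal(c(e$window_min, e$window_max), c(13L, 20L))
  expect_error(editor_spec(window_min = 0), class = "bescan_argument_error")
  expect_error(editor_spec(window_min = 9, window_max = 8),
               class = "bescan_argument_error")
})

test_that("compute_edit_window mirrors correctly across strands", {
  recs <- list(genome_record("c", strrep("A", 200)))
  # + strand, PAM forward [100,103), defaults: window = forward [80,88)
  g <- manual_guide("c", "+", 100, 103, 80, 100)
  expect_equal(compute_edit_window(g, editor_spec(), recs), c(80L, 88L))
  # - strand, PAM forward [10,13): window = forward [25,33)
  g <- manual_guide("c", "-", 10, 13, 13, 33)
  expect_equal(compute_edit_window(g, editor_spec(), recs), c(25L, 33L))
  # degenerate single-base window adjacent to the PAM
  g <- manual_guide("c", "+", 100, 103, 80, 100)
  expect_equal(compute_edit_window(g, editor_spec(window_min = 1,
                                                  window_max = 1), recs),
               c(99L, 100L))
  # window larger than the spacer is rejected
  expect_error(compute_edit_window(g, editor_spec(window_max = 21), recs),
               class = "bescan_argument_error")
})

test_that("editable_positions selects source bases on the protospacer strand", {
  # forward window [80,84) = "CCGA"
  seq <- paste0(strrep("A", 80), "CCGA", strrep("A", 40))
  recs <- list(genome_record("c", seq))
  ed <- editor_spec(window_min = 17, window_max = 20)
  g <- manual_guide("c", "+", 100, 103, 80, 100)
  expect_equal(editable_positions(g, ed, recs), c(80L, 81L))

  # - strand guide: window forward slice "GGAT" = Cs on the protospacer strand
  seq <- paste0(strrep("A", 25), "GGAT", strrep("A", 40))
  recs <- list(genome_record("c", seq))
  ed <- editor_spec(window_min = 13, window_max = 16)
  g <- manual_guide("c", "-", 10, 13, 13, 33)
  expect_equal(editable_positions(g, ed, recs), c(25L, 26L))

  # no source bases in the window
  recs <- list(genome_record("c", strrep("A", 200)))
  g <- manual_guide("c", "+", 100, 103, 80, 100)
  expect_equal(editable_positions(g, editor_spec(), recs), integer(0))
})

# Helper: simulate a single-base edit at 0-based position b of `seq` with a
# CDS at [cds_start, cds_end) on cds_strand, using a guide on guide_strand
# whose single-base edit window covers exactly b.
simulate_one <- function(seq, b, cds_start, cds_end, cds_strand,
                         guide_strand, conversion) {
  n <- nchar(seq)
  recs <- list(genome_record("c", seq, list(
    gene_feature(matrix(c(cds_start, cds_end), ncol = 2), cds_strand)
  )))
  ed <- editor_spec(conversion, window_min = 1, window_max = 1)
  g <- if (guide_strand == "+") {
    manual_guide("c", "+", b + 1, b + 4, b - 19, b + 1)
  } else {
    manual_guide("c", "-", b - 3, b, b, b + 20)
  }
  simulate_edits(g, ed, recs)
}

test_that("codon-level consequences follow the standard genetic code", {
  pad <- function(codon) paste0(strrep("A", 30), codon, strrep("A", 30))
  # CAA with first C edited, C_to_T: TAA, Q -> *, stop gain
  oc <- simulate_one(pad("CAA"), 30, 30, 33, "+", "+", "C_to_T")
  expect_equal(oc$alt_codon, "TAA")
  expect_equal(c(oc$ref_aa, oc$alt_aa), c("Q", "*"))
  expect_true(oc$is_stop_gain)
  # CGA -> TGA, R -> *
  oc <- simulate_one(pad("CGA"), 30, 30, 33, "+", "+", "C_to_T")
  expect_equal(oc$alt_codon, "TGA")
  expect_true(oc$is_stop_gain)
  # CTG -> TTG is synonymous (L -> L)
  oc <- simulate_one(pad("CTG"), 30, 30, 33, "+", "+", "C_to_T")
  expect_equal(c(oc$ref_aa, oc$alt_aa), c("L", "L"))
  expect_true(oc$is_synonymous)
  expect_false(classify_guide(oc)$can_edit)
})

test_that("both Cs of a codon are edited simultaneously", {
  # CCG with both Cs in the window -> TTG, P -> L, one outcome row
  seq <- paste0(strrep("A", 30), "CCG", strrep("A", 30))
  recs <- list(genome_record("c", seq, list(
    gene_feature(matrix(c(30L, 33L), ncol = 2), "+")
  )))
  ed <- editor_spec("C_to_T", window_min = 1, window_max = 2)
  g <- manual_guide("c", "+", 32, 35, 12, 32)  # window = [30,32)
  oc <- simulate_edits(g, ed, recs)
  expect_equal(nrow(oc), 1L)
  expect_equal(oc$alt_codon, "TTG")
  expect_equal(c(oc$ref_aa, oc$alt_aa), c("P", "L"))
})

test_that("opposite-strand editing converts TGG codons to stops", {
  # CDS on +, guide on -: protospacer C -> T appears as G -> A on coding
  # strand; editing TGG's middle G gives TAG (W -> *)
  seq <- paste0(strrep("A", 30), "TGG", strrep("A", 30))
  oc <- simulate_one(seq, 31, 30, 33, "+", "-", "C_to_T")
  expect_equal(oc$ref_codon, "TGG")
  expect_equal(oc$alt_codon, "TAG")
  expect_true(oc$is_stop_gain)

  # CDS on -, guide on +: forward C inside a minus-strand TGG codon
  # forward "CCA" at [30,33) reads TGG on the - strand
  seq <- paste0(strrep("A", 30), "CCA", strrep("T", 30))
  oc <- simulate_one(seq, 31, 30, 33, "-", "+", "C_to_T")
  expect_equal(oc$ref_codon, "TGG")
  expect_equal(oc$alt_codon, "TAG")
  expect_true(oc$is_stop_gain)
})

test_that("A_to_G conversions translate correctly", {
  seq <- paste0(strrep("C", 30), "AAA", strrep("C", 30))
  oc <- simulate_one(seq, 30, 30, 33, "+", "+", "A_to_G")
  expect_equal(oc$alt_codon, "GAA")
  expect_equal(c(oc$ref_aa, oc$alt_aa), c("K", "E"))
})

test_that("edits outside any CDS and synonymous-only guides are flagged", {
  seq <- paste0(strrep("A", 30), "CCC", strrep("A", 30))
  recs <- list(genome_record("c", seq))  # no features
  ed <- editor_spec("C_to_T", window_min = 1, window_max = 3)
  g <- manual_guide("c", "+", 33, 36, 13, 33)
  oc <- simulate_edits(g, ed, recs)
  expect_equal(nrow(oc), 0L)
  cls <- classify_guide(oc)
  expect_false(cls$can_edit)
  expect_false(cls$introduces_stop)
})

test_that("incomplete terminal codons are skipped with a warning", {
  # CDS of 4 bases: one full codon + 1 trailing base carrying the edit
  seq <- paste0(strrep("A", 30), "TTTC", strrep("A", 30))
  recs <- list(genome_record("c", seq, list(
    gene_feature(matrix(c(30L, 34L), ncol = 2), "+")
  )))
  ed <- editor_spec("C_to_T", window_min = 1, window_max = 1)
  g <- manual_guide("c", "+", 34, 37, 14, 34)
  expect_warning(oc <- simulate_edits(g, ed, recs), "incomplete terminal")
  expect_equal(nrow(oc), 0L)
})

test_that("codon_start offsets shift the reading frame", {
  # offset 1: coding sequence starts one base in; CAA sits at [31,34)
  seq <- paste0(strrep("A", 30), "GCAA", strrep("A", 30))
  recs <- list(genome_record("c", seq, list(
    gene_feature(matrix(c(30L, 34L), ncol = 2), "+",
                 codon_start_offset = 1L)
  )))
  ed <- editor_spec("C_to_T", window_min = 1, window_max = 1)
  b <- 31L
  g <- manual_guide("c", "+", b + 1, b + 4, b - 19, b + 1)
  oc <- simulate_edits(g, ed, recs)
  expect_equal(oc$ref_codon, "CAA")
  expect_equal(oc$alt_codon, "TAA")
  expect_equal(oc$codon_index, 0L)
})

test_that("exhaustive single-substitution truth over all codons", {
  codons <- names(Biostrings::GENETIC_CODE)
  gc <- Biostrings::GENETIC_CODE
  pad_l <- 30L
  cases <- list(
    list(conv = "C_to_T", src = "C", tgt = "T", guide_strand = "+"),
    list(conv = "C_to_T", src = "G", tgt = "A", guide_strand = "-"),
    list(conv = "A_to_G", src = "A", tgt = "G", guide_strand = "+"),
    list(conv = "A_to_G", src = "T", tgt = "C", guide_strand = "-")
  )
  stop_gain_ct <- character(0)
  for (cs in cases) {
    for (codon in codons) {
      for (j in 0:2) {
        if (substr(codon, j + 1, j + 1) != cs$src) next
        seq <- paste0(strrep("A", pad_l), codon, strrep("A", pad_l))
        b <- pad_l + j
        oc <- simulate_one(seq, b, pad_l, pad_l + 3L, "+", cs$guide_strand,
                           cs$conv)
        expect_equal(nrow(oc), 1L)
        expected_alt <- codon
        substr(expected_alt, j + 1, j + 1) <- cs$tgt
        expect_equal(oc$alt_codon, expected_alt)
        expect_equal(oc$ref_aa, unname(gc[codon]))
        expect_equal(oc$alt_aa, unname(gc[expected_alt]))
        if (cs$conv == "C_to_T" && cs$guide_strand == "+" &&
            oc$is_stop_gain) {
          stop_gain_ct <- c(stop_gain_ct,
                            paste0(codon, ">", expected_alt))
        }
      }
    }
  }
  # the complete coding-strand C->T stop-gain set
  expect_setequal(stop_gain_ct, c("CAA>TAA", "CAG>TAG", "CGA>TGA"))
})

test_that("strand consistency: mirrored genomes give identical outcomes", {
  fix <- make_editing_fixture(56)
  recs <- fix$records
  n <- recs[[1]]$length
  # mirror the genome and its features
  mfeats <- lapply(recs[[1]]$features, function(f) {
    gene_feature(cbind(n - f$intervals[, 2], n - f$intervals[, 1]),
                 if (f$strand == "+") "-" else "+",
                 locus_tag = f$locus_tag, gene_name = f$gene_name,
                 protein_id = f$protein_id,
                 codon_start_offset = f$codon_start_offset)
  })
  mrecs <- list(genome_record("synctg", revcomp(recs[[1]]$sequence), mfeats))
  query <- sprintf("1-%d", n)
  r1 <- run_bescan(recs, query, mode = "all")
  r2 <- run_bescan(mrecs, query, mode = "all")
  m2 <- r2
  m2$strand <- ifelse(r2$strand == "+", "-", "+")
  m2$start <- n - r2$end + 1L
  m2$end <- n - r2$start + 1L
  cols <- c("strand", "start", "end", "spacer", "pam", "offtargets_0",
            "offtargets_1", "offtargets_2", "offtargets_3", "aa_changes",
            "introduces_stop")
  expect_equal(canon(r1[, cols]), canon(m2[, cols]))
})
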