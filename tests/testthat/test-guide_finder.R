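test_that("pam_spec extracts the longest non-degenerate anchor", {
  expect_equal(pam_spec("NGG")$anchor, "GG")
  expect_equal(pam_spec("NNGRRT")$anchor, "T")   # R is degenerate
  expect_equal(pam_spec("TTTV")$anchor, "")      # degenerate suffix
  expect_equal(pam_spec("NNNN")$anchor, "")
  expect_equal(pam_spec("ACGT")$anchor, "ACGT")
  expect_error(pam_spec(""), class = "bescan_argument_error")
  expect_error(pam_spec("NGG", 0), class = "bescan_argument_error")
})

test_that("find_pam_sites locates NGG sites inside the region", {
  recs <- list(genome_record("c1", "AAACGGAAA"))
  idx <- build_suffix_index(recs)
  sites <- find_pam_sites(idx, recs, pam_spec("NGG"),
                          target_region("c1", 0, 9))
  expect_equal(sites$strand, "+")
  expect_equal(sites$pam_start, 3L)
  expect_equal(sites$pam_end, 6L)

  # region excluding the GG dinucleotide
  empty <- find_pam_sites(idx, recs, pam_spec("NGG"),
                          target_region("c1", 0, 4))
  expect_equal(nrow(empty), 0L)

  # N in the genome at the degenerate PAM position matches nothing
  recs2 <- list(genome_record("c2", "AANGGAA"))
  idx2 <- build_suffix_index(recs2)
  sites2 <- find_pam_sites(idx2, recs2, pam_spec("NGG"),
                           target_region("c2", 0, 7))
  expect_equal(nrow(sites2), 0L)
})

test_that("fully degenerate PAM patterns degrade to a full scan", {
  recs <- list(genome_record("c1", "ACGTACGTAC"))
  idx <- build_suffix_index(recs)
  sites <- find_pam_sites(idx, recs, pam_spec("NN"),
                          target_region("c1", 0, 10))
  expect_equal(nrow(sites), 18L)  # 9 windows per strand
})

test_that("anchor-based PAM search equals the regex oracle", {
  set.seed(404)
  for (k in 1:15) {
    fix <- make_genome(4000 + k, length = 1200, gc_content = 0.55,
                       n_genes = 1)
    idx <- build_suffix_index(fix$records)
    n <- fix$records[[1]]$length
    a <- sample(0:(n - 200), 1)
    region <- target_region("synctg", a, a + sample(100:200, 1))
    pat <- sample(c("NGG", "NAG", "TTN", "NNGRRT"), 1)
    expect_equal(
      canon(find_pam_sites(idx, fix$records, pam_spec(pat), region)),
      canon(oracle_pam_scan(fix$records, pat, region))
    )
  }
})

test_that("extract_candidates applies strand-correct adjacency arithmetic", {
  set.seed(99)
  seq <- random_dna_str(150)
  recs <- list(genome_record("c1", seq))
  pam <- pam_spec("NGG")

  # + strand PAM at forward [100,103): spacer [80,100), seed [87,100)
  sites <- data.frame(contig_id = "c1", strand = "+",
                      pam_start = 100L, pam_end = 103L,
                      stringsAsFactors = FALSE)
  g <- extract_candidates(recs, sites, pam)
  expect_equal(c(g$spacer_start, g$spacer_end), c(80L, 100L))
  expect_equal(g$spacer_seq, substr(seq, 81, 100))
  expect_equal(g$seed_seq, substr(seq, 88, 100))

  # - strand PAM at forward [10,13): spacer at forward [13,33), revcomp
  sites <- data.frame(contig_id = "c1", strand = "-",
                      pam_start = 10L, pam_end = 13L,
                      stringsAsFactors = FALSE)
  g <- extract_candidates(recs, sites, pam)
  expect_equal(c(g$spacer_start, g$spacer_end), c(13L, 33L))
  expect_equal(g$spacer_seq, revcomp(substr(seq, 14, 33)))
  expect_equal(g$seed_seq, revcomp(substr(seq, 14, 26)))
  expect_equal(g$pam_seq, revcomp(substr(seq, 11, 13)))

  # insufficient upstream bases: no candidate
  sites <- data.frame(contig_id = "c1", strand = "+",
                      pam_start = 5L, pam_end = 8L, stringsAsFactors = FALSE)
  expect_equal(nrow(extract_candidates(recs, sites, pam)), 0L)

  # spacer containing N is discarded
  seqN <- paste0(substr(seq, 1, 90), "N", substr(seq, 92, 150))
  recsN <- list(genome_record("c1", seqN))
  sites <- data.frame(contig_id = "c1", strand = "+",
                      pam_start = 100L, pam_end = 103L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(extract_candidates(recsN, sites, pam)), 0L)
})

test_that("candidate enumeration matches the naive oracle on random fixtures", {
  set.seed(505)
  for (k in 1:10) {
    fix <- make_genome(7000 + k, length = 900, gc_content = 0.5, n_genes = 1)
    idx <- build_suffix_index(fix$records)
    region <- target_region("synctg", 0, fix$records[[1]]$length)
    pam <- pam_spec("NGG")
    sites <- find_pam_sites(idx, fix$records, pam, region)
    guides <- extract_candidates(fix$records, sites, pam)
    guides <- attach_offtargets(idx, guides)
    truth <- oracle_guide_truth(fix$records, region)
    expect_equal(
      canon(guides[, c("strand", "pam_start", "spacer_seq",
                       "off_0", "off_1", "off_2", "off_3")]),
      canon(truth[, c("strand", "pam_start", "spacer_seq",
                      "off_0", "off_1", "off_2", "off_3")])
    )
    # every candidate finds itself before self-exclusion
    for (i in seq_len(nrow(guides))) {
      h <- mismatch_histogram(idx, guides$seed_seq[i], 0)
      expect_gte(unname(h["0"]), 1L)
    }
  }
})

test_that("attach_offtargets removes the self hit exactly once", {
  fix <- make_offtarget_fixture(31, copies = integer(0),
                                mismatches = integer(0))
  idx <- build_suffix_index(fix$records)
  region <- target_region("synctg", 0, fix$records[[1]]$length)
  pam <- pam_spec("NGG")
  guides <- extract_candidates(fix$records,
                               find_pam_sites(idx, fix$records, pam, region),
                               pam)
  guides <- attach_offtargets(idx, guides)
  tg <- fix$truth$planted_guides
  planted <- guides[guides$pam_start == tg$pam_start &
                      guides$strand == tg$strand, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(unname(unlist(planted[, c("off_0", "off_1", "off_2",
                                         "off_3")])),
               c(0L, 0L, 0L, 0L))
})

test_that("planted off-target copies appear in the right histogram bins", {
  fix <- make_offtarget_fixture(32, copies = c(1L, 2L),
                                mismatches = c(0L, 3L))
  idx <- build_suffix_index(fix$records)
  tg <- fix$truth$planted_guides
  h <- mismatch_histogram(idx, tg$seed_seq, 3)
  h["0"] <- h["0"] - 1L  # self
  expect_equal(unname(h), c(1L, 0L, 0L, 2L))

  # planting on the minus strand gives the same histogram (strand symmetry)
  fix2 <- make_offtarget_fixture(33, copies = 1L, mismatches = 2L)
  set.seed(1234)
  fix2b <- plant_offtarget(fix2, "guide", n_copies = 1L, mismatches = 2L,
                           strand = "-")
  expect_true(verify_planted_offtargets(fix2b))
})

test_that("require_pam keeps only PAM-adjacent off-target loci", {
  # guide planted with CGG; one exact seed copy with PAM, one without
  set.seed(77)
  fix <- make_genome(606, length = 1500, gc_content = 0.5, n_genes = 0)
  spacer <- "GATCCATGCTAAGCTTGACT"  # non-periodic
  seed <- substr(spacer, 8, 20)
  # copy A: seed followed by TGG (PAM-adjacent)
  fix <- bescan:::write_slice(fix, 100L, paste0(seed, "TGG"))
  fix <- bescan:::mark_occupied(fix, 100L, 116L)
  # copy B: seed followed by TTT (no PAM)
  fix <- bescan:::write_slice(fix, 200L, paste0(seed, "TTT"))
  fix <- bescan:::mark_occupied(fix, 200L, 216L)
  fix <- plant_guide_site(fix, spacer = spacer, label = "g")
  idx <- build_suffix_index(fix$records)
  region <- target_region("synctg", 0, fix$records[[1]]$length)
  pam <- pam_spec("NGG")
  guides <- extract_candidates(fix$records,
                               find_pam_sites(idx, fix$records, pam, region),
                               pam)
  tg <- fix$truth$planted_guides
  sel <- guides$pam_start == tg$pam_start & guides$strand == tg$strand
  loose <- attach_offtargets(idx, guides)
  strict <- attach_offtargets(idx, guides, require_pam = TRUE, pam = pam,
                              records = fix$records)
  expect_equal(loose$off_0[sel], 2L)
  expect_equal(strict$off_0[sel], 1L)
  expect_true(all(strict$off_0 <= loose$off_0))
})
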