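# Deterministic synthetic genomes with planted guides, off-targets and CDSs.
#
# Every generator is a pure function of its `rng_seed`: the same seed
# reproduces byte-identical GenBank output and truth tables.  Truth tables
# record what was planted; before a fixture is used to test the pipeline,
# the naive oracle (see naive_oracle.R) re-derives every entry, and builders
# that plant off-target copies regenerate on accidental background
# collisions, as detected by that scan.
#
# The editing fixture ([make_editing_fixture()]) needs *exact* guide truth,
# so its background is generated without GG or CC dinucleotides on the
# forward strand (hence no NGG PAM on either strand outside planted
# cassettes) and its genes are built from safe filler codons; every PAM in
# such a fixture is planted deliberately.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0))
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE == "*"]

random_dna <- function(n, gc_content) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Background without GG/CC dinucleotides on the forward strand: after a G
# the next base is drawn from {A,C,T}, after a C from {A,G,T}.
random_dna_no_gg_cc <- function(n, gc_content = 0.5) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2, G = gc_content / 2,
         T = (1 - gc_content) / 2)
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    allowed <- switch(prev,
                      G = c("A", "C", "T"),
                      C = c("A", "G", "T"),
                      DNA_BASES)
    w <- p[allowed] / sum(p[allowed])
    out[i] <- sample(allowed, 1, prob = w)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

new_fixture <- function(record, rng_seed) {
  structure(
    list(
      records = list(record),
      truth = list(
        rng_seed = rng_seed,
        planted_guides = data.frame(
          label = character(0), contig_id = character(0),
          strand = character(0), pam_start = integer(0),
          seed_seq = character(0),
          off_0 = integer(0), off_1 = integer(0), off_2 = integer(0),
          off_3 = integer(0),
          can_edit = logical(0), introduces_stop = logical(0),
          stringsAsFactors = FALSE
        )
      ),
      occupied = matrix(integer(0), ncol = 2)
    ),
    class = "bescan_fixture"
  )
}

mark_occupied <- function(fix, start, end) {
  fix$occupied <- rbind(fix$occupied, c(as.integer(start), as.integer(end)))
  fix
}

pick_free_slot <- function(fix, width, margin = 25L, tries = 500L) {
  len <- fix$records[[1]]$length
  lo <- margin
  hi <- len - width - margin
  if (hi <= lo) {
    bescan_abort("fixture too small for requested planting",
                 "bescan_argument_error")
  }
  for (t in seq_len(tries)) {
    s <- sample(lo:hi, 1)
    if (nrow(fix$occupied) == 0 ||
        all(s + width + margin <= fix$occupied[, 1] |
            s - margin >= fix$occupied[, 2])) {
      return(s)
    }
  }
  bescan_abort("no free slot found (infeasible packing)",
               "bescan_argument_error")
}

write_slice <- function(fix, start, value) {
  seq <- fix$records[[1]]$sequence
  substr(seq, start + 1L, start + nchar(value)) <- value
  fix$records[[1]]$sequence <- seq
  fix
}

add_truth_guide <- function(fix, label, strand, pam_start, seed_seq = NA,
                            hist = rep(NA_integer_, 4), can_edit = NA,
                            introduces_stop = NA) {
  fix$truth$planted_guides <- rbind(fix$truth$planted_guides, data.frame(
    label = label, contig_id = fix$records[[1]]$contig_id,
    strand = strand, pam_start = as.integer(pam_start),
    seed_seq = seed_seq,
    off_0 = hist[1], off_1 = hist[2], off_2 = hist[3], off_3 = hist[4],
    can_edit = can_edit, introduces_stop = introduces_stop,
    stringsAsFactors = FALSE
  ))
  fix
}

#' Generate a synthetic annotated genome
#'
#' Background bases are i.i.d. with the requested GC content; genes are
#' non-overlapping CDSs with a valid start codon, internal sense codons, a
#' stop codon and a length divisible by three, on random strands.  All
#' generation is a pure function of `rng_seed`.
#'
#' @param rng_seed integer seed.
#' @param length contig length in bases (>= 200).
#' @param gc_content background GC fraction in (0, 1).
#' @param n_genes number of CDS features to plant.
#' @param path optional path; when given the genome is also written as a
#'   GenBank file re-readable by [read_genbank()].
#' @return a `bescan_fixture`: list with `records` (one
#'   [genome_record()]), `truth` (seed + planted-guide table) and the
#'   occupied-interval ledger used by the planting functions.
#' @export
make_genome <- function(rng_seed, length = 5000L, gc_content = 0.5,
                        n_genes = 3L, path = NULL) {
  length <- as.integer(length)
  if (length < 200L) {
    bescan_abort("fixture genomes must be >= 200 bp", "bescan_argument_error")
  }
  if (gc_content <= 0 || gc_content >= 1) {
    bescan_abort("gc_content must be in (0, 1)", "bescan_argument_error")
  }
  set.seed(rng_seed)
  seq <- random_dna(length, gc_content)
  rec <- genome_record("synctg", seq)
  fix <- new_fixture(rec, rng_seed)

  features <- list()
  for (g in seq_len(n_genes)) {
    n_codons <- sample(15:40, 1)
    glen <- 3L * n_codons
    start <- pick_free_slot(fix, glen, margin = 40L)
    strand <- sample(c("+", "-"), 1)
    body <- paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                  collapse = "")
    gene_local <- paste0("ATG", body, sample(STOP_CODONS, 1))
    fwd_seq <- if (strand == "+") gene_local else revcomp(gene_local)
    fix <- write_slice(fix, start, fwd_seq)
    fix <- mark_occupied(fix, start, start + glen)
    features[[g]] <- gene_feature(
      intervals = matrix(c(start, start + glen), ncol = 2),
      strand = strand,
      locus_tag = sprintf("SYN_%04d", g),
      gene_name = sprintf("syn%s", LETTERS[g]),
      protein_id = sprintf("SYNP%04d.1", g)
    )
  }
  fix$records[[1]] <- genome_record("synctg", fix$records[[1]]$sequence,
                                    features)
  fix$truth$planted_features <- features
  if (!is.null(path)) {
    write_genbank(fix$records, path)
    fix$path <- path
  }
  fix
}

#' Plant a full guide site (spacer + PAM) in a fixture
#'
#' Writes `spacer` immediately followed by a CGG PAM at a free background
#' position, on the requested strand, and records the planted guide in the
#' truth table with an expected all-zero off-target histogram (verify with
#' the naive oracle; collisions with random background must be handled by
#' the caller, see [make_offtarget_fixture()]).
#'
#' @param fix a `bescan_fixture`.
#' @param spacer 20-nt spacer (default: random A/C/G/T).
#' @param strand strand to plant on.
#' @param label truth-table label.
#' @return the updated fixture.
#' @export
plant_guide_site <- function(fix, spacer = NULL, strand = "+",
                             label = "guide") {
  if (is.null(spacer)) {
    spacer <- paste(sample(DNA_BASES, 20, replace = TRUE), collapse = "")
  }
  sl <- nchar(spacer)
  block <- paste0(spacer, "CGG")
  width <- nchar(block)
  start <- pick_free_slot(fix, width, margin = 30L)
  len <- fix$records[[1]]$length
  fwd_block <- if (strand == "+") block else revcomp(block)
  fix <- write_slice(fix, start, fwd_block)
  fix <- mark_occupied(fix, start, start + width)
  pam_start <- if (strand == "+") start + sl else start
  seed <- substr(spacer, sl - 12L, sl)
  add_truth_guide(fix, label, strand, pam_start, seed_seq = seed,
                  hist = c(0L, 0L, 0L, 0L),
                  can_edit = FALSE, introduces_stop = FALSE)
}

# Mutate exactly `k` distinct positions of a DNA string (substitutions to a
# different base, positions ascending for reproducibility).
mutate_seq <- function(x, k) {
  cs <- chars(x)
  at <- sort(sample(seq_along(cs), k))
  for (i in at) cs[i] <- sample(setdiff(DNA_BASES, cs[i]), 1)
  paste(cs, collapse = "")
}

#' Plant off-target copies of a planted guide's seed
#'
#' Inserts `n_copies` copies of the labelled guide's 13-bp seed, each with
#' exactly `mismatches` substitutions, at free background positions (on the
#' forward or reverse strand) and updates the guide's expected histogram.
#'
#' @param fix a `bescan_fixture` containing a guide planted with
#'   [plant_guide_site()].
#' @param label label of the planted guide.
#' @param n_copies number of copies to insert.
#' @param mismatches Hamming distance of each copy from the seed (0..3).
#' @param strand strand to plant on (default: random per copy).
#' @return the updated fixture.
#' @export
plant_offtarget <- function(fix, label, n_copies = 1L, mismatches = 0L,
                            strand = NULL) {
  if (mismatches < 0L || mismatches > 3L) {
    bescan_abort("mismatches must be in 0..3", "bescan_argument_error")
  }
  tg <- fix$truth$planted_guides
  row <- which(tg$label == label)
  if (length(row) != 1) {
    bescan_abort(sprintf("no planted guide labelled '%s'", label),
                 "bescan_not_found_error")
  }
  seed <- tg$seed_seq[row]
  for (cp in seq_len(n_copies)) {
    s <- if (is.null(strand)) sample(c("+", "-"), 1) else strand
    variant <- mutate_seq(seed, mismatches)
    start <- pick_free_slot(fix, nchar(variant), margin = 25L)
    fwd <- if (s == "+") variant else revcomp(variant)
    fix <- write_slice(fix, start, fwd)
    fix <- mark_occupied(fix, start, start + nchar(variant))
    col <- paste0("off_", mismatches)
    fix$truth$planted_guides[row, col] <-
      fix$truth$planted_guides[row, col] + 1L
  }
  fix
}

#' Verify planted off-target truth with the naive oracle
#'
#' Recomputes every planted guide's seed histogram with
#' [oracle_mismatch_histogram()] (self-occurrence removed) and compares it
#' with the truth table.
#'
#' @param fix a `bescan_fixture`.
#' @return `TRUE` if every expected histogram matches, else `FALSE`.
#' @export
verify_planted_offtargets <- function(fix) {
  tg <- fix$truth$planted_guides
  for (i in seq_len(nrow(tg))) {
    if (is.na(tg$off_0[i])) next
    h <- oracle_mismatch_histogram(fix$records, tg$seed_seq[i], 3L)
    h["0"] <- h["0"] - 1L
    if (!identical(unname(as.integer(h)),
                   as.integer(c(tg$off_0[i], tg$off_1[i], tg$off_2[i],
                                tg$off_3[i])))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Build an off-target fixture with verified truth
#'
#' Generates a gene-free background, plants one guide and the requested
#' off-target copies, and verifies the resulting histogram with the naive
#' oracle; on an accidental background collision the whole fixture is
#' regenerated (deterministically) with the next derived seed.
#'
#' @param rng_seed integer seed.
#' @param copies,mismatches parallel integer vectors: plant `copies[k]`
#'   copies at `mismatches[k]` mismatches.
#' @param length background length in bases.
#' @param max_tries regeneration attempts before giving up.
#' @return a verified `bescan_fixture`.
#' @export
make_offtarget_fixture <- function(rng_seed, copies = c(1L, 1L),
                                   mismatches = c(0L, 3L), length = 2000L,
                                   max_tries = 50L) {
  stopifnot(length(copies) == length(mismatches))
  for (t in seq_len(max_tries)) {
    fix <- make_genome(rng_seed + 100003L * (t - 1L), length = length,
                       gc_content = 0.5, n_genes = 0L)
    fix <- plant_guide_site(fix, label = "guide")
    for (k in seq_along(copies)) {
      fix <- plant_offtarget(fix, "guide", n_copies = copies[k],
                             mismatches = mismatches[k])
    }
    if (verify_planted_offtargets(fix)) return(fix)
  }
  bescan_abort("could not build a collision-free off-target fixture",
               "bescan_internal_error")
}

# ---------------------------------------------------------------------------
# Codon cassettes for base-editor truth
#
# All cassettes are written in gene-local (coding strand) coordinates and
# avoid GG/CC dinucleotides except where a PAM is intended, so that inside
# the GG/CC-free editing fixture every guide is planted.
#
# Coding-strand guide (stop codons CAA/CAG/CGA, synonymous codon CTG):
# codons i..i+6 become  <codon> ACT ACT ACT ACT GCG GCA ; the junction
# GCG|GCA supplies the only GG, giving a PAM (CGG) at local 3i+16 whose
# edit window (13..20 upstream) covers the codon's editable C at local 3i.
#
# Anti-strand guide (TGG -> stop via the template strand): codons i-6..i
# become ACC GAT GAT GAT GAT GAT TGG ; the ACC supplies a CC (= PAM GG on
# the anti strand) at local 3i-17..3i-16, and the window of that anti-strand
# guide covers both Gs of TGG, which read as editable Cs on the anti strand.

map_local_iv <- function(gs, ge, gstrand, a, b) {
  if (gstrand == "+") c(gs + a, gs + b) else c(ge - b, ge - a)
}

#' Plant a base-editable codon cassette inside a fixture gene
#'
#' Overwrites codons of gene `gene` so that one guide with a known
#' base-editing consequence exists: `"CAA"`, `"CAG"` or `"CGA"` plant a
#' C-to-T stop-gain edited from the coding strand; `"TGG"` plants a
#' stop-gain edited from the opposite strand (the tryptophan codon's Gs are
#' cytidines on the template); `"CTG"` plants a guide whose only edit is
#' synonymous (CTG to TTG, both leucine), i.e. a `can_edit = FALSE` guide.
#' The expected guide and its flags are recorded in the truth table.
#'
#' @param fix a `bescan_fixture` with planted features.
#' @param gene index of the gene to modify.
#' @param codon one of `"CAA"`, `"CAG"`, `"CGA"`, `"TGG"`, `"CTG"`.
#' @param codon_index 0-based codon position for the planted codon
#'   (default: chosen automatically near codon 15, clamped to the gene).
#' @param label truth-table label.
#' @return the updated fixture.
#' @export
plant_stop_site <- function(fix, gene, codon = c("CAA", "CAG", "CGA", "TGG",
                                                 "CTG"),
                            codon_index = NULL, label = codon) {
  codon <- match.arg(codon)
  f <- fix$truth$planted_features[[gene]]
  if (is.null(f)) {
    bescan_abort(sprintf("fixture has no gene %d", gene),
                 "bescan_not_found_error")
  }
  gs <- f$intervals[1, 1]
  ge <- f$intervals[1, 2]
  n_codons <- (ge - gs) %/% 3L
  anti <- codon == "TGG"
  if (is.null(codon_index)) {
    codon_index <- if (anti) max(7L, min(n_codons - 2L, 15L)) else
      max(2L, min(n_codons - 8L, 15L))
  }
  i <- as.integer(codon_index)
  if (anti) {
    if (i < 7L || i > n_codons - 2L) {
      bescan_abort("codon_index out of range for a TGG cassette",
                   "bescan_argument_error")
    }
  } else if (i < 2L || i > n_codons - 8L) {
    bescan_abort("codon_index out of range for this cassette",
                 "bescan_argument_error")
  }

  rec <- fix$records[[1]]
  gl <- if (f$strand == "+") substr(rec$sequence, gs + 1L, ge) else
    revcomp(substr(rec$sequence, gs + 1L, ge))

  put <- function(x, at, value) {  # gene-local 0-based replacement
    substr(x, at + 1L, at + nchar(value)) <- value
    x
  }
  if (anti) {
    gl <- put(gl, 3L * (i - 6L),
              paste0("ACC", strrep("GAT", 5), "TGG"))
    pam_iv <- map_local_iv(gs, ge, f$strand, 3L * i - 17L, 3L * i - 14L)
    gstrand <- if (f$strand == "+") "-" else "+"
    can_edit <- TRUE; introduces_stop <- TRUE
  } else {
    if (codon == "CTG") {
      # keep the edit window free of bystander Cs upstream of the codon
      gl <- put(gl, 3L * i - 4L, "T")    # last base of codon i-2
      gl <- put(gl, 3L * (i - 1L), "GAT")
    }
    gl <- put(gl, 3L * i,
              paste0(codon, strrep("ACT", 4), "GCG", "GCA"))
    pam_iv <- map_local_iv(gs, ge, f$strand, 3L * i + 16L, 3L * i + 19L)
    gstrand <- f$strand
    can_edit <- codon != "CTG"
    introduces_stop <- codon != "CTG"
  }
  fwd_gene <- if (f$strand == "+") gl else revcomp(gl)
  fix <- write_slice(fix, gs, fwd_gene)
  fix$records[[1]] <- genome_record(rec$contig_id,
                                    fix$records[[1]]$sequence,
                                    rec$features)
  add_truth_guide(fix, label, gstrand, pam_iv[1],
                  can_edit = can_edit, introduces_stop = introduces_stop)
}

#' Build an editing fixture with exact guide truth
#'
#' A GG/CC-free background (no PAM on either strand except where planted)
#' carrying four filler-codon genes -- a coding-strand stop cassette
#' (CAA/CAG/CGA rotating with the seed), the same cassette on a minus-strand
#' gene, a TGG (opposite-strand stop) cassette and a synonymous-only CTG
#' cassette -- plus one intergenic PAM with full spacer room.  Every NGG/CCN
#' PAM in the fixture is therefore planted or a construction side effect of
#' a cassette (the TGG codon itself), and the truth table plus the naive
#' oracle give the complete expected guide set.
#'
#' @param rng_seed integer seed.
#' @param length contig length (default 3000).
#' @return a `bescan_fixture` with truth rows labelled `stop_plus`,
#'   `stop_minus`, `stop_tgg`, `syn_ctg` and `intergenic`.
#' @export
make_editing_fixture <- function(rng_seed, length = 3000L) {
  set.seed(rng_seed)
  seq <- random_dna_no_gg_cc(length, gc_content = 0.5)
  fix <- new_fixture(genome_record("synctg", seq), rng_seed)

  gene_codons <- 40L
  glen <- 3L * gene_codons
  gene_local <- paste0("ATG", strrep("ACT", gene_codons - 2L), "TAA")
  strands <- c("+", "-", sample(c("+", "-"), 1), "+")
  features <- list()
  for (g in 1:4) {
    start <- pick_free_slot(fix, glen, margin = 40L)
    fwd <- if (strands[g] == "+") gene_local else revcomp(gene_local)
    fix <- write_slice(fix, start, fwd)
    fix <- mark_occupied(fix, start, start + glen)
    features[[g]] <- gene_feature(
      intervals = matrix(c(start, start + glen), ncol = 2),
      strand = strands[g],
      locus_tag = sprintf("SYN_%04d", g),
      gene_name = sprintf("syn%s", LETTERS[g])
    )
  }
  fix$records[[1]] <- genome_record("synctg", fix$records[[1]]$sequence,
                                    features)
  fix$truth$planted_features <- features

  stop_codon <- sample(c("CAA", "CAG", "CGA"), 1)
  fix <- plant_stop_site(fix, 1, stop_codon, label = "stop_plus")
  fix <- plant_stop_site(fix, 2, stop_codon, label = "stop_minus")
  fix <- plant_stop_site(fix, 3, "TGG", label = "stop_tgg")
  fix <- plant_stop_site(fix, 4, "CTG", label = "syn_ctg")

  # intergenic PAM with full spacer room and clean flanks
  q <- pick_free_slot(fix, 3L, margin = 30L)
  seqc <- fix$records[[1]]$sequence
  if (substr(seqc, q, q) == "C") fix <- write_slice(fix, q - 1L, "A")
  if (substr(fix$records[[1]]$sequence, q + 4L, q + 4L) == "G") {
    fix <- write_slice(fix, q + 3L, "A")
  }
  fix <- write_slice(fix, q, "CGG")
  fix <- mark_occupied(fix, q - 1L, q + 4L)
  fix$records[[1]] <- genome_record("synctg", fix$records[[1]]$sequence,
                                    features)
  fix <- add_truth_guide(fix, "intergenic", "+", q,
                         can_edit = FALSE, introduces_stop = FALSE)
  fix
}
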