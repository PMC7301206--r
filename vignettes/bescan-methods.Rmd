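---
title: "Designing base-editor sgRNAs with bescan: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing base-editor sgRNAs with bescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## Scope and model

`bescan` designs single guide RNAs (sgRNAs) for Cas9 and for
cytidine/adenine base editors on annotated microbial genomes.  The design
model has three parts.

**Guide geometry.** A guide is a spacer of `spacer_length` bases (default
20) lying immediately 5′ of a protospacer-adjacent motif (PAM, default
`NGG`, given as an IUPAC pattern on the protospacer strand).  Candidates are
enumerated on both strands of the target region; a PAM whose spacer would
cross the contig start is dropped — contigs are treated as linear even when
the source replicon is circular, since origin-spanning guides are not a
practical design target.  Spacers containing `N` are discarded.

**Off-target model.** Specificity is judged on the *seed*: the
`seed_length` (default 13) PAM-proximal bases of the spacer.  For each
candidate we count genomic windows on both strands whose Hamming distance to
the seed is exactly 0, 1, 2 or 3 (substitutions only — no indels; the
mismatch bound matches the variant-enumeration complexity of the search
structure).  The candidate's own locus is removed from the 0-mismatch bin,
exactly once; if a candidate fails to find itself the run aborts, since that
indicates an indexing bug rather than a design condition.  By default an
off-target locus does *not* need its own adjacent PAM — the count is a pure
uniqueness measure — but `--offtarget-require-pam` enables the stricter
variant.  Guides are ranked ascending-lexicographically on
`(n0, n1, n2, n3)`, ties broken by position, so the most unique seeds come
first.

**Editing model.** A base editor is `conversion` (C→T or A→G) plus an edit
window given as distances upstream of the PAM, inclusive: base 1 is
PAM-proximal, the defaults 13–20 correspond to spacer positions 1–8 from the
5′ end of a 20-nt spacer.  Deamination acts on the protospacer strand (the
displaced, single-stranded strand during R-loop formation), so a minus-strand
guide edits forward-strand G→A (for C→T chemistry).  *All* source bases in
the window are converted simultaneously — deaminases process every
accessible substrate, so the joint outcome is the realistic prediction —
and every changed codon of every overlapping CDS is reported as one outcome
row under the standard genetic code (tables 1 and 11 agree on all sense
codons; start-codon special casing is ignored).  Only CDS features produce
outcomes; edits in RNA genes or intergenic sequence are window-valid but
consequence-free.

Guides are classified by two flags: `can_edit` (at least one
amino-acid-changing outcome) and `introduces_stop` (at least one stop-gain).
"Conservative" edits are interpreted as *synonymous*: a guide whose edits
change no amino acid is kept in the unfiltered view but flagged
`can_edit = FALSE`, so the three report modes nest:
`stop ⊆ edit ⊆ all`.  An alternative reading of "conservative" —
biochemically similar substitutions, e.g. BLOSUM-positive — was considered
and rejected: it would make the filter scoring-matrix dependent and
non-reproducible across tools, and the stop/edit workflow only needs the
synonymous/non-synonymous distinction.

## The search structure

The index concatenates every contig's forward sequence and its reverse
complement, each segment closed by a unique sentinel symbol ordered below
the DNA alphabet, and builds a suffix array with SA-IS (induced sorting,
linear time; implemented in C++).  Indexing both strands keeps one code path
and one coordinate convention; sentinels make suffix comparison well-defined
and — because a sentinel code can never equal a pattern code — guarantee
that no reported match spans a segment boundary.

Queries descend suffix-array intervals: at depth *k* the interval holds all
suffixes sharing the chosen *k*-symbol prefix, within which symbol *k* is
non-decreasing, so each child interval costs two binary searches.  A child
equal to the pattern symbol is free; any other base (or `N`, which carries
its own code) costs one unit of the mismatch budget.  Each matching window
is reached by exactly one path, whose accumulated cost is its true Hamming
distance — so minimality of the reported mismatch count holds by
construction rather than by deduplication.  Exact search is the same descent
with budget 0.  PAM sites are found by exact lookup of the longest
non-degenerate suffix of the PAM (`GG` for `NGG`) followed by validation of
the degenerate positions against the genome; a fully degenerate pattern
degrades to a windowed scan.

`N` handling is deliberately conservative: `N` in the genome never matches
any pattern base (it always costs a mismatch) and patterns must be
`N`-free.  Ambiguity codes other than `N` are normalised to `N` on input,
with one warning per contig.

## Coordinates and formats

Internally every interval is 0-based half-open; all user-facing coordinates
(target queries, CSV output) are 1-based inclusive, matching GenBank.  A
range query `START-END` with `START == END` denotes a single base.  On
multi-contig genomes a bare range is ambiguous and must be prefixed
`contig:START-END`; feature queries (gene name, locus tag, protein ID) must
match exactly one CDS, and ambiguity is an error that lists the matches
rather than a silent first-match guess.  Multi-interval (`join`) CDSs are
supported with spliced translation; fuzzy bounds (`<`/`>`) are truncated
with a warning.  GenBank parsing is a focused flat-file reader (LOCUS /
FEATURES / ORIGIN, CDS qualifiers `locus_tag`, `gene`, `protein_id`,
`codon_start`) because the installed R stack has no GenBank parser; FASTA
goes through Biostrings.  CSV output has a fixed column set, CRLF line ends
and deterministic bytes for a fixed input.

## Synthetic data: what it emulates, what it does not

`make_genome()` draws i.i.d. background at a requested GC content (0.72
reproduces a streptomycete-like composition) and plants non-overlapping
CDSs with valid start/stop codons and no internal in-frame stops, on random
strands.  `plant_guide_site()` / `plant_offtarget()` insert a spacer+PAM
block and seed copies at exact Hamming distances; because a random
background can by chance contain additional neighbours of a 13-mer seed,
`make_offtarget_fixture()` verifies the final histogram with the naive
oracle and regenerates deterministically on collision — the truth table is
therefore sound by verification, not by hope.

`make_editing_fixture()` needs *exact* guide truth, so its background is
constrained to contain no `GG`/`CC` dinucleotide (hence no `NGG` PAM on
either strand outside planted material) and its genes are built from filler
codons with the same property.  Five guides are planted: a coding-strand
stop cassette (CAA/CAG/CGA) on a plus- and on a minus-strand gene, a TGG
cassette edited from the opposite strand, a synonymous-only CTG cassette
(CTG→TTG, leucine to leucine), and an intergenic PAM.  One construction
side effect is documented rather than hidden: the TGG codon itself contains
a `GG`, creating one additional guide whose window edits produce only
missense changes — it is part of the oracle-checked expected set and never a
stop.

Limitations of the generator, hence of what a green test establishes: no
real-genome composition beyond GC content (no codon bias, repeats, or
skew), no editing-efficiency or sequence-context model (every window source
base is treated as editable, with no TC-motif preference), linear contigs
only, and seeds/fixtures far smaller than real chromosomes.  Correctness
claims transfer to large genomes through the oracle-equivalence properties,
not through the fixtures' realism.

## Numerical and design choices

* **Joint vs independent edits.** Whether bystander bases are edited jointly
  or one at a time is ambiguous in the base-editing literature's tool
  descriptions; `bescan` edits jointly (and reports each changed codon
  separately), which matches deaminase biochemistry and never reports fewer
  changed codons than any single edit would.
* **Self-exclusion.** Only the candidate's exact seed position is excluded
  from the 0-mismatch bin; overlapping shifted windows on the same strand
  are counted as off-targets.  This is the conservative choice for a
  uniqueness measure.
* **Error taxonomy.** Argument/target errors (`bescan_argument_error`,
  `bescan_not_found_error`, `bescan_ambiguous_error`, `bescan_bounds_error`)
  exit the CLI with status 2; runtime/internal errors with 1; success 0.
* **Determinism.** All generators are pure functions of their seed;
  report CSVs are byte-stable; suffix-array hit order is canonicalised by
  (contig, strand, position).
* **Degenerate inputs.** Empty result sets are valid everywhere (an empty
  CSV still carries its header); an empty genome or pattern is an error;
  window bounds are validated against the spacer length at specification
  and again at use.

## Validation strategy

Every operation is tested against an independent implementation that shares
no code with the production path: generic-sort suffix arrays, quadratic
double-strand Hamming scans, regex PAM scans, and direct genetic-code
translation over all 64 codons × all single substitutions for both editor
chemistries and both strand configurations (the coding-strand C→T stop-gain
set is exactly CAA→TAA, CAG→TAG, CGA→TGA).  End-to-end, planted fixtures
are recovered exactly in `stop` and `edit` modes, mirrored genomes yield
mirrored guide sets with identical histograms, and genome doubling leaves
region-restricted results oracle-equal.  The acceptance suite
(`tests/testthat/test-acceptance.R`) runs these properties at the sizes
stated there; no empirical number is claimed in this vignette that those
tests do not themselves compute.
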