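# bescan

Base-editor aware sgRNA design for microbial genomes.

## The problem

CRISPR/Cas9 knock-outs rely on double-strand breaks, which destabilise the
genomes of some organisms (streptomycetes are the classic case).  Base
editors sidestep this: a cytidine (C→T) or adenine (A→G) deaminase fused to
a Cas9 nickase converts individual bases inside a narrow *edit window* of
the protospacer — by default bases 13–20 upstream of the PAM — without
cutting both strands.  A well-chosen guide can convert a sense codon into a
translational STOP (CAA→TAA, CAG→TAG, CGA→TGA on the coding strand, or TGG
edited from the template strand into TAA/TAG/TGA) and so inactivate a gene
with a single base change.

Designing such guides on a *non-model* genome needs, beyond ordinary spacer
enumeration:

1. **Off-target specificity** of each spacer's PAM-proximal 13-bp *seed*,
   counted genome-wide at 0–3 mismatches on both strands.
2. **Deamination simulation**: which source bases fall inside the edit
   window, what the simultaneously edited codons become under the standard
   genetic code, and whether any change is non-synonymous or a stop-gain.

`bescan` implements both for user-supplied GenBank (preferred, because codon
annotation needs CDS features) or FASTA genomes.

## The algorithmic core

All pattern search runs over a suffix array built with **induced sorting
(SA-IS)** — linear-time construction — on the concatenation of every
contig's forward and reverse-complement sequence, each segment terminated by
a unique sentinel ordered below the DNA alphabet.  Exact anchor lookup (the
non-degenerate suffix of the PAM, `GG` for `NGG`) costs
O(|anchor|·log|text|); bounded-mismatch seed search descends suffix-array
intervals, exploring only variants within the Hamming budget *d*, i.e.
O(a·(s·w)^d·log|text|) for alphabet size *s* = 4 and seed width *w*.  An
`N` in the genome matches nothing and always costs a mismatch.  Guides are
ranked by the off-target histogram `(n0, n1, n2, n3)` in ascending
lexicographic order — unique seeds first.

A deliberately naive oracle (regex PAM scan, quadratic Hamming scan, direct
codon translation) ships with the package and backs every property test, as
does a deterministic synthetic-genome generator that plants guides,
off-target copies at known distances, and codon cassettes with known editing
outcomes.

## Worked example

```r
library(bescan)

# a deterministic synthetic genome: 3 kb, four annotated CDSs, five planted
# guides with known base-editing consequences
fix <- make_editing_fixture(101)
write_genbank(fix$records, "example.gbk")

# design C->T base-editor guides across the whole contig and keep only
# guides that introduce a STOP codon
res <- run_bescan("example.gbk", "1-3000", editor = "cbest", mode = "stop")
print(res, row.names = FALSE)
```

```
 contig start  end strand               spacer pam offtargets_0 offtargets_1
 synctg  1390 1409      + AGTCCAATCATCATCATCAT CGG            0            0
 synctg   703  722      + TACTCGAACTACTACTACTG CGG            3           99
 synctg  1907 1926      - TACTCGAACTACTACTACTG CGG            3           99
 offtargets_2 offtargets_3    genes aa_changes introduces_stop
            2            0 SYN_0003       W16*            TRUE
            3            9 SYN_0001  T15I;R16*            TRUE
            3            9 SYN_0002  T15I;R16*            TRUE
```

Reading the first row: a plus-strand guide with spacer at bases 1390–1409
(1-based inclusive) next to a `CGG` PAM; its 13-bp seed is unique in the
genome at 0–1 mismatches (`offtargets_0/1 = 0`); simulated deamination
converts codon 16 of gene `SYN_0003` from tryptophan to a STOP (`W16*`) —
here via the template strand, the TGG special case.  The other two rows are
planted stop cassettes in two genes sharing the same cassette sequence,
hence the large mutual off-target counts (`R16*` is the intended stop;
`T15I` is a bystander edit in the same window).  On this fixture
`mode = "all"` reports 6 guides and `mode = "edit"` (any amino acid change)
4; the synonymous-only and intergenic planted guides are excluded from
`edit`, as designed.

The same run from the command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "bescan.R", package = "bescan"))') \
  find --genome example.gbk --target 1-3000 --editor cbest --mode stop \
  --out guides.csv
```

Targets can also be a locus tag, gene name or protein ID
(`--target SYN_0003`), or `--gene SYN_0003` restricts output to guides whose
edit window overlaps that gene.  `--editor none` gives classic
(non-base-editor) sgRNA design; `--offtarget-require-pam` counts only
PAM-adjacent off-target loci.

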