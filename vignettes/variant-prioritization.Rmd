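---
title: "Prioritising recessive variants from a single proband genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising recessive variants from a single proband genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprior)
```

## The problem

A rare autosomal-recessive disease observed in one individual leaves no
room for linkage or association analysis: the causal allele must be found
by filtering the proband's own variant calls. For a recessive phenotype the
prior is strong — the causal genotype should be homozygous, or compound
heterozygous with the two alleles on opposite haplotypes of one gene — and
the molecular prior is equally strong: a deleterious coding change
(frameshift, premature stop, lost start or stop, or a disrupted splice
site). `varprior` encodes that reasoning as a deterministic, fully audited
filtration cascade, together with the coordinate and consequence machinery
the filters need.

## Coordinate frames and transcript models

All coordinates are 1-based and inclusive, the shared convention of GFF3
and VCF; conversions happen only at input/output boundaries. A transcript
model is a strand, an ordered set of exon intervals, and a CDS interval.
Coding (`c.`) positions number the spliced CDS from the A of the start
codon and run in transcription direction, so on a minus-strand gene they
run genomic-descending. The package restricts `c.` numbering to the CDS:
UTR and intronic positions are classified (`utr`, `intronic` with an
offset, `intergenic`) but not given coding coordinates, because the
analysis here concerns protein-coding changes only.

GFF3 dialects disagree on whether the stop codon belongs to the CDS. The
reader accepts both and normalises to stop-inclusive: when the annotated
CDS does not end in a stop codon but the next three transcript bases do,
the interval is extended. This makes "spliced CDS length is a multiple of
3, starts ATG, ends in a stop" a deterministic invariant. Models violating
it are returned with `valid = FALSE` and a reason rather than being
dropped — real annotation sources disagree precisely at such genes, and
the concordance filter needs to see them.

Translation uses the standard genetic code, stops at (and excludes) the
first stop codon, ignores a trailing partial codon, and renders any codon
containing `N` as `X`; these degenerate-input rules are explicit so they
can be tested.

## Variant normalisation: two conventions on purpose

An indel inside a repeat has many equivalent representations. The package
keeps two deliberately distinct normal forms:

* **VCF-style left alignment** for storage and matching: shared suffix
  trimmed, variant shifted to its leftmost equivalent genomic placement,
  single anchor base. Variant identity against the control panel is the
  left-aligned key `(contig, pos, ref, alt)`, so equivalent representations
  can never evade panel subtraction.
* **HGVS-style 3' shifting on the transcript strand** for reporting, with
  the inserted sequence given in transcript orientation.

On a minus-strand gene these two rules shift the same insertion toward
opposite transcript ends, which is exactly why a published variant can
carry a genomic description (`g.…insGGGGGCCG`) and a coding description
(`c.19_20insCGGCCCCC`) whose alleles are reverse complements anchored at
different repeat boundaries. Both renderings are always available; neither
is declared canonical.

`enumerate_placements()` makes the ambiguity explicit: rolling the
insertion allele base by base (rotating the allele as it moves) yields the
contiguous run of positions after which the insertion produces a
byte-identical alternate haplotype. The test suite checks this against
exhaustive enumeration over all insertion points, using the
prefix/suffix-identity definition that admits rotated alleles — the
biologically correct reading, since an insertion arising anywhere in a
tandem repeat yields the same molecule.

## Consequence prediction

Each variant × overlapping transcript receives exactly one category.
Coding calls are made by editing the spliced CDS in transcript orientation
and translating: frameshift anatomy (first divergent residue, premature
stop, wild-type and mutant protein lengths) falls out of the same
computation rather than being inferred from arithmetic. Categories map to
impact tiers through a fixed table — HIGH for frameshift, stop gained/lost,
start lost and the two splice-site categories; MODERATE for in-frame indels
and missense; LOW for synonymous; MODIFIER otherwise. The table is fixed in
code because the source analyses rarely enumerate which categories counted
as "deleterious"; fixing it makes the filter reproducible and auditable.

Design choices worth noting:

* The splice region is the two intronic bases at each CDS-flanking
  junction only — the convention under which standard annotators assign
  HIGH — with no extended splice-region category.
* Variants spanning an exon/intron boundary take the most severe
  overlapped context, coding first, then splice; a partial-CDS deletion is
  treated as a deletion of its in-CDS bases.
* An out-of-frame indel strictly inside the CDS is *always* frameshift,
  even if it happens to introduce an immediate stop.
* A mutant CDS that never reaches a stop is reported with the translated
  length and `premature_stop = FALSE` — an explicit degenerate case, not an
  error.

## The cascade and its ledger

Stages run in a fixed order: panel subtraction, dual-source annotation,
high-impact recessive partition (primary source), compound-het gene logic,
assembly-error exclusion, dual-source concordance, candidate-gene
intersection. Each stage records `in`, `removed`, `kept` and gene counts;
conservation (`in = removed + kept`) and funnel monotonicity are asserted
in tests. Assembly-error exclusion and concordance commute — also a tested
property — so their relative order is a presentational choice matching the
narrative order of such analyses.

Three decisions deserve justification:

* **Strict MAF rule.** "Unique to the proband" is implemented as removal
  of variants with panel MAF strictly greater than the threshold (default
  0.01), not as mere presence/absence: a stated numeric rule beats an
  informal one, and boundary sites at exactly the threshold survive.
* **Unresolved phase is flagged, never promoted.** A het pair with unknown
  relative phase counts toward compound-het retention but is labelled
  `unresolved`; only same-phase-set opposite-haplotype pairs are `trans`.
  Downstream users must be able to distinguish proven trans from
  unrefuted trans.
* **Gene assignment is the union over consequence calls**, and a variant
  is removed by the assembly-error filter only if *every* gene it touches
  is flagged — overlapping-gene loci must not lose candidates.

## The synthetic-data generator

Real reference genomes and population panels are too large for desk-scale
validation, so the generator builds complete miniature worlds: two ~60 kb
contigs carrying 24 multi-exon genes on both strands (valid ORFs built by
codon-level rejection sampling, GT/AG intron boundaries), a control panel
of 100 individuals with allele counts on an exact MAF grid including the
1% boundary, and a proband callset of 200 variants. Defaults were chosen
once to keep each filter's input non-trivial while the whole world
generates in seconds; the gene count (24, of which 3 candidate, 3
assembly-flagged, 3 annotation-discordant) gives every decoy class its own
hosts without gene reuse compromising class semantics.

Each decoy class is engineered to be removed by exactly one step, and a
faithfulness test runs the cascade on single-class worlds to prove it:
panel-common stop-gain variants (MAF drawn from {2%, 5%, 25%}), private
synonymous variants (a slice also placed in the panel at or below the
threshold to exercise the strict rule), singleton high-impact
heterozygotes, cis-phased het pairs, homozygous stop-gains confined to
flagged genes, variants HIGH under source A but outside source B's
truncated CDS, and homozygous survivors in non-candidate genes that only
the candidate filter can remove. The second annotation source is emulated
by truncating 120 bp from the CDS end of the discordant genes — those
models fail the terminal-stop invariant and are carried with
`valid = FALSE`, which is how real cross-annotation disagreements look.

The causal variant is an out-of-frame insertion planted after a configured
coding position in a candidate gene. The insertion allele is resampled
until the mutant protein diverges at the first affected codon and is
truncated by a premature stop; a CDS whose shifted reading frame is
stop-free downstream of the anchor admits no truncating insertion, so the
generator falls back to the next candidate gene (and the planting function
fails loudly after a bounded number of draws rather than looping). Ground
truth records left-aligned keys — the cascade's matching convention —
because a planted indel can shift through a repeat during normalisation.

All randomness flows from a single seed through one RNG stream;
byte-identical outputs for identical configurations are asserted by
checksum. What the generator does **not** emulate: real genome composition
and repeat structure, sequencing and calling error, linkage between sites,
genotype-frequency consistency within the panel, and genome-scale variant
counts. Passing tests therefore demonstrate the correctness of the
filtering logic under its stated assumptions, not calibrated performance
on real whole-genome data.

## The emulated iduronidase transcript

For end-to-end checks of the headline molecular anatomy the package
deterministically constructs a synthetic 655-codon transcript
(`emulate_idua_cds()`): bases 4–19 are two tandem copies of `CGGCCCCC`, so
an insertion of that 8-mer reported after c.19 is equivalently placeable
after any base from c.3 to c.19; base 20 breaks the repeat so the run ends
at 19; codon 7 is chosen so the first mutant codon changes the amino acid;
and the shifted reading frame is built stop-free through mutant codon 108
with a stop at codon 109, giving a 108-residue truncated product against
the 655-residue wild type. Placed on the minus strand of a small contig
(`emulate_idua_world()`), the same insertion reads `GGGGGCCG` in genomic
coordinates — the reverse complement of the transcript-strand allele. This
is a synthetic stand-in that models only the repeat context and frame
anatomy, not the real gene's sequence; projections to real chromosome
coordinates require the real reference and are out of scope here.

## Numerical and degenerate-input choices

* Variants at a contig's first base cannot extend left and are anchored on
  the following base instead.
* Half-calls (`./1`) and missing genotypes are excluded from the zygosity
  partition but counted; symbolic/breakend ALT alleles are skipped with a
  logged count rather than mis-parsed.
* Multi-allelic records are split into bi-allelic variants with genotype
  indices remapped (other alternates fold to reference for the row under
  consideration).
* Panel minor allele frequency is folded to `[0, 0.5]`
  (`min(AF, 1 - AF)`).
* Ties in report ordering are broken by `(contig, pos, alt)` so repeated
  runs are byte-identical.

## Problem sizes used in validation

The shipped tests run the full cascade on 20 planted and 20 causal-free
worlds of the default 200-variant scenario, compare compound-het retention
with brute-force enumeration on 1,000 random fixtures, check mutant
translation against an apply-then-translate oracle on 500 random indels,
verify placement runs against exhaustive enumeration on 1,000 contexts up
to 50 bp, and confirm left-alignment idempotence on 1,000 random indels.
These sizes were chosen as the smallest that exercise every code path and
failure mode repeatedly; the pipeline itself is linear in callset size and
has no stochastic components outside the generator.

## Known limitations

Only the recessive mode is implemented — no dominant, X-linked or de novo
logic, no pedigree support. Structural variants, CNVs and gVCF blocks are
out of scope, as are UTR/regulatory annotation, conservation scores,
protein-domain lookup and nonsense-mediated-decay prediction. The two
annotation "sources" are two transcript sets run through one consequence
engine: the concordance filter models annotation disagreement, not
algorithmic disagreement between independent annotators. Phase is
consumed, not computed; read-backed phasing must come from upstream tools.
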