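---
title: "Methods: panel-wide variant characterization on a synthetic resequencing panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-wide variant characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`panelvar` characterizes genome-wide variation across a panel of re-sequenced
genotypes against a common reference: small variants (SNPs and 1–58 bp
indels), their distribution and coding effects, per-gene copy-number and
presence/absence variation from sequencing depth, and larger "miscellaneous"
rearrangements — inter-chromosomal translocations (CTX), intra-chromosomal
translocations (ITX) and inversions (INV) — from discordant read-pair
geometry. Real panels of this kind (for example, parental lines of crop
mapping populations) are hundreds of gigabases of reads; the raw data behind
such studies are rarely re-runnable at desk scale. The package therefore
ships a fully specified synthetic-panel generator with a machine-readable
truth set, so that every stage of the pipeline is validated end to end by
planted-truth recovery rather than by unverifiable summary numbers.

## The retention and classification rules

A per-genotype call is retained when its phred quality strictly exceeds 30
and at least 5 reads support it, and when no other call of the same genotype
lies within 5 bp (anchor-position distance). Three choices here were
genuinely open and are fixed as follows:

* **Both members** of a too-close pair are removed. The rule names no
  survivor; symmetric removal is order-independent and matches a brute-force
  all-pairs neighbour scan, which the test suite checks on random inputs.
* Flank distance is measured between VCF `POS` anchors, not allele end
  coordinates, and the rule is applied **per genotype**, not on the merged
  panel.
* Multi-allelic records are reduced to their first alternate allele.
  Multi-nucleotide substitutions and events longer than 58 bp are classed
  `OTHER`: they are excluded from every SNP/indel statistic but kept, so
  that `input = kept + removed + other` always reconciles.

## The panel matrix and its statistics

Union sites (chromosome, position, ref, alt) across genotypes form the rows
of a sites × genotypes genotype matrix. A genotype without a record at a
union site is called homozygous-reference **only where its depth profile
covers the site with at least 5 reads**, and missing otherwise; depth is the
only confidence signal available for a reference call, and the line-specific
rule below leans on it. Without depth profiles the fallback is
homozygous-reference.

* **Line-specific variant**: the alternate allele (het or hom-alt) in exactly
  one genotype and confident hom-ref in all others; a single missing call
  disqualifies the site.
* **Heterozygosity rate**: het / (het + hom-alt) over a genotype's SNP
  calls — this reproduces the 0–1 scale such studies report.
* **Pairwise SNP count**: SNP sites where two genotypes' calls disagree and
  neither is missing. Counting disagreements (rather than unions of
  alternate alleles) measures polymorphism usable between a pair, which is
  what pairwise tables in mapping studies are for.
* **Indel ratio**: insertions / deletions per genotype, reported as absent
  when a genotype has no deletions.

Densities are computed over **union sites** in fixed, non-sliding 100 kb
windows anchored at coordinate zero (the last window may be short), and per
pseudomolecule as sites per kb. The polymorphism rate adds indel sites to
SNP sites; the surplus of the rate over the SNP density is exactly the indel
density, which mirrors how such paired numbers behave in published per-
pseudomolecule tables.

## Effect annotation

One transcript per gene. The region of a variant anchor is `EXON` inside a
CDS, `OTHER` for untranslated exon positions (and for indels spanning a CDS
boundary, whose behaviour no convention fixes), `INTRON` inside a gene span
otherwise, else `INTERGENIC`. For a coding SNP the affected codon is rebuilt
on the coding strand (reverse-complemented for minus-strand genes) and both
codons translated with the standard genetic code: same amino acid is
synonymous (a stop staying a stop is `SYNONYMOUS_STOP`), sense→stop is
`STOP_GAINED`, stop→sense at the terminal codon is `STOP_LOST`, other
changes are `NON_SYNONYMOUS_CODING`. At the initiator ATG, a change into an
alternative start codon (CTG, TTG, GTG) is `NON_SYNONYMOUS_START` and any
other change `START_LOST` — the conventional split used by variant-effect
predictors, which keeps ATG→ATA a start loss. Coding indels are
`FRAME_SHIFT` unless their length is a multiple of three
(`CODON_INSERTION` / `CODON_DELETION`). Summaries group mis-sense
(non-synonymous coding + start), non-sense (stop gained) and silent
(synonymous coding + stop).

A reference-allele mismatch between a record and the genome is a hard error
by design: it is the cheapest tripwire for coordinate bugs.

The annotator is validated two ways: against an independent oracle that
mutates the chromosome, re-extracts the CDS from the GFF intervals,
re-translates the whole protein and diffs it; and by strand-mirror symmetry
(annotating a reverse-complemented genome gives identical classes).

## CNV/PAV calling from depth

Only genes of at least 1,000 bp are considered. Per gene and genotype the
package computes **breadth** (fraction of gene-span bases covered by ≥ 1
read) and the **depth ratio** (mean depth over the gene span divided by the
genotype's genome-wide median depth). Presence/absence uses breadth:
< 10 % is `ABSENT`, > 50 % `PRESENT`, the gap deliberately `AMBIGUOUS`
rather than forced to a side. Whether the published 10 %/50 % thresholds
apply to breadth or to normalized depth is genuinely ambiguous; breadth is
the standard PAV statistic, both statistics are always computed, and the
operand is a switch (`pav_operand`) defaulting to breadth. Duplication is
called at depth ratio ≥ 1.75 — midpoint-plus-margin between one-copy (≈ 1)
and two-copy (≈ 2) expectations; a full segmentation-based CNV caller is
out of scope, and this transparent statistic is presented as such, not as a
re-implementation of one. Events also called in the reference control
(reference reads mapped to the reference itself) are excluded as false
positives; the exclusion is idempotent.

## Structural variants from discordant pairs

Pairs with mapping quality ≥ 30 are clustered by single linkage: two pairs
join when both corresponding mate spans lie within `insert_size_mean +
3 × insert_size_sd` of each other. Clusters of ≥ 2 pairs are typed by
geometry: different mate chromosomes → CTX; identically oriented mates on
one chromosome → INV; opposite-orientation mates whose separation exceeds
the concordant insert model (or whose mate order is reversed) → ITX. The
ITX-vs-CTX geometry is nowhere defined beyond the names in the source
material; the definitions above are the standard discordant-pair reading
and are stated as the package's convention.

The probabilistic confidence score of conventional discordant-pair callers
is replaced by a transparent capped-linear score, `min(99, 20 × support)`,
sharing the 0–99 range and the same filter semantics: the "score = 99"
cutoff keeps only saturated-confidence calls (≥ 5 coherent pairs), and is
implemented as ≥ 99 so it is robust to a different cap. Calls whose
breakpoint neighbourhoods overlap any control-supported cluster are
dropped; the filter is applied before control exclusion, and the two
operations commute.

Breakpoints are refined from the innermost edges of supporting mate spans:
a `+` mate points at the junction and ends just before it (breakpoint =
max span end + 1), a `-` mate points away and starts just after it
(breakpoint = min span start, 1-based); each side uses its majority
strand. A CTX is counted on its first-side chromosome in the
type × pseudomolecule matrix, and its size is the sum of the two per-side
supporting-span extents; same-chromosome events use the breakpoint
distance.

## The synthetic-panel generator

The generator emits post-alignment evidence directly (no reads, no
aligner): a reference FASTA, gene models in GFF3, one VCF per genotype
(QUAL, GT and DP populated), per-base depth as bedGraph, discordant pairs
as a BEDPE-like table, and the truth tables. VCF/GFF3 are 1-based
inclusive; bedGraph/BEDPE are 0-based half-open; a single conversion layer
owns the transforms. Indels follow the VCF anchor-base convention.

Default study conditions: 2 pseudomolecules × 1 Mb, 20 genes (1.2–2.4 kb,
both strands, one or two exons, CDS written into the sequence with ATG
start, terminal stop, no internal stop), 5 genotypes plus a control,
SNP sites at 10⁻³ per base and indels at 10⁻⁴ (uniform lengths 1–58 bp),
heterozygous fraction 0.3, 25 line-specific variants and 3 gene deletions,
3 duplications and 3 SVs per type per genotype, 10× depth with SD 1,
read length 100, insert 400 ± 40.

Choices the generator fixes, and why:

* **Rates are panel-level union-site rates.** Shared sites are drawn once
  and assigned to ≥ 2 carrier genotypes (line-specific sites to exactly
  one); a per-genotype rate would inflate the union density by the panel
  size and break the Poisson density calibration of the union panel. With
  ≥ 2 carriers, no shared site can masquerade as line-specific, so the
  line-specific truth is exactly identifiable.
* **Exact-count spaced placement.** Site counts are Poisson per
  chromosome; positions are then placed uniformly with a minimum gap of
  `indel_length_max + 7` bases. Planted sites therefore never collide
  under the 5 bp flank rule and indel spans never overlap, while the
  Poisson count keeps densities unbiased.
* **No variants in deletion-scheduled genes.** A variant inside a gene
  deleted in some genotype cannot be confirmed hom-ref there (zero depth →
  missing), making a planted line-specific site unrecoverable by
  construction; the generator avoids creating such undecidable truth.
* **Depth is piecewise-constant over 100 bp bins**, Normal(mean, SD)
  truncated at zero and rounded. Real coverage is locally autocorrelated,
  not i.i.d. per base; bins also keep run-length-encoded profiles and
  bedGraph files compact. Deleted genes keep ≈ 4 % residual covered bases
  (a mis-mapping analog) so the < 10 % absence rule is exercised away from
  the trivial zero; duplicated genes get doubled depth.
* **Forced effect classes.** A configurable set of coding variants is
  planted by enumerating single-base codon edits and keeping one that the
  genetic code classifies as the target class (e.g. TGG→TGA for a stop
  gain); every planted edit is re-classified at generation time and the
  run aborts on disagreement, so effect truth can never drift from the
  codon table.
* **Pair geometry.** Each planted SV emits 6 supporting pairs whose inner
  edges sit within one insert-size SD of the true breakpoint (jitter is
  uniform on 0..SD), so refined breakpoints are within one SD of truth by
  construction — the property the recovery tests assert.

What the generator does **not** emulate: mapping artefacts, repeat-driven
mis-alignment, GC-dependent coverage, genotype-calling uncertainty,
multi-allelic sites, overlapping genes, isoforms, and concordant background
pairs (optional noise is off by default). Passing planted-truth recovery
therefore demonstrates that the analysis rules are implemented correctly,
not that they are robust to real-data artefacts.

## Determinism and numerical conventions

One RNG stream seeded from `config$seed` drives the four generator stages
in a fixed order; identical seed and configuration give byte-identical
files (no timestamps are written). Panel statistics are invariant to
genotype order and site order. Ties and boundaries are resolved exactly as
stated: QUAL strictly > 30, depth ≥ 5, flank < 5 removes, breadth < 0.10 /
> 0.50, indel length ≤ 58, score ≥ 99, gene length ≥ 1,000. Genome median
depth is the weighted median over run-length encoded per-base values.

## Problem sizes used in validation

The test suite exercises a small panel (2 × 0.3 Mb, 8 genes, 3 genotypes)
for unit and property tests, the default study panel (2 × 1 Mb, 20 genes,
5 genotypes, ~2,200 union sites) for end-to-end recovery and the
annotation oracle (500 random coding variants over the 20 genes), and a
calibration panel (SNP rate 0.005, no planted events, > 10,000 union
sites) for the statistical checks: heterozygosity within three binomial
SDs of 0.3, per-pseudomolecule density within three Poisson SDs of 5/kb,
and exact window-to-chromosome count conservation. These sizes were chosen
so the full suite and the acceptance script each run comfortably on a
single CPU.

## Known limitations

* Gene-level CNV/PAV only; no breakpoint-resolution CNV boundaries.
* One transcript per gene; no splice-site, UTR-distance or regulatory
  subclasses; no impact scoring or ontology lookups.
* The SV score is a support count in disguise; it ranks but does not
  calibrate confidence probabilistically.
* No imputation, phasing or population-genetic statistics — the analysis
  mirrors a descriptive panel characterization, not an inference method.
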