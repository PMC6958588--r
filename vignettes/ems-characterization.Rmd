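---
title: "Characterizing EMS-induced mutations and selecting salt-tolerant wheat lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing EMS-induced mutations and selecting salt-tolerant wheat lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emschar)
```

## The analysis problem

Ethyl methanesulfonate (EMS) mutagenesis is the workhorse of forward
genetics in crops: treated seed carries thousands of random point
mutations, and lines with a desired phenotype — here, germination under
high salinity — are recovered by screening.  Sequencing a selected line
against the unmutagenized parent then yields a catalogue of candidate
mutations, provided three confounders are dealt with:

1. **low-confidence calls** — removed by strict depth and quality filters
   (`DP > 5` and `QUAL > 20`, both exclusive);
2. **background polymorphism** — the parent line itself differs from the
   reference assembly at hundreds of thousands of sites; any variant
   shared between a mutant and the parent is subtracted so the remainder
   can be attributed to mutagenesis;
3. **caller artefacts** — EMS has a sharp chemical signature (alkylation
   of guanine fixes G:C → A:T transitions, read as G>A or C>T on the
   reference strand), so the 12-type substitution spectrum of the cleaned
   call set is itself a quality control: a credible EMS catalogue is
   dominated by G>A and C>T.

`emschar` implements this characterization pipeline — filtering,
subtraction, spectrum aggregation, mutation densities per sub-genome and
chromosome, codon-level effect classification — together with the
phenotype analytics used in the selection campaign (germination
screening, root/shoot group statistics, field-trial cut-offs and PCA).
Because the original sequencing data are not publicly deposited, the
package also ships a first-class synthetic-data module that generates
genomes, gene models, VCFs and phenotype tables with the statistical
structure the analysis assumes, including a recorded ground truth.

## The substitution spectrum and its conventions

Substitutions are classified as read off the **reference strand**: G>A
and C>T are distinct categories even though they describe the same
lesion on complementary strands.  This matches how published EMS spectra
are tabulated and is why both types are flagged `ems_canonical`.
Transitions are A↔G and C↔T; everything else is a transversion, so
`transition_share + transversion_share = 100` by construction and the
EMS-canonical share can never exceed the transition share.

```{r}
head(substitution_types(), 4)
```

The package carries the published per-type counts for the two sequenced
salt-tolerant lines (OA70, OA42; SAMtools and FreeBayes call sets) as
reference data.  Expanding a printed count table into synthetic variants
and pushing it through the aggregator reproduces the printed shares:

```{r}
counts <- ems_reference_counts("OA70", "FreeBayes")
v <- expand_type_counts(counts)
g1 <- ref_genome(Biostrings::DNAStringSet(c(chr1A = "ACGT")))
s <- aggregate_spectrum(v, g1)$summary
round(s[s$level == "genome",
        c("transition_share", "transversion_share",
          "ems_canonical_share")], 1)
```

Mutation density is reported in the field's "one change per N bases"
convention: stratum length divided by variant count, genome-wide, per
sub-genome and per chromosome.  The denominator is always the supplied
reference's actual chromosome lengths.  Published genome-wide rates for
such experiments are not exactly recomputable from published sub-genome
sizes and SNP totals (the assembly length used as denominator typically
includes unplaced scaffolds and is rarely stated); pinning the
denominator to the supplied FASTA makes the package's rates internally
consistent and reproducible, which we consider the only defensible
convention.  Chromosomes whose name carries no sub-genome letter (such
as `chrUn`) count toward the genome-wide rate but no sub-genome.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions:

* a 21-chromosome toy genome split into sub-genomes A/B/D whose total
  sizes keep the real ordering B (5.180) > A (4.935) > D (3.951),
  scaled to ~1.4 Mb (1e5 bases per Gb).  Full-genome scale is out of
  test scope; every statistic under test is scale-free (shares,
  densities, set identities).
* mutation density 1/20,000 bases; per-sample counts are Poisson with
  mean `density × genome length`, types are multinomial draws from the
  12-type spectrum (default: proportional to the OA70 FreeBayes
  counts), and each mutation is placed uniformly among positions whose
  reference base matches the type's source base, collisions re-drawn.
* background polymorphisms written into the control *and* every mutant,
  so subtraction has exactly the structure it must remove.
* noise records drawn so that the strict filters exclude exactly the
  noise set (`DP ≤ 5` or `QUAL ≤ 20`, all clean records above both
  thresholds).  This makes filter tests exact rather than statistical.
* gene models as 1–3-exon CDS features on random strands whose spliced
  coding sequence is a proper ORF.  Random sequence essentially never
  hosts long ORFs, so the generator writes the coding sequence into the
  reference and returns the edited genome alongside the gene table —
  the two are a consistent pair and must be used together.
* phenotype tables: binomial germination counts (tolerant lines
  germinate at 0.8 at 200 mM NaCl, others at 0.2, matching the
  parent's collapse to ~20–30% there); zero-truncated normal root and
  shoot lengths with the published group means and SDs; and a field
  table of 70 mutant-like lines plus two parent-control entries whose
  group means sit several SDs from the mutant cloud on germination,
  height, spike length, kernels, tillering and per-seed production.

Not emulated: read-level data (FASTQ, alignment, caller behaviour),
sequencing-error models, linkage between mutations, heterozygosity, and
any real genotype–phenotype coupling.  Passing tests therefore
demonstrate that the *analytics* are correct under the stated
statistical model, not that the model captures every property of real
resequencing data.

The per-line expected mutation count before filtering is deliberately a
free parameter (`mutation_density`): the density is calibrated to the
published per-20,000-bases figure, but raw pre-filter yields depend on
caller and coverage and are not asserted as defaults.

## Numerical and design choices

* **Multi-allelic records** are decomposed into one candidate per
  alternate allele and counted in provenance; indels and ambiguous
  bases go to rejected counts.  The provenance ledger satisfies
  `retained + filtered + rejected = parsed` at all times, so record
  loss is always visible.
* **Subtraction key** is the full `(chrom, pos, ref, alt)` tuple — the
  conservative reading of removing "common" variants; position-only
  matching is available as an option.  Site depth comes from the INFO
  `DP` field (total depth).
* **Caller sets are never intersected**: SAMtools and FreeBayes call
  sets flow through the pipeline separately, as they are reported.
* **Effect classification** uses the standard nuclear genetic code,
  hard-coded via the Biostrings code table and unit-tested.  The codon
  is located by cumulative CDS coordinates; minus-strand genes
  reverse-complement, so a genomic G>A reads as C>T on the coding
  strand.  Stop-loss is reported as non-synonymous with a `stop_lost`
  flag (the three-way scheme has no such class).  When genes overlap,
  all per-gene calls are retained and summaries take the most severe
  (nonsense > non-synonymous > synonymous).  The three-way fractions
  are computed over coding calls only, and the non-synonymous to
  synonymous ratio is reported as a plain unitless ratio (≈1.57 for
  fractions of 59.7/38.1) — a percentage makes no sense for it.
* **Welch's t-test** is the default for root/shoot group comparison:
  the compared groups have visibly unequal SDs, and Welch is the safe
  default when the variance assumption is unverifiable.  The
  pooled-variance test is available (`var_equal = TRUE`).  Published
  p-values for such tables are not reconstruction targets because the
  per-group n is not stated.  Identical constant groups return t = 0,
  p = 1 by convention.
* **Germination threshold** comparison is inclusive (≥ 70% at 200 mM
  NaCl — "or higher"); the field cut-offs follow their quoted boundary
  semantics exactly: *at least* 60% germination and ≥ 1
  tillers/germinated and ≥ 30 kernels and ≥ 1 g/germinated production
  (inclusive), spike *over* 2.54 cm, *less than* 30% fungal, *below*
  20% insect (strict).  Lines with missing fields are excluded with a
  recorded reason.
* **PCA** is a covariance eigendecomposition, not an SVD wrapper, to
  keep scores, loadings and eigenvalues exactly in the stated
  relationship: columns are centered and by default unit-scaled (the
  field variables mix counts, cm, g and %; raw-covariance mode exists
  for sensitivity work), a constant column raises an error naming it,
  and each loading column's sign is fixed so its largest-magnitude
  entry is positive, making reports run-to-run reproducible.  Outlier
  status is a score-distance ranking, not a hypothesis test.

## Problem sizes used in the checks

The automated checks run the worked example on the full 746,904-count
published table; spectrum recovery at ~50,000 simulated mutations per
seed across 20 seeds with a 3-standard-error multinomial envelope;
density recovery on a ~10 Mb genome (≈500 mutations, 3 Poisson SEs);
subtraction on noisy two-sample populations with shared background;
effect classification against a naive whole-CDS retranslation oracle on
1,000 variants over both strands; the germination screen at the study
scale of 1,676 lines with 70 truly tolerant; and the field table at 70
mutant-like lines plus 2 controls.  These sizes were chosen so each
statistical envelope is tight enough to be meaningful while the whole
suite stays desk-scale.

## Known limitations

* The simulator draws positions independently and uniformly; real EMS
  spectra show context effects and cluster structure the package does
  not model.
* Splice-site, UTR and regulatory effects are all `non_coding`; there
  is no protein-impact scoring.
* Phenotypes are simulated independently of genotypes; the package
  cannot be used to test genotype–phenotype association methods.
* Headline biological counts from the original campaign (70 tolerant
  lines out of 1,676; 17 lines past the field cut-offs) depend on
  unpublished per-line data; the package reproduces the *procedures*
  and, where the generator plants the truth, recovers it within the
  documented statistical envelopes.
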