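---
title: "indelscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{indelscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelscan)
```

## What the package models

`indelscan` re-implements, as reusable components, an analysis path that is
common in livestock genomics: insertion/deletion variants (indels) are
called from whole-genome sequencing of a small founder panel by several
independent callers; only calls concordant across callers are trusted;
surviving indels are annotated for functional consequence; candidates with
severe consequences and breed-divergent allele frequencies are genotyped in
experimental backcross populations; and each candidate is tested for
association with quantitative traits under a linear mixed model.

The concrete design mirrored throughout is an Iberian x commercial pig
cross: 2 Iberian boars and 5 Landrace sows as sequenced founders, and three
BC1 backcrosses — BC1_LD ((IB x LD) x LD, n = 160), BC1_DU (x Duroc,
n = 143), BC1_PI (x Pietrain, n = 138) — phenotyped for intramuscular
fatty-acid composition. The default synthetic trait is calibrated to
eicosadienoic acid, C20:2(n-6): mean 0.51, SD 0.14 (percentage of total
fatty acids), with an average carcass weight of 72.2 kg.

Because the original sequencing reads and array genotypes are not
desk-scale inputs, the package ships a first-class synthetic-data module
that generates every input the pipeline needs from a seeded configuration,
and the test suite holds the analysis code to account against independent
oracles on that synthetic world.

## Canonical indel representation

The same physical edit admits many VCF representations (different anchors
in a homopolymer run, padded alleles). `normalize_variants()` reduces each
record to the canonical key used by every other module: trim shared
trailing bases; whenever an allele empties, prepend the reference base to
the left and re-trim (this walks the record to its leftmost equivalent
position); finally trim shared leading bases down to a single anchor base.
Two records describe the same edit if and only if they share a key — the
property the consensus engine relies on, and which the tests verify
against a closed-form oracle that compares whole mutated sequences.

Coordinates are 1-based; an indel's `pos` is the anchor base preceding the
inserted/deleted sequence. Where callers disagree on placement we impose
left alignment for all — no caller's representation is treated as
canonical.

## Consensus and the filter cascade

`consensus_calls()` applies, in fixed order:

1. **Intersection** — a normalized key is *common* when present in all
   call-sets (three by default; any k >= 2 works).
2. **Genotype concordance** — per sample, the genotype supported by at
   least two callers is adopted (majority vote). A discard-only concordance rule would leave
   open which genotype survives; adopting the majority is the only
   self-consistent completion, and it is applied per variant: any
   sample without two-caller support discards the whole variant. Missing
   calls do not vote: one caller missing with the other two agreeing is
   concordant; a lone non-missing call is adopted; a variant missing in
   every sample is discarded as discordant.
3. **Multi-allelic / inconsistent-alternative filter** — any chromosomal
   position carrying more than one distinct alternative allele (across
   callers or samples) loses all its variants.
4. **Fixed-alternative filter** — a variant homozygous-alternative in all
   samples cannot segregate in the cross and is dropped. By default all
   samples must be non-missing hom-alt; a relaxed mode
   (`require_complete = FALSE`) drops on "all non-missing are hom-alt".

Every variant carries exactly one fate, so the accounting identity
`n_common = n_final + n_discordant + n_multiallelic + n_fixed_alt`
holds *exactly* on every input; it is asserted inside
`consensus_accounting()` and re-checked across seeds in the acceptance
suite, alongside equivalence with a brute-force oracle that applies each
edit to the sequence and compares mutated strings.

## Consequence annotation

`annotate_variants()` is a deliberately minimal effect predictor: one
annotation row per (variant, transcript) pair, with the controlled
vocabulary and severity classes (High > Moderate > Low > Modifier) frozen
in `severity_map()`. Numerical/structural choices, all documented because
the upstream description leaves them open:

- **Flank** for upstream/downstream classification: 5,000 bp.
- **Splice windows**: donor/acceptor = first/last 2 intronic bases
  (strand-aware); splice region = last 3 exonic or intronic bases 3–8 from
  a junction.
- **Coding logic** is executed on the reconstructed transcript: the edit
  is applied to the CDS, both alleles are translated, and terms follow
  from the comparison — frameshift iff indel length is not a multiple of
  3; inframe deletion/insertion otherwise; `start_lost` for edits hitting
  the start codon; stop bookkeeping (`stop_gained`, `stop_lost`,
  `stop_retained_variant`) from where stops appear in the mutant
  translation. A new stop counts as *gained* only when it appears at the
  edit locus (the first affected codon plus the inserted span plus one),
  not merely anywhere downstream of a frameshift — otherwise almost every
  frameshift would also be a stop gain, which does not match how the
  classes are tabulated in practice.
- **Boundary-spanning indels** (exon/intron) get `coding_sequence_variant`
  plus the splice term and never a frameshift call: the reading frame is
  undefined for such edits.
- **Protein changes** are reported HGVS-style (`p.Ala2del`, `p.Ala2dup`,
  `p.Glu5_Phe6delinsVal`) at the most N-terminal equivalent position:
  the longest common suffix is trimmed before the prefix, so deleting one
  residue of a repeat run is reported at the run's first position. A
  non-clean inframe change (delins) additionally gets
  `protein_altering_variant`.

The acceptance suite drives >= 14 hand-placed cases — including the
flagship pattern, a 3-bp inframe deletion reported as `p.AlaNdel` — against
a sequence-edit + translation oracle, plus the frameshift law over 1,000
random CDS indels.

## Candidate selection

`select_candidates()` returns the union of:

- **(a)** variants with a start/stop consequence (`start_lost`,
  `stop_gained`, `stop_lost`) in a gene from a user-supplied
  lipid-metabolism list, and
- **(b)** High/Moderate-severity variants at extreme founder frequencies:
  alt-allele frequency 1 in Iberian with <= 0.2 in Landrace, or 0 in
  Iberian with >= 0.8 in Landrace.

Frequencies are computed over non-missing founder alleles per breed
(denominators 4 and 10 under the default design).

## Mixed-model association

The trait model is

y = Sex + Batch + Backcross + beta * carcass_weight + u + delta * a + e,

with sex (2 levels), batch (14), backcross (3) fixed; `u` the polygenic
random effect with covariance K * sigma_u^2, where K is the centred
genomic relatedness matrix K = Xc Xc' / p (markers mean-imputed and
mean-centred); `delta` the marker code (+1 hom-reference, 0 het, -1
hom-alternative — orientation fixed by the backcross-design constraint
that an Iberian-fixed allele can never appear hom-alt in BC1_LD); and `a`
the additive effect being tested.

Estimation is the standard two-stage (EMMAX-style) approximation:
`fit_null()` estimates (sigma_u^2, sigma_e^2) once by REML, profiling the
variance ratio on the eigenbasis of K (log10 grid from -6 to 6, step
0.25, Brent refinement; the ratio is set to the boundary 0 when the grid
maximum sits there). `lmm_scan()` then tests every marker by generalized
least squares with the variance components fixed, which reduces to
weighted OLS in the rotated basis; the test is a Wald t on n - p - 1
degrees of freedom, so with sigma_u^2 = 0 the scan is *exactly* ordinary
least squares (verified to 1e-8). The fast rotated path is checked
against an explicit dense GLS oracle to 1e-6 in log10 p, and null
calibration of the type-I error at alpha = 0.01/0.05 is verified inside
the 99% binomial confidence band over 200 x 2,000 null markers at n = 400.

Marker QC drops MAF < 5% and missingness > 5%. Multiple testing is
Benjamini–Hochberg step-up per trait per scan (not pooled across traits,
which is how per-trait FDR values are conventionally reported): significant at
q <= 0.05, suggestive at q <= 0.1; the implementation is tested against a
brute-force step-up oracle and `stats::p.adjust`. Per-backcross scans drop
the backcross fixed effect and recompute kinship on the subset.
A `log2` transform is an explicit per-trait flag ("when needed" is not an
algorithmic criterion; we leave the decision to configuration).

## The synthetic world

`generate_genome()` builds uniform-random chromosomes carrying
non-overlapping genes with valid structure (ATG start, stop codon, no
internal stop, CDS length divisible by 3, >= 2 exons, UTRs).
`plant_truth_variants()` places indels and SNPs on a 120-bp spacing grid
(left-aligned, collision-free), with geometric lengths (mode 1 bp, capped
at 54 bp for deletions and 32 bp for insertions) and a deletion fraction
of 0.529, matching the length spectrum this kind of consensus call-set
shows in pigs (1 bp indels most frequent; deletions slightly outnumbering
insertions, with deletions up to 54 bp and insertions up to 32 bp).
Founder-frequency strata cycle through breed-divergent and ordinary
segregating patterns so every selection-relevant configuration exists.

Caller call-sets are emulated at the call level (no reads): per-variant
dropout at 1 - sensitivity, per-genotype errors, representation jitter
(equivalent right-shifted or padded records), and unlinked false positives
planted only at sites absent from truth so precision/recall bookkeeping
stays exact. The default profiles (sensitivities 0.90/0.80/0.85, genotype
error 2–3%, jitter 5–15%, false positives 60–150 per Mb) are free
parameters chosen once to give realistically partial three-way overlap
(about 61% of truth in the triple intersection); no per-caller error
characteristics are published, so these are package defaults, not
estimates.

The cross is simulated by gene drop: F1 = random Iberian sire gamete +
random Landrace dam gamete; BC1 = F1 gamete + terminal-breed gamete.
Meiosis is Haldane (Poisson crossover count per chromosome, default rate
1, uniform breakpoints, no interference) — the simplest defensible
meiosis model. Duroc and Pietrain terminal pools have no published founder
data, so they are modelled as independent per-variant allele-frequency
pools drawn from a Beta distribution centred on the Landrace frequency
(concentration 10): related to, but not identical with, the other
commercial breed. Sexes alternate; batches advance every two animals
(14 batches round-robin) so sex and batch are not confounded — the batch
structure of the real experiment is not described.

Phenotypes follow the association model exactly, with
sigma_u^2 = h2 * trait_sd^2 (default h2 = 0.5; fatty-acid traits are of
moderate-to-high heritability) and the residual taking the rest. Sex,
batch and backcross effect magnitudes and the carcass-weight slope default
to zero: no magnitudes are reported for them, and zero keeps the
trait-mean/SD calibration exact, while the model structure itself is
always simulated and fitted (tests exercise nonzero values).

### What a green test does and does not establish

The generator has no linkage-disequilibrium structure beyond the cross
design itself, no read-level error model, no genotyping-platform effects,
and gene models far smaller than real annotations. Green tests establish
that the *algorithms* are correct on a world that satisfies their stated
assumptions — not that the pipeline would reproduce the original study's
counts on real data.

### Sizing the planted effect

The end-to-end acceptance criterion plants one Moderate indel (3-bp
inframe CDS deletion) fixed-alt in Iberian and absent in Landrace, with a
BC1_PI-specific additive effect, and requires it to be selected and to
reach FDR <= 0.1 in BC1_PI only, with >= 80% power over 20 seeds. The
configured effect is **0.17 trait units per alternative-allele copy**
(about 1.2 phenotypic SD), sized a priori as follows. Such a marker is
breed-divergent, so its codes are substantially collinear with the
polygenic ancestry term; under the fitted mixed model its standard error
at n = 138 is about 0.035 (not the naive 0.14 / (0.5 * sqrt(138)) = 0.024
of an unstructured marker — an earlier draft used the naive value and
under-sized the effect; the correction is recorded in the project ledger).
Reaching q <= 0.1 against ~400 markers needs |t| >= 3.7 at rank 1; adding
one SD of power margin gives a noncentrality of ~4.8, hence
a = 4.8 * 0.035 ~ 0.17. This is consistent in magnitude with the
reference statistic the pattern emulates (p = 1.77e-5 at n = 138 implies
|t| = 4.45, i.e. an effect of ~0.16 under the same SE).

## Reproducibility

Every stochastic operation takes an explicit integer seed; the pipeline
derives per-stage seeds from one root seed, and rerunning a configuration
reproduces byte-identical FASTA/GFF3/VCF/TSV outputs (tested). The run
manifest records the configuration hash, per-stage counts and the filter
ledger; `pipeline_report()` renders them with the conservation identity
restated.

## Known limitations

- Indel-only consensus: SNP call-sets are not intersected (SNPs exist in
  the synthetic world only as association markers).
- No haplotype phasing, imputation beyond marker-mean, dominance terms, or
  multi-trait models; the association model is additive.
- The annotator freezes its own term-combination rules rather than chasing
  any particular VEP version's behaviour; counts of multi-term lines will
  differ from VEP's on identical input.
- Multi-allelic VCF lines are split at read time and then subjected to the
  position-level discard rule; records with symbolic alleles or breakends
  are skipped with a count (or rejected in strict mode), not interpreted.
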