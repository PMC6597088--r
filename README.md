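# indelscan

Consensus indel detection, consequence annotation and mixed-model trait
association for experimental crosses — with a seeded synthetic-data module
that makes the whole pipeline testable end-to-end.

## Who this is for

Groups that call insertions/deletions (indels) from whole-genome sequencing
of a small founder panel with several independent callers, keep only
concordant calls, annotate them for functional consequence, select
candidates by severity and breed-divergent founder frequencies, and test
those candidates for association with quantitative traits in structured
(backcross) populations. The reference design is an Iberian x commercial
pig cross: 2 Iberian boars + 5 Landrace sows as sequenced founders and
three BC1 backcrosses (160 BC1_LD, 143 BC1_DU, 138 BC1_PI) phenotyped for
intramuscular fatty-acid composition.

## The method in brief

1. **Normalization** — every VCF record is reduced to its left-aligned
   minimal representation, so different caller representations of the same
   edit compare equal.
2. **Consensus** — a variant is kept iff present in all call-sets; per
   sample the genotype supported by >= 2 callers is adopted; positions with
   inconsistent alternative alleles and variants homozygous-alternative in
   every sample are discarded. The accounting identity
   `n_common = n_final + n_discordant + n_multiallelic + n_fixed_alt`
   holds exactly on every run.
3. **Annotation** — a minimal consequence predictor (frameshift/inframe,
   splice, UTR, start/stop terms) with frozen severity classes
   (High > Moderate > Low > Modifier) and HGVS-style protein changes
   (e.g. `p.Ala2del`).
4. **Selection** — start/stop variants in lipid-metabolism genes, or
   High/Moderate variants at extreme founder frequencies
   (IB = 1 & LD <= 0.2, or IB = 0 & LD >= 0.8).
5. **Association** — the linear mixed model
   `y = Sex + Batch + Backcross + beta*carcass + u + delta*a + e` with
   `u ~ N(0, K sigma_u^2)`, K the centred genomic relatedness matrix,
   marker codes delta in {-1, 0, +1}; REML variance components estimated
   once under the null and reused per marker (EMMAX-style), Wald t tests,
   Benjamini–Hochberg FDR (significant q <= 0.05, suggestive q <= 0.1).

## Worked example

```r
library(indelscan)

genome <- generate_genome(n_chromosomes = 1, chrom_length = 100000,
                          n_genes = 5, seed = 7)
truth  <- plant_truth_variants(genome, n_indels = 150, n_snps = 250,
                               seed = 8,
                               planted = list(effect = 0.17,
                                              backcross = "BC1_PI"))
founders <- simulate_founders(truth, seed = 9)
callsets <- simulate_callsets(founders, genome, seed = 10)

cons <- consensus_calls(callsets, genome)
cons$accounting
#> $n_common [1] 92 ... $n_final [1] 92   (151/130/129 calls per caller;
#> 92 = 92 + 0 discordant + 0 multiallelic + 0 fixed-alt)

ret <- retained_variants(cons)
ann <- annotate_variants(ret, genome)
table(ann$severity)
#>     High Moderate Modifier
#>        5        1       86

fg <- attr(ret, "geno"); rownames(fg) <- ret$key
select_candidates(founder_freqs(fg, founders$breed), ann)
#>                 key gene_id severity freq_IB freq_LD criterion
#> 1 chr1:17854:GTGA:G gene001 Moderate       1       0         b

G  <- simulate_backcross(founders, genome, default_cross_design(), seed = 11)
K  <- centered_kinship(G)
pk <- truth$key[truth$planted_effect != 0]
ph <- simulate_phenotypes(G, K, phenotype_config(),
                          planted = data.frame(marker = pk, effect = 0.17,
                                               backcross = "BC1_PI"),
                          seed = 12)
for (bc in c("BC1_LD", "BC1_DU", "BC1_PI")) {
  res <- run_gwas(G, ph, backcross = bc)$results
  print(res[res$marker == pk, c("a_hat", "se", "p_value", "q_value", "class")])
}
#> BC1_LD: a_hat=-0.057 se=0.030 p=5.81e-02 q=0.807 class=ns
#> BC1_DU: a_hat=-0.027 se=0.039 p=4.98e-01 q=0.968 class=ns
#> BC1_PI: a_hat=-0.203 se=0.047 p=3.35e-05 q=0.013 class=significant
```

Reading: the planted 3-bp inframe deletion (fixed-alt in the Iberian
founders, absent in Landrace) survives the three-caller consensus, is
annotated Moderate, is selected under the extreme-frequency criterion, and
its backcross-specific effect is recovered in the BC1_PI scan only — the
estimate `a_hat = -0.203` is the per-allele effect on the trait scale
(negative because `+1` codes hom-reference), with the planted truth at
0.17 per alternative-allele copy.

One command runs all stages and writes FASTA/GFF3/VCF/TSV/JSON outputs
plus a manifest:

```r
manifest <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_run"))
pipeline_report(manifest)
```

A CLI with `run-all`, `consensus` and `report` subcommands is installed
under `exec/indelscan`.

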