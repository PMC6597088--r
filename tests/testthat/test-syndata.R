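test_that("generate_genome is seeded, packs genes, and builds valid CDS", {
  g <- generate_genome(1, 100000, 5, seed = 7)
  expect_length(g$genes, 5L)
  spans <- t(vapply(g$genes, function(x) range(x$transcripts[[1]]$exons),
                    integer(2)))
  o <- order(spans[, 1])
  expect_true(all(spans[o, 1][-1] > spans[o, 2][-5]))  # non-overlapping
  for (gene in g$genes) {
    tx <- gene$transcripts[[1]]
    expect_gte(nrow(tx$exons), 2L)
    cds_len <- sum(tx$cds[, 2] - tx$cds[, 1] + 1L)
    expect_equal(cds_len %% 3L, 0L)
    # extract CDS in transcription order and check start/stop/no internal stop
    ptx <- indelscan:::prepare_transcripts(list(gene), g$seq)[[1]]
    cds_seq <- substr(ptx$mrna, ptx$cds_m[1], ptx$cds_m[2])
    aa <- translate_cds(cds_seq)
    expect_equal(substr(cds_seq, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  expect_true(all(strsplit(g$seq[[1]], "")[[1]] %in% c("A", "C", "G", "T")))
  # no-gene case and packing error
  g0 <- generate_genome(2, 50000, 0, seed = 1)
  expect_length(g0$genes, 0L)
  expect_error(generate_genome(1, 12000, 5, seed = 1), "pack")
})

test_that("genome FASTA/GFF3 output is byte-identical across reruns", {
  d <- withr::local_tempdir()
  for (run in 1:2) {
    g <- generate_genome(1, 100000, 5, seed = 7)
    write_genome_fasta(g, file.path(d, paste0("g", run, ".fa")))
    write_gff3(g, file.path(d, paste0("g", run, ".gff3")))
  }
  expect_identical(readLines(file.path(d, "g1.fa")),
                   readLines(file.path(d, "g2.fa")))
  expect_identical(readLines(file.path(d, "g1.gff3")),
                   readLines(file.path(d, "g2.gff3")))
  # GFF3 round-trip reconstructs the models
  genes <- read_gff3(file.path(d, "g1.gff3"))
  g <- generate_genome(1, 100000, 5, seed = 7)
  expect_length(genes, 5L)
  expect_equal(genes[[3]]$transcripts[[1]]$exons,
               unname(g$genes[[3]]$transcripts[[1]]$exons))
  expect_equal(genes[[3]]$strand, g$genes[[3]]$strand)
})

test_that("truth planting hits strata, stays left-aligned, obeys length caps", {
  g <- generate_genome(1, 100000, 0, seed = 3)
  tr <- plant_truth_variants(g, 120, 40, seed = 5)
  expect_equal(nrow(tr), 160L)
  expect_equal(sum(tr$variant_class == "snp"), 40L)
  # every requested stratum represented
  fs <- default_freq_spec()
  expect_true(all(paste(fs$freq_IB, fs$freq_LD) %in%
                    paste(tr$freq_IB, tr$freq_LD)))
  # keys are left-aligned fixed points of normalization
  renorm <- normalize_variants(tr$chrom, tr$pos, tr$ref, tr$alt, g)
  expect_identical(renorm$key, tr$key)
  expect_true(all(tr$length[tr$variant_class == "deletion"] <= 54))
  expect_true(all(tr$length[tr$variant_class == "insertion"] <= 32))
  expect_false(anyDuplicated(tr$key) > 0)
  # n_indels = 0 plants only SNPs
  tr0 <- plant_truth_variants(g, 0, 25, seed = 6)
  expect_true(all(tr0$variant_class == "snp"))
})

test_that("founder simulation respects fixed strata and binomial sampling", {
  g <- generate_genome(1, 100000, 0, seed = 3)
  tr <- plant_truth_variants(g, 40, 0, seed = 5)
  fo <- simulate_founders(tr, seed = 1)
  fixed <- tr$freq_IB == 1 & tr$freq_LD == 0
  ib <- fo$breed == "IB"
  expect_true(all(fo$geno[fixed, ib] == 2L))     # IB founders hom-alt
  expect_true(all(fo$geno[fixed, !ib] == 0L))    # LD founders hom-ref
  # binomial oracle at scaled-up founder counts: freq (0, 0.5) with 500 dams
  design <- default_cross_design()
  design$n_founder_dams_LD <- 500L
  fo2 <- simulate_founders(tr, design, seed = 2)
  half <- which(tr$freq_IB == 0 & tr$freq_LD == 0.5)[1]
  cnt <- sum(fo2$geno[half, fo2$breed == "LD"])
  n_alleles <- 1000
  se <- sqrt(n_alleles * 0.5 * 0.5)
  expect_lt(abs(cnt - n_alleles * 0.5), 4 * se)
})

test_that("noise-free call-sets equal the truth indel set, three ways", {
  g <- generate_genome(1, 100000, 0, seed = 3)
  tr <- plant_truth_variants(g, 60, 10, seed = 5)
  fo <- simulate_founders(tr, seed = 1)
  cs <- simulate_callsets(fo, g, noise_free_profiles(), seed = 9)
  truth_indels <- tr[tr$variant_class != "snp", ]
  o <- order(truth_indels$pos)
  for (k in 1:3) {
    expect_equal(cs[[k]]$variants$pos, truth_indels$pos[o])
    expect_equal(cs[[k]]$variants$ref, truth_indels$ref[o])
    expect_equal(unname(cs[[k]]$geno),
                 unname(fo$geno[tr$variant_class != "snp", ][o, ]))
  }
  # byte-identical files
  d <- withr::local_tempdir()
  p <- vapply(1:3, function(k)
    write_vcf(cs[[k]], file.path(d, paste0(k, ".vcf"))), "")
  expect_identical(readLines(p[1])[-2], readLines(p[2])[-2])  # -2: source line
})

test_that("caller dropout follows the sensitivity product and jitter unifies", {
  g <- generate_genome(2, 200000, 0, seed = 3)
  tr <- plant_truth_variants(g, 1500, 0, seed = 5)
  fo <- simulate_founders(tr, seed = 1)
  profiles <- default_caller_profiles()
  for (i in 1:3) {
    profiles[[i]]$genotype_error_rate <- 0
    profiles[[i]]$false_positive_rate_per_mb <- 0
  }
  sens <- vapply(profiles, function(p) p$sensitivity, 0)
  cs <- simulate_callsets(fo, g, profiles, seed = 11)
  cons <- intersect_callsets(cs, g)
  p3 <- prod(sens)
  n <- nrow(tr)
  se <- sqrt(n * p3 * (1 - p3))
  expect_lt(abs(cons$venn$center - n * p3), 3.5 * se)
  # jittered representations were emitted but still intersect via keys
  raw_keys <- paste(cs[[1]]$variants$chrom, cs[[1]]$variants$pos,
                    cs[[1]]$variants$ref, cs[[1]]$variants$alt, sep = ":")
  expect_gt(sum(!(raw_keys %in% tr$key)), 0)
  expect_true(all(normalize_variants(cs[[1]]$variants$chrom,
                                     cs[[1]]$variants$pos,
                                     cs[[1]]$variants$ref,
                                     cs[[1]]$variants$alt, g)$key
                  %in% tr$key))
})

test_that("backcross gene drop: coding, Mendelian consistency, no-recomb limit", {
  g <- generate_genome(2, 50000, 0, seed = 3)
  tr <- plant_truth_variants(g, 60, 60, seed = 5)
  fo <- simulate_founders(tr, seed = 1)
  design <- default_cross_design(40)
  G <- simulate_backcross(fo, g, design, seed = 7)
  expect_equal(dim(G$codes), c(120L, 120L))
  expect_true(all(G$codes %in% c(-1L, 0L, 1L)))
  # variant fixed IB / absent LD: no hom-alt (-1) in BC1_LD
  fixed <- which(tr$freq_IB == 1 & tr$freq_LD == 0)
  ld_rows <- G$info$backcross == "BC1_LD"
  expect_true(all(G$codes[ld_rows, fixed] != -1L))
  # expected Iberian-origin fraction ~ 0.25: with freq (1,0) markers the
  # F1 gamete carries the IB allele half the time
  het_frac <- mean(G$codes[ld_rows, fixed] == 0L)
  expect_lt(abs(het_frac - 0.5), 0.1)
  # Mendelian consistency: BC1 = F1 gamete + terminal gamete
  f1g <- attr(G, "f1_gametes"); tg <- attr(G, "term_gametes")
  expect_true(all(1L - (f1g + tg) == G$codes))
  # F1 gamete alleles must come from the recorded sire/dam haplotypes
  for (i in sample(nrow(G$codes), 10)) {
    sire <- match(G$pedigree$f1_sire[i], fo$samples)
    dam <- match(G$pedigree$f1_dam[i], fo$samples)
    possible <- fo$hap1[, sire] == f1g[i, ] | fo$hap2[, sire] == f1g[i, ] |
      fo$hap1[, dam] == f1g[i, ] | fo$hap2[, dam] == f1g[i, ]
    expect_true(all(possible))
  }
  # zero recombination: each F1 gamete chromosome is an intact parental
  # haplotype over every chromosome
  design0 <- design; design0$recombination_rate <- 0
  G0 <- simulate_backcross(fo, g, design0, seed = 8)
  f1g0 <- attr(G0, "f1_gametes")
  for (i in sample(nrow(G0$codes), 8)) {
    sire <- match(G0$pedigree$f1_sire[i], fo$samples)
    dam <- match(G0$pedigree$f1_dam[i], fo$samples)
    for (ch in unique(tr$chrom)) {
      sites <- which(tr$chrom == ch)
      gam <- f1g0[i, sites]
      cand <- cbind(fo$hap1[sites, sire], fo$hap2[sites, sire],
                    fo$hap1[sites, dam], fo$hap2[sites, dam])
      expect_true(any(colSums(cand == gam) == length(sites)))
    }
  }
  expect_error(simulate_backcross(fo, g,
                                  modifyList(design,
                                             list(n_founder_sires_IB = 0L)),
                                  seed = 1),
               "at least one founder")
})

test_that("phenotype model: degenerate limit, calibration, planted effects, PSD", {
  g <- generate_genome(1, 60000, 0, seed = 3)
  tr <- plant_truth_variants(g, 30, 90, seed = 5)
  fo <- simulate_founders(tr, seed = 1)
  G <- simulate_backcross(fo, g, default_cross_design(50), seed = 7)
  n <- nrow(G$codes)
  K <- centered_kinship(G)
  # all effects zero, h2 = 0, residual 0 -> grand mean exactly
  cfg0 <- phenotype_config(h2_polygenic = 0, residual_sd = 0)
  ph0 <- simulate_phenotypes(G, K, cfg0, seed = 2)
  expect_equal(ph0$trait, rep(0.51, n))
  # default calibration reproduces the stated mean/SD
  ph <- simulate_phenotypes(G, K, phenotype_config(), seed = 3)
  expect_lt(abs(mean(ph$trait) - 0.51), 4 * 0.14 / sqrt(n))
  expect_lt(abs(sd(ph$trait) - 0.14), 0.04)
  # planted backcross-specific effect moves only that backcross
  pl <- data.frame(marker = tr$key[1], effect = 1,
                   backcross = "BC1_PI", stringsAsFactors = FALSE)
  ph1 <- simulate_phenotypes(G, K, cfg0, planted = pl, seed = 2)
  delta <- ph1$trait - ph0$trait
  pi_rows <- G$info$backcross == "BC1_PI"
  expect_true(all(delta[!pi_rows] == 0))
  expect_equal(delta[pi_rows], unname(1 - G$codes[pi_rows, 1]))
  # fixed effects and covariate enter the linear predictor
  cfg2 <- phenotype_config(h2_polygenic = 0, residual_sd = 0,
                           sex_effects = c(-0.3, 0.3),
                           beta_carcass = 0.01)
  ph2 <- simulate_phenotypes(G, K, cfg2, seed = 4)
  sexdiff <- mean(ph2$trait[ph2$sex == "M"] - 0.01 *
                    (ph2$carcass_weight[ph2$sex == "M"] - 72.2)) -
    mean(ph2$trait[ph2$sex == "F"] - 0.01 *
           (ph2$carcass_weight[ph2$sex == "F"] - 72.2))
  expect_equal(sexdiff, 0.6, tolerance = 1e-10)
  # non-PSD kinship is rejected by name
  Kbad <- K; Kbad[1, 2] <- Kbad[2, 1] <- 100
  expect_error(simulate_phenotypes(G, Kbad, phenotype_config(), seed = 1),
               "positive semi-definite")
  expect_error(simulate_phenotypes(G, K[-1, -1], phenotype_config(),
                                   seed = 1), "dimension")
})
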