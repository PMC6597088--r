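#' Default demo pipeline configuration
#'
#' A desk-scale configuration: one 100 kb chromosome with five genes, 2+5
#' founders, three caller call-sets under the default noise profiles, three
#' backcrosses of 60 individuals, a default-calibrated trait and one
#' planted candidate indel (3-bp inframe CDS deletion, fixed-alt Iberian /
#' absent Landrace, additive effect 0.17 trait units per alt copy in
#' BC1_PI; see the methods vignette for the sizing).
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @param n_per_backcross backcross sizes (NULL = study sizes 160/143/138).
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("indelscan_run_"),
                            n_per_backcross = 60L) {
  list(seed = as.integer(seed), out_dir = out_dir,
       genome = list(n_chromosomes = 1L, chrom_length = 100000L,
                     n_genes = 5L, noncoding_frac = 0),
       truth = list(n_indels = 150L, n_snps = 250L,
                    deletion_frac = 0.529,
                    planted = list(effect = 0.17, backcross = "BC1_PI")),
       callers = "default",
       design = list(n_per_backcross = n_per_backcross),
       phenotype = list(trait_name = "C20:2(n-6)", trait_mean = 0.51,
                        trait_sd = 0.14, h2_polygenic = 0.5,
                        log2_transform = FALSE),
       selection = list(lipid_genes = character(0)),
       fdr = list(significant = 0.05, suggestive = 0.1))
}

validate_config <- function(cfg) {
  need <- c("seed", "out_dir", "genome", "truth", "design", "phenotype")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  invisible(cfg)
}

#' Run the full pipeline: simulate, consensus, annotate, select, associate
#'
#' Stages run in order and halt on the first error; all randomness derives
#' from the root seed, so rerunning the same config reproduces identical
#' outputs. Stage outputs are written as plain-text files (FASTA, GFF3,
#' VCF, TSV, JSON) under `cfg$out_dir`.
#'
#' @param cfg a configuration list (see [pipeline_config()]) or the path
#'   of a JSON file containing one.
#' @return the run manifest (list), invisibly written as manifest.json.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg_path <- NULL
  if (is.character(cfg)) {
    cfg_path <- cfg
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(cfg$out_dir, ...)
  seed <- cfg$seed
  stage_seed <- function(k) (seed * 131L + k * 7919L) %% 2147483647L

  ## stage 1: simulate world + caller call-sets
  genome <- generate_genome(cfg$genome$n_chromosomes,
                            cfg$genome$chrom_length, cfg$genome$n_genes,
                            seed = stage_seed(1L),
                            noncoding_frac = cfg$genome$noncoding_frac %||% 0)
  planted <- cfg$truth$planted
  truth <- plant_truth_variants(genome, cfg$truth$n_indels, cfg$truth$n_snps,
                                seed = stage_seed(2L),
                                deletion_frac = cfg$truth$deletion_frac
                                %||% 0.529,
                                planted = planted)
  design <- default_cross_design(cfg$design$n_per_backcross)
  founders <- simulate_founders(truth, design, seed = stage_seed(3L))
  profiles <- if (identical(cfg$callers, "noise_free")) noise_free_profiles()
  else default_caller_profiles()
  callsets <- simulate_callsets(founders, genome, profiles,
                                seed = stage_seed(4L))
  write_genome_fasta(genome, pth("genome.fa"))
  write_gff3(genome, pth("genes.gff3"))
  vcf_paths <- vapply(callsets, function(cs)
    write_vcf(cs, pth(paste0(cs$caller, ".vcf")), genome), "")
  G <- simulate_backcross(founders, genome, design, seed = stage_seed(5L))
  K <- centered_kinship(G)
  pcfg <- do.call(phenotype_config, cfg$phenotype)
  planted_df <- NULL
  if (!is.null(planted)) {
    sp <- which(truth$planted_effect != 0)
    planted_df <- data.frame(marker = truth$key[sp],
                             effect = truth$planted_effect[sp],
                             backcross = truth$planted_backcross[sp],
                             stringsAsFactors = FALSE)
  }
  pheno <- simulate_phenotypes(G, K, pcfg, planted = planted_df,
                               seed = stage_seed(6L))
  utils::write.table(cbind(id = rownames(G$codes), as.data.frame(G$codes)),
                     pth("genotypes.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(G$pedigree, pth("pedigree.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(pheno, pth("phenotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## stage 2: consensus over the written VCFs (stage isolation)
  read_back <- lapply(vcf_paths, read_vcf)
  for (i in seq_along(read_back)) read_back[[i]]$caller <- names(callsets)[i]
  cons <- consensus_calls(read_back, genome)
  retained <- retained_variants(cons)
  cs_out <- structure(list(variants = retained[, c("chrom", "pos", "ref",
                                                   "alt")],
                           geno = attr(retained, "geno"),
                           samples = cons$samples, caller = "consensus",
                           skipped = 0L), class = "callset")
  write_vcf(cs_out, pth("consensus.vcf"), genome)
  jsonlite::write_json(cons$accounting, pth("accounting.json"),
                       auto_unbox = TRUE)
  dens <- chromosome_density(retained, genome)
  utils::write.table(dens, pth("density.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  spec <- length_spectrum(retained)
  utils::write.table(spec$spectrum, pth("length_spectrum.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## stage 3: annotate retained indels
  ann <- annotate_variants(retained, genome)
  utils::write.table(ann, pth("annotations.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## stage 4: founder frequencies + candidate selection
  fg <- attr(retained, "geno")
  rownames(fg) <- retained$key
  freqs <- founder_freqs(fg, founders$breed)
  cand <- select_candidates(freqs, ann,
                            cfg$selection$lipid_genes %||% character(0))
  utils::write.table(cand, pth("candidates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gt_freqs <- genotype_freq_table(G, intersect(cand$key, G$markers))
  utils::write.table(gt_freqs, pth("genotype_frequencies.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## stage 5: association (merged + per backcross)
  scans <- list(merged = run_gwas(G, pheno, kinship = K,
                                  log2_transform = pcfg$log2_transform))
  for (bc in design$backcrosses$name)
    scans[[bc]] <- run_gwas(G, pheno, backcross = bc,
                            log2_transform = pcfg$log2_transform)
  n_sig <- list()
  for (nm in names(scans)) {
    utils::write.table(scans[[nm]]$results,
                       pth(paste0("assoc_", gsub("[^A-Za-z0-9_]", "_", nm),
                                  ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    n_sig[[nm]] <- list(
      significant = sum(scans[[nm]]$results$class == "significant",
                        na.rm = TRUE),
      suggestive = sum(scans[[nm]]$results$class == "suggestive",
                       na.rm = TRUE))
  }

  manifest <- list(
    tool_version = as.character(utils::packageVersion("indelscan")),
    config_hash = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA_character_,
    seed = seed,
    paths = list(out_dir = cfg$out_dir,
                 vcf = unname(vcf_paths), consensus = pth("consensus.vcf"),
                 annotations = pth("annotations.tsv"),
                 candidates = pth("candidates.tsv")),
    counts = list(n_truth = nrow(truth),
                  n_truth_indels = sum(truth$variant_class != "snp"),
                  accounting = cons$accounting,
                  n_annotations = nrow(ann),
                  n_candidates = nrow(cand),
                  qc = scans$merged$qc_report,
                  associations = n_sig),
    planted = if (is.null(planted_df)) NULL else planted_df)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable run report
#'
#' @param manifest a manifest list from [run_pipeline()] or the path to a
#'   manifest.json.
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  a <- manifest$counts$accounting
  lines <- c(
    "== indelscan run report ==",
    sprintf("seed: %s  out: %s", manifest$seed, manifest$paths$out_dir),
    "-- filter ledger --",
    sprintf("per-caller calls: %s",
            paste(a$n_per_caller, collapse = " / ")),
    sprintf("common: %d = final %d + discordant %d + multiallelic %d + fixed-alt %d",
            a$n_common, a$n_final, a$n_discordant,
            a$n_multiallelic_inconsistent, a$n_fixed_alt),
    "-- annotation --",
    sprintf("annotation lines: %d (variants retained: %d)",
            manifest$counts$n_annotations, a$n_final),
    "-- candidates --",
    sprintf("selected candidates: %d", manifest$counts$n_candidates),
    "-- associations (significant / suggestive) --")
  for (nm in names(manifest$counts$associations)) {
    s <- manifest$counts$associations[[nm]]
    lines <- c(lines, sprintf("%-8s %d / %d", nm, s$significant,
                              s$suggestive))
  }
  ok <- a$n_common == a$n_final + a$n_discordant +
    a$n_multiallelic_inconsistent + a$n_fixed_alt
  lines <- c(lines, sprintf("ledger conservation: %s",
                            if (ok) "OK" else "VIOLATED"))
  cat(lines, sep = "\n")
  invisible(lines)
}
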