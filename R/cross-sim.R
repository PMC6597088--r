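#' Gene-drop simulation of BC1 backcross populations
#'
#' F1 individuals are produced from a random Iberian sire gamete and a
#' random Landrace dam gamete; each BC1 individual is an F1 gamete plus a
#' terminal-breed gamete. Gametes are formed per chromosome with a
#' Poisson-distributed crossover count (Haldane model, no interference) and
#' uniform breakpoints. Terminal-breed allele pools: "LD" reuses the
#' Landrace stratum frequencies; "DU"/"PI" get independent per-variant
#' frequencies drawn once from a Beta distribution centred on the Landrace
#' frequency (the commercial breeds are related but not identical; no
#' founder data exists for them, so they are modelled as independent pools).
#'
#' Genotype coding is +1 = hom-reference, 0 = het, -1 = hom-alternative.
#'
#' @param founders a `founder_set`.
#' @param genome the `sim_genome` (for chromosome lengths).
#' @param design a cross design (see [default_cross_design()]).
#' @param seed integer seed.
#' @return a `genotype_matrix`: list with `codes` (individuals x markers,
#'   values -1/0/+1), `markers` (truth keys), `info` (id, backcross, sex,
#'   batch), `pedigree`, and bookkeeping attributes for Mendelian checks.
#' @export
simulate_backcross <- function(founders, genome,
                               design = default_cross_design(), seed) {
  if (design$n_founder_sires_IB < 1 || design$n_founder_dams_LD < 1)
    stop("cross design needs at least one founder per breed")
  set.seed(as.integer(seed))
  truth <- founders$truth
  seqs <- genome_seqs(genome)
  chrom_of <- match(truth$chrom, names(seqs))
  n_ib <- design$n_founder_sires_IB
  n_ld <- design$n_founder_dams_LD
  ib_cols <- which(founders$breed == "IB")
  ld_cols <- which(founders$breed == "LD")
  # terminal-breed allele frequencies per variant
  term_freq <- list(LD = truth$freq_LD)
  for (b in setdiff(unique(design$backcrosses$terminal), "LD")) {
    k <- 10
    term_freq[[b]] <- stats::rbeta(nrow(truth), truth$freq_LD * k + 0.5,
                                   (1 - truth$freq_LD) * k + 0.5)
  }
  gamete <- function(h1, h2) {
    out <- integer(length(h1))
    for (ci in unique(chrom_of)) {
      sites <- which(chrom_of == ci)
      L <- nchar(seqs[[ci]])
      nx <- stats::rpois(1L, design$recombination_rate)
      bp <- sort(stats::runif(nx, 1, L))
      seg <- findInterval(truth$pos[sites], bp)  # segment index per site
      start <- sample(0:1, 1L)
      use_h1 <- (seg + start) %% 2L == 0L
      out[sites] <- ifelse(use_h1, h1[sites], h2[sites])
    }
    out
  }
  n_tot <- sum(design$backcrosses$n)
  codes <- matrix(NA_integer_, n_tot, nrow(truth))
  info <- data.frame(id = character(n_tot), backcross = character(n_tot),
                     sex = character(n_tot), batch = integer(n_tot),
                     stringsAsFactors = FALSE)
  ped <- data.frame(id = character(n_tot), f1_sire = character(n_tot),
                    f1_dam = character(n_tot), stringsAsFactors = FALSE)
  f1_gametes <- matrix(NA_integer_, n_tot, nrow(truth))
  term_gametes <- matrix(NA_integer_, n_tot, nrow(truth))
  row <- 0L
  for (bi in seq_len(nrow(design$backcrosses))) {
    bc <- design$backcrosses$name[bi]
    tb <- design$backcrosses$terminal[bi]
    for (j in seq_len(design$backcrosses$n[bi])) {
      row <- row + 1L
      sire <- sample(ib_cols, 1L)
      dam <- sample(ld_cols, 1L)
      f1_h1 <- gamete(founders$hap1[, sire], founders$hap2[, sire])
      f1_h2 <- gamete(founders$hap1[, dam], founders$hap2[, dam])
      g_f1 <- gamete(f1_h1, f1_h2)
      g_term <- stats::rbinom(nrow(truth), 1L, term_freq[[tb]])
      dosage <- g_f1 + g_term
      codes[row, ] <- 1L - dosage           # +1 hom-ref, 0 het, -1 hom-alt
      f1_gametes[row, ] <- g_f1
      term_gametes[row, ] <- g_term
      info$id[row] <- sprintf("%s_%03d", bc, j)
      info$backcross[row] <- bc
      info$sex[row] <- if (row %% 2L == 0L) "M" else "F"
      # batches advance every two animals so sex is not confounded with batch
      info$batch[row] <- (((row - 1L) %/% 2L) %% 14L) + 1L
      ped$id[row] <- info$id[row]
      ped$f1_sire[row] <- founders$samples[sire]
      ped$f1_dam[row] <- founders$samples[dam]
    }
  }
  rownames(codes) <- info$id
  colnames(codes) <- truth$key
  structure(list(codes = codes, markers = truth$key, info = info,
                 pedigree = ped),
            class = "genotype_matrix",
            f1_gametes = f1_gametes, term_gametes = term_gametes)
}
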