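#' Default founder-frequency strata
#'
#' Breed-stratified alternative-allele frequencies (Iberian, Landrace) that
#' truth variants are cycled through. The mix covers the patterns seen in
#' real founder data: variants fixed in one breed and rare/absent in the
#' other (the candidate-selection strata), plus ordinary segregating
#' variants.
#' @export
default_freq_spec <- function() {
  data.frame(
    freq_IB = c(1.0, 1.0, 0.0, 0.0, 0.25, 0.5, 0.2, 0.8),
    freq_LD = c(0.0, 0.2, 0.8, 0.5, 0.70, 0.5, 0.4, 0.6))
}

#' Plant truth variants (indels and SNPs) into a simulated genome
#'
#' Sites are drawn on a spacing grid so edits never overlap; every key is
#' stored left-aligned. Indel lengths follow a geometric distribution with
#' mode 1 bp, capped at 54 bp for deletions and 32 bp for insertions;
#' the deletion fraction defaults to 0.529. Each variant is assigned a
#' founder-frequency stratum from `freq_spec` round-robin, so every
#' requested stratum is represented at least once when enough variants are
#' requested.
#'
#' A "special" indel emulating the headline candidate pattern can be
#' requested via `planted`: a 3-bp inframe deletion placed inside a coding
#' gene's CDS (clear of start/stop codons and exon junctions), fixed-alt in
#' Iberian, absent in Landrace, carrying an additive phenotype effect.
#'
#' @param genome a `sim_genome` from [generate_genome()].
#' @param n_indels,n_snps counts of indels and SNPs to plant.
#' @param freq_spec data.frame with columns freq_IB, freq_LD.
#' @param seed integer seed.
#' @param deletion_frac fraction of indels that are deletions.
#' @param length_p geometric parameter; indel length = 1 + rgeom(length_p).
#' @param planted NULL, or list(effect =, backcross =) for the special
#'   CDS indel (effect in trait units per alt-allele copy; backcross names
#'   the population whose phenotypes carry the effect, NA for all).
#' @return data.frame (class `truth_set`): chrom, pos, ref, alt, key,
#'   variant_class, length, freq_IB, freq_LD, planted_effect,
#'   planted_backcross.
#' @export
plant_truth_variants <- function(genome, n_indels, n_snps,
                                 freq_spec = default_freq_spec(), seed,
                                 deletion_frac = 0.529, length_p = 0.5,
                                 planted = NULL) {
  stopifnot(all(freq_spec$freq_IB >= 0 & freq_spec$freq_IB <= 1),
            all(freq_spec$freq_LD >= 0 & freq_spec$freq_LD <= 1))
  set.seed(as.integer(seed))
  seqs <- genome_seqs(genome)
  n_total <- n_indels + n_snps
  spacing <- 120L
  # candidate anchor grid: one site per spacing window, away from edges
  grid <- do.call(rbind, lapply(names(seqs), function(ch) {
    L <- nchar(seqs[[ch]])
    anchors <- seq.int(spacing, L - spacing, by = spacing)
    data.frame(chrom = ch, slot = anchors, stringsAsFactors = FALSE)
  }))
  if (n_total + ifelse(is.null(planted), 0L, 1L) > nrow(grid))
    stop("genome too small for the requested number of variants")
  pick <- grid[sample.int(nrow(grid), n_total), , drop = FALSE]
  is_indel <- c(rep(TRUE, n_indels), rep(FALSE, n_snps))
  res_chrom <- character(n_total); res_pos <- integer(n_total)
  res_ref <- character(n_total); res_alt <- character(n_total)
  active <- seq_len(n_total)
  bases <- c("A", "C", "G", "T")
  for (try in 1:50) {
    if (!length(active)) break
    na <- length(active)
    pos <- pick$slot[active] + sample.int(20L, na, replace = TRUE) - 1L
    del <- stats::runif(na) < deletion_frac
    len <- pmin(1L + stats::rgeom(na, length_p), ifelse(del, 54L, 32L))
    ref <- alt <- character(na)
    for (ch in unique(pick$chrom[active])) {
      ii <- which(pick$chrom[active] == ch)
      s <- seqs[[ch]]
      anchor <- substring(s, pos[ii], pos[ii])
      ind <- is_indel[active[ii]]
      ref[ii] <- ifelse(ind & del[ii],
                        substring(s, pos[ii], pos[ii] + len[ii]), anchor)
      ins <- ii[ind[seq_along(ii)] & !del[ii]]
      if (length(ins))
        alt[ins] <- paste0(ref[ins], vapply(len[ins], random_dna, ""))
      dl <- ii[ind[seq_along(ii)] & del[ii]]
      alt[dl] <- anchor[match(dl, ii)]
      sn <- ii[!ind[seq_along(ii)]]
      if (length(sn))
        alt[sn] <- vapply(anchor[match(sn, ii)], function(b)
          sample(setdiff(bases, b), 1L), "")
    }
    nk <- normalize_variants(pick$chrom[active], pos, ref, alt, genome)
    # keep the left-aligned site near its spacing window so edits from
    # neighbouring windows can never overlap (max span 55 bp << 120 bp)
    ok <- nk$pos >= pick$slot[active] - 40L & nk$pos <= pick$slot[active] + 19L
    done <- active[ok]
    res_chrom[done] <- nk$chrom[ok]; res_pos[done] <- nk$pos[ok]
    res_ref[done] <- nk$ref[ok]; res_alt[done] <- nk$alt[ok]
    active <- active[!ok]
  }
  if (length(active)) stop("failed to place a variant after bounded retries")
  out <- data.frame(chrom = res_chrom, pos = res_pos, ref = res_ref,
                    alt = res_alt,
                    key = paste(res_chrom, res_pos, res_ref, res_alt,
                                sep = ":"),
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$key))
  st <- freq_spec[rep_len(seq_len(nrow(freq_spec)), n_total), , drop = FALSE]
  cls <- rep("snp", n_total)
  if (n_indels > 0) {
    vc <- variant_class(out$ref[is_indel], out$alt[is_indel])
    cls[is_indel] <- vc$class
  }
  lens <- abs(nchar(out$ref) - nchar(out$alt))
  res <- data.frame(out, variant_class = cls, length = lens,
                    freq_IB = st$freq_IB, freq_LD = st$freq_LD,
                    planted_effect = 0, planted_backcross = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    sp <- plant_special_indel(genome, res, planted)
    res <- rbind(res, sp)
  }
  rownames(res) <- NULL
  class(res) <- c("truth_set", "data.frame")
  res
}

# place a 3-bp inframe CDS deletion, fixed-alt IB / absent LD, with an effect
plant_special_indel <- function(genome, existing, planted) {
  coding <- Filter(function(g) g$biotype == "coding", genome$genes)
  if (!length(coding))
    stop("planted special indel requires at least one coding gene")
  for (g in coding) {
    tx <- g$transcripts[[1]]
    cds <- tx$cds
    for (ii in seq_len(nrow(cds))) {
      a <- cds[ii, 1]; b <- cds[ii, 2]
      if (b - a < 60L) next
      # stay clear of interval ends (junctions, start/stop codons)
      for (anchor in seq(a + 20L, b - 25L, by = 3L)) {
        ch <- g$chrom
        ref <- substr(genome$seq[[ch]], anchor, anchor + 3L)
        alt <- substr(ref, 1L, 1L)
        nk <- normalize_variants(ch, anchor, ref, alt, genome)
        if (nk$pos < a + 3L || nk$pos + 3L > b - 3L) next
        clash <- any(abs(existing$pos[existing$chrom == ch] - nk$pos) < 60L)
        if (clash) next
        return(data.frame(nk, variant_class = "deletion", length = 3L,
                          freq_IB = 1, freq_LD = 0,
                          planted_effect = planted$effect,
                          planted_backcross =
                            if (is.null(planted$backcross)) NA_character_
                            else planted$backcross,
                          stringsAsFactors = FALSE))
      }
    }
  }
  stop("could not place the special CDS indel clear of existing sites")
}

#' Default cross design: 2 Iberian sires, 5 Landrace dams, three BC1s
#'
#' Backcross sizes follow the study design (160 BC1_LD, 143 BC1_DU,
#' 138 BC1_PI); `recombination_rate` is the expected number of crossovers
#' per chromosome per meiosis (Haldane model, no interference).
#' @param n_per_backcross optional single size overriding all three.
#' @export
default_cross_design <- function(n_per_backcross = NULL) {
  n <- c(160L, 143L, 138L)
  if (!is.null(n_per_backcross)) n <- rep(as.integer(n_per_backcross), 3L)
  list(n_founder_sires_IB = 2L, n_founder_dams_LD = 5L,
       backcrosses = data.frame(
         name = c("BC1_LD", "BC1_DU", "BC1_PI"),
         terminal = c("LD", "DU", "PI"),
         n = n, stringsAsFactors = FALSE),
       recombination_rate = 1)
}

#' Simulate founder genotypes from truth frequencies
#'
#' Each founder receives two haplotypes; every allele is an independent
#' Bernoulli draw from the founder's breed-stratum frequency.
#'
#' @param truth a `truth_set`.
#' @param design a cross design (see [default_cross_design()]).
#' @param seed integer seed.
#' @return list (class `founder_set`): `geno` (variants x founders, codes
#'   0/1/2 alt-allele dosage), `hap1`/`hap2` (0/1 haplotype matrices),
#'   `samples`, `breed` (per founder, "IB"/"LD"), `truth`.
#' @export
simulate_founders <- function(truth, design = default_cross_design(), seed) {
  stopifnot(design$n_founder_sires_IB >= 1, design$n_founder_dams_LD >= 1)
  set.seed(as.integer(seed))
  ids <- c(paste0("IB", seq_len(design$n_founder_sires_IB)),
           paste0("LD", seq_len(design$n_founder_dams_LD)))
  breed <- c(rep("IB", design$n_founder_sires_IB),
             rep("LD", design$n_founder_dams_LD))
  nv <- nrow(truth)
  f <- ifelse(rep(breed, each = nv) == "IB", rep(truth$freq_IB, length(ids)),
              rep(truth$freq_LD, length(ids)))
  hap1 <- matrix(stats::rbinom(nv * length(ids), 1L, f), nv, length(ids))
  hap2 <- matrix(stats::rbinom(nv * length(ids), 1L, f), nv, length(ids))
  colnames(hap1) <- colnames(hap2) <- ids
  geno <- hap1 + hap2
  structure(list(geno = geno, hap1 = hap1, hap2 = hap2, samples = ids,
                 breed = breed, truth = truth),
            class = "founder_set")
}
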