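#' Default caller noise profiles
#'
#' Three profiles emulating the disagreement structure of independent indel
#' callers run on the same alignments: per-variant dropout (1 - sensitivity),
#' per-genotype error, a probability of emitting an equivalent but
#' non-left-aligned representation, and unlinked false-positive calls per Mb.
#' Magnitudes are free parameters chosen to give realistically partial
#' three-way overlap (~60% of truth in the triple intersection).
#' @export
default_caller_profiles <- function() {
  list(
    list(name = "callerA", sensitivity = 0.90, genotype_error_rate = 0.020,
         representation_jitter_rate = 0.10, false_positive_rate_per_mb = 150),
    list(name = "callerB", sensitivity = 0.80, genotype_error_rate = 0.030,
         representation_jitter_rate = 0.05, false_positive_rate_per_mb = 60),
    list(name = "callerC", sensitivity = 0.85, genotype_error_rate = 0.025,
         representation_jitter_rate = 0.15, false_positive_rate_per_mb = 90))
}

#' Noise-free caller profiles (all three identical to truth)
#' @export
noise_free_profiles <- function() {
  lapply(c("callerA", "callerB", "callerC"), function(nm)
    list(name = nm, sensitivity = 1, genotype_error_rate = 0,
         representation_jitter_rate = 0, false_positive_rate_per_mb = 0))
}

#' Simulate per-caller call-sets from founder genotypes
#'
#' Each caller independently drops truth variants, perturbs genotypes,
#' re-expresses a fraction of indels in an equivalent right-shifted (or
#' padded) representation, and adds false positives at sites absent from
#' the truth set. Indels only (callers in this pipeline are indel callers);
#' truth SNPs are ignored here.
#'
#' @param founders a `founder_set` from [simulate_founders()].
#' @param genome the `sim_genome` the truth was planted in.
#' @param profiles list of >= 2 caller profiles
#'   (see [default_caller_profiles()]).
#' @param seed integer seed.
#' @return list of `callset` objects; each carries a `truth_key` column
#'   bookkeeping attribute (NA for false positives).
#' @export
simulate_callsets <- function(founders, genome,
                              profiles = default_caller_profiles(), seed) {
  stopifnot(length(profiles) >= 2L)
  set.seed(as.integer(seed))
  truth <- founders$truth
  idx <- which(truth$variant_class != "snp")
  seqs <- genome_seqs(genome)
  genome_mb <- sum(nchar(seqs)) / 1e6
  taken <- truth$pos  # occupied anchors, for FP placement
  callsets <- list()
  for (p in profiles) {
    keep <- idx[stats::runif(length(idx)) < p$sensitivity]
    v <- truth[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    g <- founders$geno[keep, , drop = FALSE]
    # genotype errors: replace with one of the two other genotype classes
    err <- which(stats::runif(length(g)) < p$genotype_error_rate)
    if (length(err)) {
      g[err] <- (g[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
    # representation jitter
    jit <- which(stats::runif(nrow(v)) < p$representation_jitter_rate)
    if (length(jit)) {
      vc <- v$chrom; vp <- v$pos; vr <- v$ref; va <- v$alt
      for (i in jit) {
        s <- shift_representation(seqs[[vc[i]]], vp[i], vr[i], va[i])
        vp[i] <- s$pos; vr[i] <- s$ref; va[i] <- s$alt
      }
      v$pos <- vp; v$ref <- vr; v$alt <- va
    }
    truth_key <- truth$key[keep]
    # false positives, unlinked, away from every truth site
    n_fp <- stats::rpois(1L, p$false_positive_rate_per_mb * genome_mb)
    if (n_fp > 0L) {
      fp <- fp_records(seqs, n_fp, taken)
      nfp <- nrow(fp)
      if (nfp) {
        gfp <- matrix(sample(0:2, nfp * ncol(g), replace = TRUE,
                             prob = c(0.45, 0.45, 0.10)), nfp, ncol(g))
        v <- rbind(v, fp)
        g <- rbind(g, gfp)
        truth_key <- c(truth_key, rep(NA_character_, nfp))
      }
    }
    o <- order(match(v$chrom, names(seqs)), v$pos)
    v <- v[o, , drop = FALSE]; g <- g[o, , drop = FALSE]
    colnames(g) <- founders$samples
    cs <- structure(list(variants = v, geno = g, samples = founders$samples,
                         caller = p$name, skipped = 0L),
                    class = "callset")
    attr(cs, "truth_key") <- truth_key[o]
    callsets[[p$name]] <- cs
  }
  callsets
}

# false-positive indel records at anchors >= 60 bp from any occupied site
fp_records <- function(seqs, n_fp, taken_pos) {
  out <- list()
  tries <- 0L
  chroms <- names(seqs)
  while (length(out) < n_fp && tries < n_fp * 20L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1L)
    pos <- sample.int(nchar(seqs[[ch]]) - 60L, 1L) + 30L
    if (any(abs(taken_pos - pos) < 60L)) next
    taken_pos <- c(taken_pos, pos)  # conservative: pooled across chromosomes
    if (stats::runif(1) < 0.5) {
      len <- 1L + stats::rgeom(1L, 0.5)
      len <- min(len, 10L)
      ref <- substr(seqs[[ch]], pos, pos + len)
      alt <- substr(ref, 1L, 1L)
    } else {
      ref <- substr(seqs[[ch]], pos, pos)
      alt <- paste0(ref, random_dna(1L + min(stats::rgeom(1L, 0.5), 9L)))
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = pos, ref = ref,
                                          alt = alt, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), stringsAsFactors = FALSE)
}
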