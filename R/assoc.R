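#' Alternative-allele frequencies in the founders, per breed
#'
#' @param geno variants x founders matrix of alt-allele dosages (0/1/2,
#'   NA = missing), e.g. `founder_set$geno` or resolved consensus
#'   genotypes.
#' @param breed per-founder breed labels ("IB"/"LD").
#' @param keys optional variant keys (defaults to rownames).
#' @return data.frame: key, freq_IB, freq_LD, n_alleles_IB, n_alleles_LD.
#'   A breed with no non-missing allele reports NA.
#' @export
founder_freqs <- function(geno, breed, keys = rownames(geno)) {
  stopifnot(ncol(geno) == length(breed), all(breed %in% c("IB", "LD")))
  one <- function(cols) {
    g <- geno[, cols, drop = FALSE]
    n <- 2L * rowSums(!is.na(g))
    f <- rowSums(g, na.rm = TRUE) / n
    f[n == 0L] <- NA_real_
    list(f = f, n = n)
  }
  ib <- one(breed == "IB"); ld <- one(breed == "LD")
  data.frame(key = if (is.null(keys)) seq_len(nrow(geno)) else keys,
             freq_IB = ib$f, freq_LD = ld$f,
             n_alleles_IB = ib$n, n_alleles_LD = ld$n,
             stringsAsFactors = FALSE)
}

#' Select candidate indels by consequence and founder frequency
#'
#' Two selection criteria, returned as a union with provenance:
#' (a) a start/stop consequence (start_lost, stop_gained, stop_lost) in a
#' gene from the supplied lipid-metabolism list; (b) High or Moderate
#' severity at extreme founder frequencies
#' (freq_IB = 1 and freq_LD <= 0.2, or freq_IB = 0 and freq_LD >= 0.8).
#'
#' @param freqs data.frame from [founder_freqs()].
#' @param annotations data.frame from [annotate_variants()].
#' @param lipid_genes character vector of gene ids considered
#'   lipid-metabolism related.
#' @return data.frame: key, gene_id, severity, freq_IB, freq_LD, criterion
#'   ("a", "b" or "ab").
#' @export
select_candidates <- function(freqs, annotations, lipid_genes = character(0)) {
  ann <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(key = character(), gene_id = character(),
                      severity = character(), freq_IB = numeric(),
                      freq_LD = numeric(), criterion = character(),
                      stringsAsFactors = FALSE))
  ann$has_startstop <- vapply(strsplit(ann$terms, ",", fixed = TRUE),
                              function(t) any(t %in% c("start_lost",
                                                       "stop_gained",
                                                       "stop_lost")), TRUE)
  f <- freqs[match(ann$key, freqs$key), , drop = FALSE]
  eps <- 1e-9
  crit_a <- ann$has_startstop & ann$gene_id %in% lipid_genes
  crit_b <- ann$severity %in% c("High", "Moderate") &
    !is.na(f$freq_IB) & !is.na(f$freq_LD) &
    ((abs(f$freq_IB - 1) < eps & f$freq_LD <= 0.2 + eps) |
       (abs(f$freq_IB) < eps & f$freq_LD >= 0.8 - eps))
  sel <- crit_a | crit_b
  out <- data.frame(key = ann$key, gene_id = ann$gene_id,
                    severity = ann$severity,
                    freq_IB = f$freq_IB, freq_LD = f$freq_LD,
                    criterion = paste0(ifelse(crit_a, "a", ""),
                                       ifelse(crit_b, "b", "")),
                    stringsAsFactors = FALSE)[sel, , drop = FALSE]
  out <- out[!duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype-class frequencies per marker per backcross
#'
#' @param G a `genotype_matrix`.
#' @param markers keys of the markers to report (default all).
#' @return data.frame: marker, backcross, freq_hom_ref, freq_het,
#'   freq_hom_alt, n (non-missing count). Frequencies sum to 1 over
#'   non-missing individuals; an all-missing cell reports NA.
#' @export
genotype_freq_table <- function(G, markers = G$markers) {
  mi <- match(markers, G$markers)
  if (any(is.na(mi))) stop("unknown marker(s)")
  out <- list()
  for (bc in unique(G$info$backcross)) {
    rows <- G$info$backcross == bc
    for (k in seq_along(markers)) {
      g <- G$codes[rows, mi[k]]
      n <- sum(!is.na(g))
      f <- if (n) c(mean(g == 1L, na.rm = TRUE), mean(g == 0L, na.rm = TRUE),
                    mean(g == -1L, na.rm = TRUE)) else rep(NA_real_, 3L)
      out[[length(out) + 1L]] <- data.frame(
        marker = markers[k], backcross = bc, freq_hom_ref = f[1],
        freq_het = f[2], freq_hom_alt = f[3], n = n,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker quality control
#'
#' Drops markers with minor allele frequency below `maf_min` (computed on
#' non-missing codes) or missing-genotype rate above `miss_max`.
#'
#' @param G a `genotype_matrix`.
#' @param maf_min MAF threshold (drop if MAF < maf_min). Default 0.05.
#' @param miss_max missingness threshold (drop if rate > miss_max).
#'   Default 0.05.
#' @return list: `G` (filtered `genotype_matrix` with `maf` and
#'   `missing_rate` per retained marker), `report` (n_input, n_low_maf,
#'   n_high_missing, n_removed, n_kept).
#' @export
marker_qc <- function(G, maf_min = 0.05, miss_max = 0.05) {
  codes <- G$codes
  miss <- colMeans(is.na(codes))
  alt_f <- colMeans(1 - codes, na.rm = TRUE) / 2   # alt copies = 1 - code
  maf <- pmin(alt_f, 1 - alt_f)
  maf[is.nan(maf)] <- 0
  low_maf <- maf < maf_min
  high_miss <- miss > miss_max
  keep <- !(low_maf | high_miss)
  Gf <- G
  Gf$codes <- codes[, keep, drop = FALSE]
  Gf$markers <- G$markers[keep]
  Gf$maf <- maf[keep]
  Gf$missing_rate <- miss[keep]
  list(G = Gf,
       report = list(n_input = ncol(codes), n_low_maf = sum(low_maf),
                     n_high_missing = sum(high_miss),
                     n_removed = sum(!keep), n_kept = sum(keep)))
}

#' Centred genomic relatedness matrix
#'
#' K = Xc Xc' / p, where Xc is the individuals x markers code matrix with
#' missing values mean-imputed per marker and every column mean-centred.
#'
#' @param G a `genotype_matrix`, or a bare codes matrix.
#' @return symmetric n x n matrix.
#' @export
centered_kinship <- function(G) {
  X <- if (is.matrix(G)) G else G$codes
  if (ncol(X) == 0L) stop("no markers to build a kinship matrix from")
  X <- impute_marker_means(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / ncol(Xc)
  (K + t(K)) / 2
}

impute_marker_means <- function(X) {
  mi <- which(colSums(is.na(X)) > 0L)
  for (j in mi) {
    m <- mean(X[, j], na.rm = TRUE)
    if (is.nan(m)) m <- 0
    X[is.na(X[, j]), j] <- m
  }
  X
}
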