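#' Intersect caller call-sets after normalization
#'
#' Every record is left-aligned/minimalized; a normalized key is "common"
#' when it is present in all call-sets. Duplicate keys inside one call-set
#' keep the first record (a message reports the count).
#'
#' @param callsets list of `callset` objects (>= 2; the study design
#'   uses 3).
#' @param genome genome for normalization.
#' @return list with `common` (data.frame of common keys), `geno` (list of
#'   per-caller genotype matrices aligned to `common`), `venn` (per-caller,
#'   pairwise and centre counts), `samples`.
#' @export
intersect_callsets <- function(callsets, genome) {
  stopifnot(length(callsets) >= 2L)
  samples <- callsets[[1]]$samples
  norm <- lapply(callsets, function(cs) {
    stopifnot(identical(cs$samples, samples))
    nk <- normalize_variants(cs$variants$chrom, cs$variants$pos,
                             cs$variants$ref, cs$variants$alt, genome)
    dup <- duplicated(nk$key)
    if (any(dup))
      message(sprintf("%s: %d duplicate normalized key(s), keeping first",
                      cs$caller, sum(dup)))
    list(keys = nk[!dup, , drop = FALSE],
         geno = cs$geno[!dup, , drop = FALSE])
  })
  keysets <- lapply(norm, function(x) x$keys$key)
  common_keys <- Reduce(intersect, keysets)
  nm <- vapply(callsets, function(cs) cs$caller, "")
  venn <- list(per_caller = stats::setNames(lengths(keysets), nm),
               union = length(Reduce(union, keysets)),
               center = length(common_keys))
  if (length(callsets) >= 2L) {
    prs <- utils::combn(seq_along(callsets), 2L)
    venn$pairwise <- stats::setNames(
      apply(prs, 2L, function(ij)
        length(intersect(keysets[[ij[1]]], keysets[[ij[2]]]))),
      apply(prs, 2L, function(ij) paste(nm[ij], collapse = "&")))
  }
  i1 <- match(common_keys, keysets[[1]])
  common <- norm[[1]]$keys[i1, , drop = FALSE]
  rownames(common) <- NULL
  geno <- lapply(norm, function(x)
    x$geno[match(common_keys, x$keys$key), , drop = FALSE])
  names(geno) <- nm
  list(common = common, geno = geno, venn = venn, samples = samples)
}

#' Resolve per-sample genotypes across callers by majority vote
#'
#' For each sample the genotype supported by at least two callers is
#' adopted. Missing calls do not vote: with one caller missing, agreement
#' of the other two suffices; a lone non-missing call is adopted as-is.
#' A variant is fated `discarded_genotype_discordant` when any sample has
#' no two-caller (or lone-call) support among its non-missing calls, or
#' when every sample is missing everywhere.
#'
#' @param ix result of [intersect_callsets()].
#' @return list `consensus_set`: `variants` (common keys + `fate` +
#'   `support`), `geno` (resolved matrix, NA where all callers missing).
#' @export
resolve_genotypes <- function(ix) {
  gl <- ix$geno
  k <- length(gl)
  nv <- nrow(ix$common); ns <- length(ix$samples)
  counts <- lapply(0:2, function(v)
    Reduce(`+`, lapply(gl, function(g) (!is.na(g) & g == v) + 0L)))
  n_nonmiss <- Reduce(`+`, lapply(gl, function(g) !is.na(g) + 0L))
  best <- pmax(counts[[1]], counts[[2]], counts[[3]])
  resolved <- matrix(NA_integer_, nv, ns)
  for (v in 0:2) resolved[counts[[v + 1L]] == best & best > 0L] <- v
  # a cell is concordant if >=2 callers agree, or exactly one voted at all
  cell_ok <- best >= 2L | (n_nonmiss == 1L & best == 1L) | n_nonmiss == 0L
  resolved[n_nonmiss == 0L] <- NA_integer_
  discord <- rowSums(!cell_ok) > 0L
  all_missing <- rowSums(n_nonmiss) == 0L
  fate <- ifelse(discord | all_missing, "discarded_genotype_discordant",
                 "retained")
  variants <- ix$common
  variants$fate <- as.character(fate)
  variants$support <- rep(paste(names(gl), collapse = ","), nv)
  colnames(resolved) <- ix$samples
  structure(list(variants = variants, geno = resolved,
                 samples = ix$samples, venn = ix$venn),
            class = "consensus_set")
}

#' Discard positions with inconsistent alternative alleles
#'
#' Any chromosomal position carrying more than one distinct alternative
#' allele (across callers or samples, i.e. among the common normalized
#' keys) has all its variants fated `discarded_multiallelic_inconsistent`.
#' Applies only to variants still retained.
#'
#' @param cons a `consensus_set`.
#' @export
filter_alleles <- function(cons) {
  v <- cons$variants
  live <- v$fate == "retained"
  posid <- paste(v$chrom, v$pos, sep = ":")
  n_alt <- tapply(v$alt[live], posid[live], function(a) length(unique(a)))
  bad_pos <- names(n_alt)[n_alt > 1L]
  hit <- live & posid %in% bad_pos
  v$fate[hit] <- "discarded_multiallelic_inconsistent"
  cons$variants <- v
  cons
}

#' Discard variants homozygous-alternative in every sample
#'
#' Such variants cannot segregate in the cross. By default a variant is
#' discarded only when *all* samples are non-missing hom-alt;
#' `require_complete = FALSE` relaxes this to "all non-missing genotypes
#' hom-alt and at least one non-missing".
#'
#' @param cons a `consensus_set`.
#' @param require_complete see above.
#' @export
filter_fixed_alt <- function(cons, require_complete = TRUE) {
  v <- cons$variants
  live <- v$fate == "retained"
  g <- cons$geno
  all_alt_nonmiss <- rowSums(g != 2L, na.rm = TRUE) == 0L
  n_miss <- rowSums(is.na(g))
  hit <- if (require_complete) all_alt_nonmiss & n_miss == 0L
  else all_alt_nonmiss & n_miss < ncol(g)
  v$fate[live & hit] <- "discarded_fixed_alt"
  cons$variants <- v
  cons
}

#' Exact filter accounting
#'
#' @param cons a `consensus_set` with all fates assigned.
#' @return list with n_common, n_discordant, n_multiallelic_inconsistent,
#'   n_fixed_alt, n_final; the conservation identity
#'   n_common = n_final + sum(discards) holds by construction and is
#'   asserted.
#' @export
consensus_accounting <- function(cons) {
  f <- cons$variants$fate
  if (any(is.na(f))) stop("unassigned fate in consensus set")
  acc <- list(n_common = length(f),
              n_discordant = sum(f == "discarded_genotype_discordant"),
              n_multiallelic_inconsistent =
                sum(f == "discarded_multiallelic_inconsistent"),
              n_fixed_alt = sum(f == "discarded_fixed_alt"),
              n_final = sum(f == "retained"))
  stopifnot(acc$n_common == acc$n_final + acc$n_discordant +
              acc$n_multiallelic_inconsistent + acc$n_fixed_alt)
  if (!is.null(cons$venn)) {
    acc$n_per_caller <- cons$venn$per_caller
    acc$n_union <- cons$venn$union
  }
  acc
}

#' Run the full consensus cascade
#'
#' common -> genotype concordance -> multi-allelic/inconsistent ->
#' fixed-alternative, in that order; each filter only touches variants
#' still retained, so the accounting identity is exact.
#'
#' @param callsets list of `callset`s.
#' @param genome genome for normalization.
#' @param require_complete passed to [filter_fixed_alt()].
#' @return a `consensus_set` with `accounting` attached.
#' @export
consensus_calls <- function(callsets, genome, require_complete = TRUE) {
  cons <- resolve_genotypes(intersect_callsets(callsets, genome))
  cons <- filter_alleles(cons)
  cons <- filter_fixed_alt(cons, require_complete = require_complete)
  cons$accounting <- consensus_accounting(cons)
  cons
}

#' Per-chromosome indel density, sorted ascending
#'
#' @param variants data.frame with a `chrom` column (typically the retained
#'   variants of a `consensus_set`).
#' @param genome genome providing chromosome lengths.
#' @return data.frame (chrom, n, mb, density) sorted by increasing density;
#'   chromosomes with zero variants are included.
#' @export
chromosome_density <- function(variants, genome) {
  seqs <- genome_seqs(genome)
  len <- nchar(seqs)
  if (any(len == 0L)) stop("zero-length chromosome")
  n <- vapply(names(seqs), function(ch) sum(variants$chrom == ch), 0L)
  d <- data.frame(chrom = names(seqs), n = n, mb = len / 1e6,
                  density = n / (len / 1e6), stringsAsFactors = FALSE)
  d <- d[order(d$density, d$chrom), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Indel length spectrum and deletion fraction
#'
#' @param variants data.frame with `ref` and `alt` columns (indels only).
#' @return list with `spectrum` (data.frame class, length, n) and
#'   `deletion_fraction` (NA for empty input).
#' @export
length_spectrum <- function(variants) {
  if (!nrow(variants))
    return(list(spectrum = data.frame(class = character(), length = integer(),
                                      n = integer()),
                deletion_fraction = NA_real_))
  vc <- variant_class(variants$ref, variants$alt)
  tab <- as.data.frame(table(class = vc$class, length = vc$length),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  spectrum <- data.frame(class = tab$class,
                         length = as.integer(tab$length), n = tab$Freq,
                         stringsAsFactors = FALSE)
  spectrum <- spectrum[order(spectrum$class, spectrum$length), , drop = FALSE]
  rownames(spectrum) <- NULL
  list(spectrum = spectrum,
       deletion_fraction = mean(vc$class == "deletion"))
}

#' Retained variants of a consensus set
#' @param cons a `consensus_set`.
#' @return data.frame of retained variants with resolved genotypes attached
#'   as attribute `geno`.
#' @export
retained_variants <- function(cons) {
  keep <- cons$variants$fate == "retained"
  out <- cons$variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "geno") <- cons$geno[keep, , drop = FALSE]
  out
}
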