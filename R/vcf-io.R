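#' Read a multi-sample VCF into a call-set
#'
#' A deliberately narrow VCF v4.x reader: it keeps CHROM/POS/REF/ALT and the
#' GT subfield only, splits multi-allelic lines into biallelic records (each
#' retaining its own alt and a per-alt genotype recoding), and skips -- with
#' a count -- records it cannot represent (symbolic alleles such as
#' `<DEL>`, breakends). Genotypes are coded 0 = hom-ref, 1 = het,
#' 2 = hom-alt, NA = missing; in a split multi-allelic record an allele
#' belonging to a *different* alt is treated as reference-like for this alt's
#' dosage, except fully-other-alt genotypes which become missing.
#'
#' @param path path to an uncompressed VCF file.
#' @param caller label stored on the returned call-set.
#' @param strict if TRUE, unsupported records are an error instead of a skip.
#' @return a `callset` object: list with `variants` (data.frame chrom, pos,
#'   ref, alt), `geno` (integer matrix records x samples), `samples`,
#'   `caller`, `skipped` (count of unsupported records).
#' @export
read_vcf <- function(path, caller = basename(path), strict = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stop("malformed VCF header: no #CHROM line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("VCF must be multi-sample (FORMAT + sample columns): ", path)
  samples <- cols[-(1:9)]
  body_idx <- seq.int(hdr + 1L, length.out = max(0L, length(lines) - hdr))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); geno <- list()
  skipped <- 0L
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                   i, length(f), length(cols)))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (any(grepl("[][<>]", alts)) || f[5] == ".") {
      if (strict)
        stop(sprintf("unsupported allele class at line %d: %s", i, f[5]))
      skipped <- skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i))
      stop(sprintf("no GT subfield in FORMAT at line %d", i))
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_i)
    alleles <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    bad_gt <- lengths(alleles) != 2L
    if (any(bad_gt))
      stop(sprintf("malformed GT field at line %d: '%s'", i, gts[bad_gt][1]))
    am <- matrix(suppressWarnings(as.integer(unlist(alleles))),
                 ncol = 2L, byrow = TRUE)
    for (k in seq_along(alts)) {
      dose <- rowSums(am == k)
      dose[rowSums(is.na(am)) > 0L] <- NA_integer_
      # genotype made only of other alts carries no information on this alt
      other <- !is.na(dose) & dose == 0L & rowSums(am == 0L, na.rm = TRUE) == 0L
      dose[other] <- NA_integer_
      chrom <- c(chrom, f[1]); pos <- c(pos, as.integer(f[2]))
      ref <- c(ref, toupper(f[4])); alt <- c(alt, toupper(alts[k]))
      geno[[length(geno) + 1L]] <- as.integer(dose)
    }
  }
  g <- if (length(geno)) do.call(rbind, geno) else
    matrix(integer(0), 0L, length(samples))
  colnames(g) <- samples
  structure(list(variants = data.frame(chrom = chrom, pos = pos, ref = ref,
                                       alt = alt, stringsAsFactors = FALSE),
                 geno = g, samples = samples, caller = caller,
                 skipped = skipped),
            class = "callset")
}

#' Write a call-set to a VCF v4.2 file
#'
#' @param cs a `callset` object (see [read_vcf()]).
#' @param path output path.
#' @param genome optional `sim_genome`; when given, contig header lines with
#'   lengths are emitted.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, genome = NULL) {
  gt_str <- c("0/0", "0/1", "1/1")
  v <- cs$variants
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=indelscan(%s)", cs$caller))
  if (!is.null(genome)) {
    seqs <- genome_seqs(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(seqs), nchar(seqs)))
  }
  hdr <- c(hdr, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cs$samples), collapse = "\t"))
  gm <- matrix("./.", nrow(v), length(cs$samples))
  ok <- !is.na(cs$geno)
  gm[ok] <- gt_str[cs$geno[ok] + 1L]
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gm, 1L, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
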