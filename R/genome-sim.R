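#' Generate a random genome with non-overlapping gene models
#'
#' Builds a desk-scale stand-in for a reference assembly: uniform-random
#' A/C/G/T chromosomes carrying a configurable number of non-overlapping
#' genes. Every coding gene has at least two exons, a 5' and 3' UTR, and a
#' CDS that starts with ATG, ends with a stop codon, contains no internal
#' stop on its strand, and has length divisible by three -- so consequence
#' annotation has well-formed models to work against. A fraction of genes
#' can be non-coding (same exon structure, no CDS).
#'
#' @param n_chromosomes number of chromosomes ("chr1", "chr2", ...).
#' @param chrom_length length in bases of each chromosome (>= 10 kb).
#' @param n_genes total number of genes, distributed round-robin.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param noncoding_frac fraction of genes generated as non-coding.
#' @return a `sim_genome`: list with `seq` (named character vector) and
#'   `genes` (list of gene models; see [make_gene_model()]).
#' @export
generate_genome <- function(n_chromosomes, chrom_length, n_genes, seed,
                            noncoding_frac = 0) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 10000, n_genes >= 0)
  set.seed(as.integer(seed))
  chroms <- paste0("chr", seq_len(n_chromosomes))
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = ""), "")
  genome <- structure(list(seq = seqs, genes = list()), class = "sim_genome")
  if (n_genes == 0L) return(genome)
  per_chrom <- tabulate(rep_len(seq_len(n_chromosomes), n_genes),
                        nbins = n_chromosomes)
  gap <- 12000L  # inter-gene margin so intergenic/flank cases exist
  genes <- list()
  gid <- 0L
  for (ci in seq_len(n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    # worst-case gene span is ~4.2 kb; each gene gets its own slot with
    # placement jitter, so slots must be comfortably larger than that
    slot <- (chrom_length - gap) %/% k
    if (slot < 12800L)
      stop(sprintf("cannot pack %d genes into a %d bp chromosome", k,
                   chrom_length))
    for (j in seq_len(k)) {
      gid <- gid + 1L
      start <- as.integer(gap + (j - 1L) * slot +
                            sample.int(max(1L, slot - 9000L), 1L))
      coding <- stats::runif(1) >= noncoding_frac
      gm <- make_gene_model(
        gene_id = sprintf("gene%03d", gid), chrom = chroms[ci],
        start = start, strand = sample(c("+", "-"), 1L),
        biotype = if (coding) "coding" else "non_coding")
      seqs[chroms[ci]] <- paste0(
        substr(seqs[chroms[ci]], 1L, gm$region_start - 1L), gm$region_seq,
        substr(seqs[chroms[ci]], gm$region_start + nchar(gm$region_seq),
               chrom_length))
      gm$region_seq <- NULL; gm$region_start <- NULL
      genes[[length(genes) + 1L]] <- gm
    }
  }
  genome$seq <- seqs
  genome$genes <- genes
  genome
}

# Build one gene model plus the genomic sequence of its region.
# Returns the gene model with two extra fields (region_start, region_seq)
# that generate_genome() splices into the chromosome.
make_gene_model <- function(gene_id, chrom, start, strand,
                            biotype = "coding", tags = character(0)) {
  n_exons <- sample(2:4, 1L)
  u5 <- sample(30:100, 1L)
  n_codons <- sample(60:300, 1L)
  u3 <- sample(30:100, 1L)
  cds_len <- 3L * n_codons
  mrna_len <- u5 + cds_len + u3
  mrna <- paste0(random_dna(u5), random_cds(n_codons), random_dna(u3))
  # cut the mRNA into exons; junctions kept >= 12 bp from the CDS ends so
  # start/stop codons sit strictly inside exons
  forbidden <- c(seq(u5 - 11L, u5 + 12L), seq(u5 + cds_len - 11L,
                                              u5 + cds_len + 12L))
  cand <- setdiff(seq(40L, mrna_len - 40L), forbidden)
  cuts <- sort(sample(cand, n_exons - 1L))
  while (any(diff(cuts) < 40L)) cuts <- sort(sample(cand, n_exons - 1L))
  ex_b <- c(0L, cuts, mrna_len)                 # exon boundaries in mRNA coords
  introns <- vapply(seq_len(n_exons - 1L), function(i)
    random_dna(sample(100:1000, 1L)), "")
  # assemble genomic (+ orientation) region and exon coordinates
  region <- ""
  exons <- matrix(0L, n_exons, 2L)
  off <- 0L
  mrna2gen <- integer(mrna_len)               # mRNA index -> region offset
  for (i in seq_len(n_exons)) {
    es <- ex_b[i] + 1L; ee <- ex_b[i + 1L]
    exons[i, ] <- c(off + 1L, off + (ee - es + 1L))
    mrna2gen[es:ee] <- seq.int(off + 1L, off + (ee - es + 1L))
    region <- paste0(region, substr(mrna, es, ee))
    off <- off + (ee - es + 1L)
    if (i < n_exons) {
      region <- paste0(region, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  # CDS intervals in region coordinates (only for coding genes)
  cds <- NULL
  if (biotype == "coding") {
    cds_mrna <- seq(u5 + 1L, u5 + cds_len)
    gpos <- mrna2gen[cds_mrna]
    cds <- runs_to_intervals(gpos)
  }
  region_len <- nchar(region)
  if (strand == "-") {
    region <- revcomp(region)
    flip <- function(m) {
      out <- cbind(region_len - m[, 2L] + 1L, region_len - m[, 1L] + 1L)
      out[order(out[, 1L]), , drop = FALSE]
    }
    exons <- flip(exons)
    if (!is.null(cds)) cds <- flip(cds)
  }
  shift <- function(m) cbind(m[, 1L] + start - 1L, m[, 2L] + start - 1L)
  exons <- shift(exons)
  if (!is.null(cds)) cds <- shift(cds)
  list(gene_id = gene_id, chrom = chrom, strand = strand, biotype = biotype,
       tags = tags,
       transcripts = list(list(transcript_id = paste0(gene_id, ".t1"),
                               exons = exons, cds = cds)),
       region_start = start, region_seq = region)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# ATG + (n-2) random non-stop codons + one stop codon
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2L)
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
  body <- sample(setdiff(all_codons, stops), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(stops, 1L)), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

# consecutive integer positions -> matrix of [start, end] intervals
runs_to_intervals <- function(p) {
  p <- sort(p)
  brk <- c(0L, which(diff(p) != 1L), length(p))
  t(vapply(seq_len(length(brk) - 1L), function(i)
    c(p[brk[i] + 1L], p[brk[i + 1L]]), integer(2L)))
}

#' Write a simulated genome to FASTA
#' @param genome a `sim_genome`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome_seqs(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a bare genome (no gene models)
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(seq = stats::setNames(as.character(x),
                                       sub("\\s.*$", "", names(x))),
                 genes = list()),
            class = "sim_genome")
}

#' Write gene models to GFF3 (1-based inclusive coordinates)
#' @param genome a `sim_genome` whose `genes` are exported.
#' @param path output path.
#' @export
write_gff3 <- function(genome, path) {
  out <- "##gff-version 3"
  for (g in genome$genes) {
    sp <- range(unlist(lapply(g$transcripts, function(t) t$exons)))
    out <- c(out, gff_line(g$chrom, "gene", sp[1], sp[2], g$strand,
                           sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)))
    for (t in g$transcripts) {
      sp <- range(t$exons)
      out <- c(out, gff_line(g$chrom, "mRNA", sp[1], sp[2], g$strand,
                             sprintf("ID=%s;Parent=%s", t$transcript_id,
                                     g$gene_id)))
      for (i in seq_len(nrow(t$exons)))
        out <- c(out, gff_line(g$chrom, "exon", t$exons[i, 1], t$exons[i, 2],
                               g$strand, sprintf("Parent=%s",
                                                 t$transcript_id)))
      if (!is.null(t$cds))
        for (i in seq_len(nrow(t$cds)))
          out <- c(out, gff_line(g$chrom, "CDS", t$cds[i, 1], t$cds[i, 2],
                                 g$strand, sprintf("Parent=%s",
                                                   t$transcript_id)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "indelscan", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

#' Read gene models from a GFF3 file
#'
#' Understands the gene/mRNA/exon/CDS hierarchy written by [write_gff3()]
#' (ID/Parent attributes, 1-based inclusive coordinates).
#' @param path GFF3 path.
#' @return list of gene models.
#' @export
read_gff3 <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attr_get <- function(a, k) {
    m <- regmatches(a, regexpr(paste0("(^|;)", k, "=[^;]*"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)", k, "="), a))) > 0,
           sub(paste0("^.*", k, "="), "", m), NA_character_)
  }
  df <- data.frame(chrom = f[, 1], type = f[, 3],
                   start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                   strand = f[, 7], attrs = f[, 9], stringsAsFactors = FALSE)
  df$id <- vapply(df$attrs, attr_get, "", k = "ID")
  df$parent <- vapply(df$attrs, attr_get, "", k = "Parent")
  genes <- list()
  for (gi in which(df$type == "gene")) {
    gid <- df$id[gi]
    txs <- list()
    for (ti in which(df$type == "mRNA" & df$parent == gid)) {
      tid <- df$id[ti]
      ex <- df[df$type == "exon" & df$parent == tid, , drop = FALSE]
      cd <- df[df$type == "CDS" & df$parent == tid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cd <- cd[order(cd$start), , drop = FALSE]
      txs[[length(txs) + 1L]] <- list(
        transcript_id = tid,
        exons = cbind(ex$start, ex$end),
        cds = if (nrow(cd)) cbind(cd$start, cd$end) else NULL)
    }
    genes[[length(genes) + 1L]] <- list(
      gene_id = gid, chrom = df$chrom[gi], strand = df$strand[gi],
      biotype = {
        b <- attr_get(df$attrs[gi], "biotype")
        if (is.na(b)) "coding" else b
      },
      tags = character(0), transcripts = txs)
  }
  genes
}
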