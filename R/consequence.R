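#' Consequence-term severity map
#'
#' The controlled vocabulary of consequence terms with their ordinal
#' severity class. The per-term assignment is frozen; severity of a term
#' set is the maximum under High > Moderate > Low > Modifier.
#' @export
severity_map <- function() {
  c(intergenic_variant = "Modifier",
    intron_variant = "Modifier",
    downstream_gene_variant = "Modifier",
    upstream_gene_variant = "Modifier",
    non_coding_transcript_variant = "Modifier",
    "3_prime_UTR_variant" = "Modifier",
    NMD_transcript_variant = "Modifier",
    splice_region_variant = "Low",
    frameshift_variant = "High",
    "5_prime_UTR_variant" = "Modifier",
    non_coding_transcript_exon_variant = "Modifier",
    inframe_deletion = "Moderate",
    inframe_insertion = "Moderate",
    coding_sequence_variant = "Modifier",
    splice_acceptor_variant = "High",
    splice_donor_variant = "High",
    mature_miRNA_variant = "Modifier",
    start_lost = "High",
    stop_gained = "High",
    protein_altering_variant = "Moderate",
    stop_retained_variant = "Low",
    stop_lost = "High",
    incomplete_terminal_codon_variant = "Low")
}

severity_levels <- c("Modifier", "Low", "Moderate", "High")

#' Maximum severity of a set of consequence terms
#' @param terms character vector of terms (non-empty, all in the
#'   vocabulary of [severity_map()]).
#' @return one of "High", "Moderate", "Low", "Modifier".
#' @export
severity_of <- function(terms) {
  stopifnot(length(terms) > 0)
  m <- severity_map()
  unknown <- setdiff(terms, names(m))
  if (length(unknown))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  severity_levels[max(match(m[terms], severity_levels))]
}

#' Annotate normalized indels against gene models
#'
#' A minimal consequence predictor. For each transcript whose span plus
#' flank contains a variant, one annotation row is emitted; a variant
#' hitting no transcript is a single intergenic annotation. Coding logic
#' reconstructs the mutant CDS, translates both alleles, and derives
#' frameshift/inframe, start/stop and protein-level changes from the
#' comparison. Splice windows: donor/acceptor = first/last 2 intronic
#' bases; splice region = last 3 exonic or intronic bases 3-8 from a
#' junction (strand-aware).
#'
#' @param variants data.frame with normalized chrom, pos, ref, alt (and
#'   optionally key).
#' @param genome a `sim_genome` (its `genes` are used unless `genes` is
#'   given).
#' @param genes optional list of gene models.
#' @param flank upstream/downstream window in bp (default 5000).
#' @return data.frame: key, gene_id, transcript_id, terms
#'   (comma-separated), severity, protein_change.
#' @export
annotate_variants <- function(variants, genome, genes = NULL, flank = 5000L) {
  if (is.null(genes)) genes <- genome$genes
  seqs <- genome_seqs(genome)
  if (is.null(variants$key))
    variants$key <- paste(variants$chrom, variants$pos, variants$ref,
                          variants$alt, sep = ":")
  if (any(!(variants$chrom %in% names(seqs))))
    stop("variant on unknown chromosome")
  if (any(nchar(variants$ref) == nchar(variants$alt)))
    stop("annotate_variants() handles indels only")
  txs <- prepare_transcripts(genes, seqs)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- FALSE
    for (tx in txs) {
      if (tx$chrom != v$chrom) next
      ann <- annotate_one(v, tx, flank)
      if (is.null(ann)) next
      hit <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        key = v$key, gene_id = tx$gene_id, transcript_id = tx$transcript_id,
        terms = paste(ann$terms, collapse = ","),
        severity = severity_of(ann$terms),
        protein_change = if (is.null(ann$protein_change)) NA_character_
        else ann$protein_change,
        stringsAsFactors = FALSE)
    }
    if (!hit)
      out[[length(out) + 1L]] <- data.frame(
        key = v$key, gene_id = NA_character_, transcript_id = NA_character_,
        terms = "intergenic_variant", severity = "Modifier",
        protein_change = NA_character_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Precompute per-transcript machinery: mRNA sequence, genomic<->mRNA maps,
# CDS bounds in mRNA coordinates.
prepare_transcripts <- function(genes, seqs) {
  out <- list()
  for (g in genes) {
    for (t in g$transcripts) {
      ex <- t$exons[order(t$exons[, 1L]), , drop = FALSE]
      # genomic positions of exonic bases, in transcription order
      gpos <- unlist(lapply(seq_len(nrow(ex)), function(k)
        seq.int(ex[k, 1L], ex[k, 2L])))
      if (g$strand == "-") gpos <- rev(gpos)
      mrna <- paste(vapply(seq_len(nrow(ex)), function(k)
        substr(seqs[[g$chrom]], ex[k, 1L], ex[k, 2L]), ""), collapse = "")
      if (g$strand == "-") mrna <- revcomp(mrna)
      cds_m <- NULL
      if (!is.null(t$cds)) {
        cpos <- unlist(lapply(seq_len(nrow(t$cds)), function(k)
          seq.int(t$cds[k, 1L], t$cds[k, 2L])))
        m <- match(cpos, gpos)
        cds_m <- c(min(m), max(m))
      }
      out[[length(out) + 1L]] <- list(
        gene_id = g$gene_id, transcript_id = t$transcript_id,
        chrom = g$chrom, strand = g$strand, biotype = g$biotype,
        tags = g$tags, exons = ex, cds = t$cds,
        span = c(min(ex), max(ex)), gpos = gpos, mrna = mrna, cds_m = cds_m)
    }
  }
  out
}

# Annotate one variant against one prepared transcript; NULL if the variant
# is outside span +/- flank.
annotate_one <- function(v, tx, flank) {
  is_del <- nchar(v$ref) > nchar(v$alt)
  len <- abs(nchar(v$ref) - nchar(v$alt))
  # genomic footprint: deleted bases, or the two bases flanking an insertion
  if (is_del) { s <- v$pos + 1L; e <- v$pos + len }
  else        { s <- v$pos;      e <- v$pos + 1L }
  if (e < tx$span[1] - flank || s > tx$span[2] + flank) return(NULL)
  inside <- s >= tx$span[1] && e <= tx$span[2]
  if (!inside) {
    if (e < tx$span[1] || s > tx$span[2]) {
      left <- e < tx$span[1]
      term <- if ((left && tx$strand == "+") || (!left && tx$strand == "-"))
        "upstream_gene_variant" else "downstream_gene_variant"
      return(list(terms = term))
    }
    # straddles a transcript edge: classify by the inside portion
    s <- max(s, tx$span[1]); e <- min(e, tx$span[2])
  }
  terms <- character(0)
  ex <- tx$exons
  base_exonic <- function(p) any(ex[, 1L] <= p & p <= ex[, 2L])
  span_bases <- seq.int(s, e)
  exonic <- vapply(span_bases, base_exonic, TRUE)
  nmd <- "NMD" %in% tx$tags
  add_nmd <- function(t) if (nmd) unique(c(t, "NMD_transcript_variant")) else t
  # splice windows in genomic coordinates
  introns <- if (nrow(ex) > 1L)
    cbind(ex[-nrow(ex), 2L] + 1L, ex[-1L, 1L] - 1L) else
      matrix(integer(0), 0L, 2L)
  ov <- function(a, b) s <= b && e >= a
  donor_left <- tx$strand == "+"  # donor side = left end of intron on "+"
  splice_terms <- character(0)
  for (k in seq_len(nrow(introns))) {
    a <- introns[k, 1L]; b <- introns[k, 2L]
    dw <- if (donor_left) c(a, a + 1L) else c(b - 1L, b)
    aw <- if (donor_left) c(b - 1L, b) else c(a, a + 1L)
    if (ov(dw[1], dw[2])) splice_terms <- c(splice_terms,
                                            "splice_donor_variant")
    if (ov(aw[1], aw[2])) splice_terms <- c(splice_terms,
                                            "splice_acceptor_variant")
    rw1 <- c(a + 2L, min(a + 7L, b)); rw2 <- c(max(b - 7L, a), b - 2L)
    if ((rw1[1] <= rw1[2] && ov(rw1[1], rw1[2])) ||
        (rw2[1] <= rw2[2] && ov(rw2[1], rw2[2])))
      splice_terms <- c(splice_terms, "splice_region_variant")
  }
  # exonic bases within 3 bp of an internal junction
  for (k in seq_len(nrow(ex))) {
    if (k < nrow(ex) && ov(ex[k, 2L] - 2L, ex[k, 2L]))
      splice_terms <- c(splice_terms, "splice_region_variant")
    if (k > 1L && ov(ex[k, 1L], ex[k, 1L] + 2L))
      splice_terms <- c(splice_terms, "splice_region_variant")
  }
  splice_terms <- unique(splice_terms)
  if (all(!exonic)) {                      # fully intronic
    terms <- if (length(splice_terms))
      unique(c(splice_terms,
               if (!any(c("splice_donor_variant", "splice_acceptor_variant")
                        %in% splice_terms)) "intron_variant"))
    else "intron_variant"
    if (tx$biotype != "coding")
      terms <- c(terms, "non_coding_transcript_variant")
    return(list(terms = add_nmd(terms)))
  }
  if (any(exonic) && any(!exonic)) {       # spans an exon-intron boundary
    terms <- splice_terms
    if (tx$biotype == "coding") {
      cds_ov <- !is.null(tx$cds) &&
        any(apply(tx$cds, 1L, function(iv) ov(iv[1], iv[2])))
      terms <- c(terms, if (cds_ov) "coding_sequence_variant")
    } else terms <- c(terms, "non_coding_transcript_exon_variant")
    if (!length(terms)) terms <- "coding_sequence_variant"
    return(list(terms = add_nmd(unique(terms))))
  }
  # fully exonic
  if (tx$biotype == "miRNA")
    return(list(terms = add_nmd(unique(c("mature_miRNA_variant",
                                         splice_terms)))))
  if (tx$biotype != "coding")
    return(list(terms = add_nmd(unique(c("non_coding_transcript_exon_variant",
                                         splice_terms)))))
  coding_ann(v, tx, s, e, is_del, len, splice_terms, add_nmd)
}

# coding-transcript logic for a fully exonic indel
coding_ann <- function(v, tx, s, e, is_del, len, splice_terms, add_nmd) {
  m_s <- match(s, tx$gpos); m_e <- match(e, tx$gpos)
  mm <- sort(c(m_s, m_e))                  # mRNA coords, transcription order
  cs <- tx$cds_m[1]; ce <- tx$cds_m[2]
  cds_len <- ce - cs + 1L
  incomplete <- cds_len %% 3L != 0L
  if (is_del) {
    del_s <- mm[1]; del_e <- mm[2]
    if (del_e < cs) return(list(terms = add_nmd(unique(c(
      "5_prime_UTR_variant", splice_terms)))))
    if (del_s > ce) return(list(terms = add_nmd(unique(c(
      "3_prime_UTR_variant", splice_terms)))))
    if (del_s < cs || del_e > ce) {
      utr <- if (del_s < cs) "5_prime_UTR_variant" else "3_prime_UTR_variant"
      lost <- if (del_s <= cs + 2L && del_e >= cs) "start_lost"
      return(list(terms = add_nmd(unique(c("coding_sequence_variant", utr,
                                           lost, splice_terms)))))
    }
    i <- del_s - cs + 1L; j <- del_e - cs + 1L
    ins_sense <- ""
  } else {
    # insertion lands between mRNA positions min(mm) and min(mm)+1
    m_left <- mm[1]
    ins_nt <- substr(v$alt, 2L, nchar(v$alt))
    ins_sense <- if (tx$strand == "-") revcomp(ins_nt) else ins_nt
    if (m_left < cs) return(list(terms = add_nmd(unique(c(
      "5_prime_UTR_variant", splice_terms)))))
    if (m_left >= ce) return(list(terms = add_nmd(unique(c(
      "3_prime_UTR_variant", splice_terms)))))
    i <- m_left - cs + 2L; j <- i - 1L     # insert before cds offset i
  }
  cds_seq <- substr(tx$mrna, cs, ce)
  mut_cds <- if (is_del)
    paste0(substr(cds_seq, 1L, i - 1L), substr(cds_seq, j + 1L, cds_len))
  else
    paste0(substr(cds_seq, 1L, i - 1L), ins_sense,
           substr(cds_seq, i, cds_len))
  terms <- splice_terms
  frameshift <- len %% 3L != 0L
  terms <- c(terms, if (frameshift) "frameshift_variant"
             else if (is_del) "inframe_deletion" else "inframe_insertion")
  if (incomplete) {
    tail_start <- cds_len - (cds_len %% 3L) + 1L
    if (j >= tail_start || (!is_del && i > tail_start))
      terms <- c(terms, "incomplete_terminal_codon_variant")
  }
  # start codon (cds offsets 1-3)
  start_hit <- if (is_del) i <= 3L else i <= 3L && i >= 2L
  if (start_hit) terms <- c(terms, "start_lost")
  aa_ref <- translate_cds(cds_seq)
  aa_mut <- translate_cds(mut_cds)
  touches_stop <- if (is_del) j >= cds_len - 2L else i > cds_len - 2L
  first_codon <- ceiling(i / 3)
  if (touches_stop && !incomplete) {
    after <- substr(aa_mut, first_codon, nchar(aa_mut))
    if (grepl("*", after, fixed = TRUE))
      terms <- c(terms, "stop_retained_variant")
    else terms <- c(terms, "stop_lost")
  } else if (!incomplete) {
    # a stop created at the edit locus
    n_new <- if (is_del) 1L else ceiling((len + 2L) / 3) + 1L
    win <- substr(aa_mut, first_codon, min(first_codon + n_new,
                                           nchar(aa_mut) - 1L))
    ref_win <- substr(aa_ref, first_codon,
                      min(first_codon + n_new, nchar(aa_ref) - 1L))
    if (grepl("*", win, fixed = TRUE) && !grepl("*", ref_win, fixed = TRUE))
      terms <- c(terms, "stop_gained")
  }
  pc <- NULL
  if (!frameshift && !start_hit && !incomplete)
    pc <- protein_change_string(aa_ref, aa_mut)
  if (!frameshift && !is.null(pc) && grepl("delins", pc))
    terms <- c(terms, "protein_altering_variant")
  list(terms = add_nmd(unique(terms)), protein_change = pc)
}

#' Translate a CDS nucleotide string (trailing partial codon dropped)
#' @param nt nucleotide string.
#' @return amino-acid string, stops as `*`.
#' @export
translate_cds <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

#' HGVS-style protein change from reference and mutant protein strings
#'
#' Compares the two translations, trimming the longest common suffix first
#' and then the prefix, so changes are reported at their most N-terminal
#' equivalent position (e.g. deleting one Ala of an Ala-Ala run at codons
#' 2-3 is p.Ala2del). Recognizes deletions, insertions, duplications and
#' delins; returns NULL when the proteins are identical.
#'
#' @param aa_ref,aa_mut single-letter amino-acid strings (stop as `*`).
#' @export
protein_change_string <- function(aa_ref, aa_mut) {
  if (identical(aa_ref, aa_mut)) return(NULL)
  r <- strsplit(aa_ref, "", fixed = TRUE)[[1]]
  m <- strsplit(aa_mut, "", fixed = TRUE)[[1]]
  ns <- 0L
  while (ns < min(length(r), length(m)) &&
         r[length(r) - ns] == m[length(m) - ns]) ns <- ns + 1L
  rr <- r[seq_len(length(r) - ns)]; mmv <- m[seq_len(length(m) - ns)]
  p <- 0L
  while (p < min(length(rr), length(mmv)) && rr[p + 1L] == mmv[p + 1L])
    p <- p + 1L
  ref_mid <- if (length(rr) > p) rr[(p + 1L):length(rr)] else character(0)
  mut_mid <- if (length(mmv) > p) mmv[(p + 1L):length(mmv)] else character(0)
  A <- function(x) paste(aa3[x], collapse = "")
  if (!length(mut_mid)) {                              # pure deletion
    i <- p + 1L; j <- p + length(ref_mid)
    if (i == j) sprintf("p.%s%ddel", aa3[r[i]], i)
    else sprintf("p.%s%d_%s%ddel", aa3[r[i]], i, aa3[r[j]], j)
  } else if (!length(ref_mid)) {                       # insertion / dup
    k <- length(mut_mid)
    follows <- p + k <= length(r) && all(r[(p + 1L):(p + k)] == mut_mid)
    precedes <- p >= k && all(r[(p - k + 1L):p] == mut_mid)
    if (follows) {
      i <- p + 1L; j <- p + k
      if (k == 1L) sprintf("p.%s%ddup", aa3[r[i]], i)
      else sprintf("p.%s%d_%s%ddup", aa3[r[i]], i, aa3[r[j]], j)
    } else if (precedes) {
      i <- p - k + 1L
      if (k == 1L) sprintf("p.%s%ddup", aa3[r[p]], p)
      else sprintf("p.%s%d_%s%ddup", aa3[r[i]], i, aa3[r[p]], p)
    } else {
      sprintf("p.%s%d_%s%dins%s", aa3[r[p]], p, aa3[r[p + 1L]], p + 1L,
              A(mut_mid))
    }
  } else {                                             # delins
    i <- p + 1L; j <- p + length(ref_mid)
    if (i == j) sprintf("p.%s%ddelins%s", aa3[r[i]], i, A(mut_mid))
    else sprintf("p.%s%d_%s%ddelins%s", aa3[r[i]], i, aa3[r[j]], j,
                 A(mut_mid))
  }
}
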