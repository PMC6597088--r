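# Independent oracles and tiny fixture constructors. Everything here is
# deliberately written with different algorithms than the package code paths
# it checks (string comparison, explicit enumeration, dense linear algebra).

toy_genome <- function(...) {
  seqs <- c(...)
  structure(list(seq = seqs, genes = list()), class = "sim_genome")
}

# Mutated-chromosome string for one record: the representation-free identity
# of an edit. Two records are the same edit iff their mutated strings match.
oracle_mutate <- function(genome, chrom, pos, ref, alt) {
  s <- genome$seq[[chrom]]
  if (substr(s, pos, pos + nchar(ref) - 1L) != ref) stop("ref mismatch")
  paste0(substr(s, 1L, pos - 1L), alt,
         substr(s, pos + nchar(ref), nchar(s, type = "bytes")))
}

# Closed-form left-aligned minimal representation derived from the
# (reference, mutated) string pair: maximize the common suffix, then the
# common prefix, then re-anchor. Independent of normalize_variants().
oracle_normalize <- function(genome, chrom, pos, ref, alt) {
  rs <- genome$seq[[chrom]]
  ms <- oracle_mutate(genome, chrom, pos, ref, alt)
  nr <- nchar(rs, type = "bytes"); nm <- nchar(ms, type = "bytes")
  S <- 0L
  while (S < min(nr, nm) &&
         substr(rs, nr - S, nr - S) == substr(ms, nm - S, nm - S)) S <- S + 1L
  P <- 0L
  while (P < min(nr, nm) - S && substr(rs, P + 1L, P + 1L) ==
         substr(ms, P + 1L, P + 1L)) P <- P + 1L
  delp <- substr(rs, P + 1L, nr - S)
  insp <- substr(ms, P + 1L, nm - S)
  list(chrom = chrom, pos = P, ref = paste0(substr(rs, P, P), delp),
       alt = paste0(substr(rs, P, P), insp),
       key = paste(chrom, P, paste0(substr(rs, P, P), delp),
                   paste0(substr(rs, P, P), insp), sep = ":"))
}

# Brute-force consensus: intersect call-sets by mutated-string identity,
# resolve genotypes by explicit per-cell vote counting, filter multi-allelic
# positions (using the oracle-normalized position) and fixed-alt variants.
oracle_consensus <- function(callsets, genome, require_complete = TRUE) {
  ids <- lapply(callsets, function(cs) {
    v <- cs$variants
    vapply(seq_len(nrow(v)), function(i)
      paste(v$chrom[i],
            oracle_mutate(genome, v$chrom[i], v$pos[i], v$ref[i], v$alt[i]),
            sep = "|"), "")
  })
  ids <- lapply(ids, function(x) x[!duplicated(x)])
  keep_geno <- lapply(seq_along(callsets), function(k) {
    v <- callsets[[k]]$variants
    full <- vapply(seq_len(nrow(v)), function(i)
      paste(v$chrom[i],
            oracle_mutate(genome, v$chrom[i], v$pos[i], v$ref[i], v$alt[i]),
            sep = "|"), "")
    callsets[[k]]$geno[!duplicated(full), , drop = FALSE]
  })
  common <- Reduce(intersect, ids)
  if (!length(common)) return(character(0))
  ns <- ncol(callsets[[1]]$geno)
  res <- list()
  for (id in common) {
    gs <- lapply(seq_along(callsets), function(k)
      keep_geno[[k]][match(id, ids[[k]]), ])
    resolved <- integer(ns); bad <- FALSE
    n_nonmiss_total <- 0L
    for (s in seq_len(ns)) {
      votes <- vapply(gs, function(g) g[s], 0L)
      votes <- votes[!is.na(votes)]
      n_nonmiss_total <- n_nonmiss_total + length(votes)
      if (!length(votes)) { resolved[s] <- NA_integer_; next }
      tab <- table(votes)
      if (max(tab) >= 2L) resolved[s] <- as.integer(names(tab)[which.max(tab)])
      else if (length(votes) == 1L) resolved[s] <- votes
      else bad <- TRUE
    }
    if (bad || n_nonmiss_total == 0L) next
    res[[id]] <- resolved
  }
  if (!length(res)) return(character(0))
  # multi-allelic filter on oracle-normalized positions (ids are whole
  # mutated chromosomes, so index them rather than use them as names)
  all_ids <- character(0); all_norms <- list()
  for (k in seq_along(callsets)) {
    v <- callsets[[k]]$variants
    for (i in seq_len(nrow(v))) {
      id <- paste(v$chrom[i],
                  oracle_mutate(genome, v$chrom[i], v$pos[i], v$ref[i],
                                v$alt[i]), sep = "|")
      if (!id %in% all_ids) {
        all_ids <- c(all_ids, id)
        all_norms[[length(all_norms) + 1L]] <-
          oracle_normalize(genome, v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
      }
    }
  }
  nm_of <- function(id) all_norms[[match(id, all_ids)]]
  keys <- vapply(names(res), function(id) nm_of(id)$key, "")
  posid <- vapply(names(res), function(id)
    paste(nm_of(id)$chrom, nm_of(id)$pos, sep = ":"), "")
  alts <- vapply(names(res), function(id) nm_of(id)$alt, "")
  multi <- posid %in% names(which(tapply(alts, posid, function(a)
    length(unique(a))) > 1L))
  fixed <- vapply(names(res), function(id) {
    g <- res[[id]]
    if (require_complete) !any(is.na(g)) && all(g == 2L)
    else sum(!is.na(g)) > 0L && all(g[!is.na(g)] == 2L)
  }, TRUE)
  sort(unname(keys[!multi & !fixed]))
}

# Brute-force Benjamini-Hochberg step-up by the definition, double loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# Explicit dense GLS with the marker appended to the design matrix;
# t-test on n - p - 1 df. The oracle route for the rotated fast scan.
oracle_gls <- function(y, X, g, V) {
  Xa <- cbind(X, g)
  Vi <- solve(V)
  A <- solve(t(Xa) %*% Vi %*% Xa)
  b <- A %*% t(Xa) %*% Vi %*% y
  r <- y - Xa %*% b
  df <- length(y) - ncol(Xa)
  s2 <- drop(t(r) %*% Vi %*% r) / df
  se <- sqrt(s2 * A[ncol(Xa), ncol(Xa)])
  stat <- drop(b[ncol(Xa)]) / se
  list(a = drop(b[ncol(Xa)]), se = se, stat = stat,
       p = 2 * stats::pt(-abs(stat), df))
}

# Deterministic hand-built single-gene genome for consequence tests.
# Plus-strand layout (all coordinates 1-based):
#   6000 bp flank | exon1 = 12 bp UTR5 + CDS[1..30] | 100 bp intron1 |
#   exon2 = CDS[31..60] | 100 bp intron2 | exon3 = CDS[61..90] + 12 bp UTR3 |
#   6000 bp flank
# CDS codons (30): ATG, GCT(Ala2), GCA(Ala3), then fixed non-stop codons,
# ending TAA. For strand = "-", the entire chromosome is reverse-complemented
# and all intervals are flipped, so the transcript content is identical.
toy_gene <- function(strand = "+", seed = 404) {
  set.seed(seed)
  # codon 20 ends exon 2; TAC (not TGG) so no base run spans the junction
  codons <- c("ATG", "GCT", "GCA", "TGT", "GAA", "TTC", "GGA", "CAT", "ATC",
              "AAA", "CTG", "ATG", "AAC", "CCT", "CAA", "CGT", "AGC", "ACT",
              "GTA", "TAC", "TAC", "GTC", "GAC", "TTG", "GCC", "AGA", "AAG",
              "CTC", "CCG", "TAA")
  cds <- paste(codons, collapse = "")          # 90 nt
  u5 <- "TTCTTCTTCTTC"; u3 <- "GAAGGAAGGAAG"
  flank1 <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  # period-3 intron body: 2-bp edits in it are never shift-equivalent, so
  # splice-window test cases keep their anchors after normalization
  intron1 <- paste0("GT", strrep("ACT", 32), "AG")
  intron2 <- paste0("GT", strrep("ACT", 32), "AG")
  exon1 <- paste0(u5, substr(cds, 1, 30))      # 42 bp
  exon2 <- substr(cds, 31, 60)                 # 30 bp
  exon3 <- paste0(substr(cds, 61, 90), u3)     # 42 bp
  chrom_seq <- paste0(flank1, exon1, intron1, exon2, intron2, exon3, flank2)
  e1s <- 6001L; e1e <- e1s + 42L - 1L
  i1s <- e1e + 1L; i1e <- i1s + 100L - 1L
  e2s <- i1e + 1L; e2e <- e2s + 30L - 1L
  i2s <- e2e + 1L; i2e <- i2s + 100L - 1L
  e3s <- i2e + 1L; e3e <- e3s + 42L - 1L
  exons <- cbind(c(e1s, e2s, e3s), c(e1e, e2e, e3e))
  cdsm <- cbind(c(e1s + 12L, e2s, e3s), c(e1e, e2e, e3s + 29L))
  L <- nchar(chrom_seq)
  if (strand == "-") {
    chrom_seq <- indelscan:::revcomp(chrom_seq)
    flip <- function(m) {
      out <- cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
      out[order(out[, 1]), , drop = FALSE]
    }
    exons <- flip(exons); cdsm <- flip(cdsm)
  }
  gene <- list(gene_id = "toy", chrom = "chrT", strand = strand,
               biotype = "coding", tags = character(0),
               transcripts = list(list(transcript_id = "toy.t1",
                                       exons = exons, cds = cdsm)))
  genome <- structure(list(seq = c(chrT = chrom_seq), genes = list(gene)),
                      class = "sim_genome")
  # genomic coordinate of CDS offset k (1..90), and of intron starts
  cds_g <- function(k) {
    if (strand == "+") {
      if (k <= 30) e1s + 12L + k - 1L
      else if (k <= 60) e2s + (k - 31L)
      else e3s + (k - 61L)
    } else {
      L - (if (k <= 30) e1s + 12L + k - 1L
           else if (k <= 60) e2s + (k - 31L)
           else e3s + (k - 61L)) + 1L
    }
  }
  list(genome = genome, gene = gene, cds = cds, cds_g = cds_g,
       coords = list(e1s = e1s, e1e = e1e, i1s = i1s, i1e = i1e, e2s = e2s,
                     e2e = e2e, i2s = i2s, i2e = i2e, e3s = e3s, e3e = e3e,
                     L = L))
}

# The consequence truth table: 18 hand-derived cases on the toy gene, one
# per coding/splice/UTR/flank behaviour. Each expectation was derived by
# applying the edit to the transcript sequence and translating (see the
# per-case notes). Returns cases with alleles materialized from the genome.
consequence_truth_cases <- function(tg) {
  cases <- list(
    # 1: inframe deletion of codon 2 (GCT) -> p.Ala2del, the headline pattern
    list(pos = 6015, ref = "GGCT", alt = "G",
         terms = c("inframe_deletion"), sev = "Moderate", pc = "p.Ala2del"),
    # 2: 4-bp insertion mid-CDS -> frameshift
    list(pos = 6151, ref = "C", alt = "CAGAC",
         terms = c("frameshift_variant"), sev = "High", pc = NA),
    # 3: intergenic, 5.8 kb from the transcript
    list(pos = 200, ref = "ig", alt = "ig",
         terms = c("intergenic_variant"), sev = "Modifier", pc = NA),
    # 4: upstream within the 5 kb flank
    list(pos = 2000, ref = "ig", alt = "ig",
         terms = c("upstream_gene_variant"), sev = "Modifier", pc = NA),
    # 5: downstream within the 5 kb flank
    list(pos = 8000, ref = "ig", alt = "ig",
         terms = c("downstream_gene_variant"), sev = "Modifier", pc = NA),
    # 6: deep intron 1
    list(pos = 6089, ref = "del2", alt = "",
         terms = c("intron_variant"), sev = "Modifier", pc = NA),
    # 7: first two intron-1 bases -> splice donor
    list(pos = 6042, ref = "del2", alt = "",
         terms = c("splice_donor_variant"), sev = "High", pc = NA),
    # 8: last two intron-1 bases -> splice acceptor
    list(pos = 6140, ref = "del2", alt = "",
         terms = c("splice_acceptor_variant"), sev = "High", pc = NA),
    # 9: intron base 5 -> splice region (+ intron)
    list(pos = 6046, ref = "del1", alt = "",
         terms = c("intron_variant", "splice_region_variant"), sev = "Low",
         pc = NA),
    # 10: deletion of one A of codon 10 (AAA), within the last 3 exon-1
    # bases: frameshift + splice region, and the shifted frame hits TGA at
    # the edit (codon 11 CTG becomes TGA) -> stop gained
    list(pos = 6039, ref = "CA", alt = "C",
         terms = c("frameshift_variant", "splice_region_variant",
                   "stop_gained"),
         sev = "High", pc = NA),
    # 11: 5' UTR insertion
    list(pos = 6005, ref = "T", alt = "TG",
         terms = c("5_prime_UTR_variant"), sev = "Modifier", pc = NA),
    # 12: 3' UTR deletion
    list(pos = 6304, ref = "AAG", alt = "A",
         terms = c("3_prime_UTR_variant"), sev = "Modifier", pc = NA),
    # 13: deletion covering the start codon
    list(pos = 6012, ref = "CATG", alt = "C",
         terms = c("inframe_deletion", "start_lost"), sev = "High", pc = NA),
    # 14: deletion of the stop codon, no new stop -> stop lost
    list(pos = 6299, ref = "GTAA", alt = "G",
         terms = c("inframe_deletion", "stop_lost"), sev = "High", pc = NA),
    # 15: frameshift insertion inside the stop that recreates a stop
    list(pos = 6300, ref = "T", alt = "TAA",
         terms = c("frameshift_variant", "stop_retained_variant"),
         sev = "High", pc = NA),
    # 16: inframe insertion of TGA at a codon boundary -> stop gained
    list(pos = 6154, ref = "T", alt = "TTGA",
         terms = c("inframe_insertion", "stop_gained"), sev = "High",
         pc = NA),
    # 17: inframe insertion duplicating an Ala codon -> p.Ala2dup
    list(pos = 6018, ref = "T", alt = "TGCT",
         terms = c("inframe_insertion"), sev = "Moderate", pc = "p.Ala2dup"),
    # 18: non-codon-aligned inframe deletion -> delins, protein altering
    list(pos = 6025, ref = "GAAT", alt = "G",
         terms = c("inframe_deletion", "protein_altering_variant"),
         sev = "Moderate", pc = "p.Glu5_Phe6delinsVal"))
  lapply(cases, function(cs) {
    if (identical(cs$ref, "ig")) {
      b <- substr(tg$genome$seq[["chrT"]], cs$pos, cs$pos)
      ins <- setdiff(c("A", "C", "G", "T"), b)[1]
      cs$ref <- b; cs$alt <- paste0(b, ins)
    } else if (cs$ref %in% c("del1", "del2")) {
      len <- if (cs$ref == "del1") 1L else 2L
      cs$ref <- substr(tg$genome$seq[["chrT"]], cs$pos, cs$pos + len)
      cs$alt <- substr(cs$ref, 1, 1)
    }
    cs
  })
}

# terms string -> sorted character vector
term_set <- function(x) sort(strsplit(x, ",", fixed = TRUE)[[1]])

# quick minimal callset constructor
make_callset <- function(chrom, pos, ref, alt, geno, samples, caller = "c") {
  g <- if (is.matrix(geno)) geno
  else matrix(as.integer(geno), nrow = length(pos), byrow = TRUE)
  storage.mode(g) <- "integer"
  colnames(g) <- samples
  structure(list(variants = data.frame(chrom = chrom, pos = as.integer(pos),
                                       ref = ref, alt = alt,
                                       stringsAsFactors = FALSE),
                 geno = g, samples = samples, caller = caller, skipped = 0L),
            class = "callset")
}
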