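# The toy gene (helper-oracles.R) has a fully known layout, so every case
# below is placed at a hand-computed offset and its expected term set was
# derived by applying the edit to the transcript sequence and translating.
# An automated sequence-edit oracle re-derives the mutant protein for the
# coding cases.

# independent route: apply the edit to the chromosome, shift the annotation
# intervals past the edit, re-extract the CDS and translate it
oracle_mutant_protein <- function(tg, pos, ref, alt) {
  genome <- tg$genome
  gene <- tg$gene
  tx <- gene$transcripts[[1]]
  mut <- oracle_mutate(genome, "chrT", pos, ref, alt)
  delta <- nchar(alt) - nchar(ref)
  edit_at <- pos + 1L   # first base after the anchor
  shift <- function(x) ifelse(x >= edit_at, x + delta, x)
  cds <- cbind(shift(tx$cds[, 1]), shift(tx$cds[, 2]))
  pieces <- vapply(seq_len(nrow(cds)), function(k)
    substr(mut, cds[k, 1], cds[k, 2]), "")
  cds_seq <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds_seq <- indelscan:::revcomp(cds_seq)
  translate_cds(cds_seq)
}

annotate_toy <- function(tg, pos, ref, alt) {
  nk <- normalize_variants("chrT", pos, ref, alt, tg$genome)
  annotate_variants(nk, tg$genome)
}

test_that("consequence truth table matches hand-derived oracle cases", {
  tg <- toy_gene("+")
  co <- tg$coords
  ref_protein <- translate_cds(tg$cds)
  cases <- consequence_truth_cases(tg)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    ann <- annotate_toy(tg, cs$pos, cs$ref, cs$alt)
    expect_equal(nrow(ann), 1L, info = paste("case", i))
    expect_equal(term_set(ann$terms), sort(cs$terms),
                 info = paste("case", i))
    expect_equal(ann$severity, cs$sev, info = paste("case", i))
    if (!is.na(cs$pc))
      expect_equal(ann$protein_change, cs$pc, info = paste("case", i))
    # sequence-edit + translation oracle for the coding cases
    if (any(c("inframe_deletion", "inframe_insertion", "frameshift_variant")
            %in% cs$terms)) {
      aa_mut <- oracle_mutant_protein(tg, cs$pos, cs$ref, cs$alt)
      d <- nchar(cs$alt) - nchar(cs$ref)
      if (d %% 3 != 0)
        expect_true("frameshift_variant" %in% term_set(ann$terms))
      if (i == 1)   # codon-2 deletion: protein loses exactly one Ala
        expect_identical(aa_mut, sub("A", "", ref_protein))
      if (i == 14)  # stop deleted: no terminal stop remains
        expect_false(grepl("*", aa_mut, fixed = TRUE))
      if (i == 15)  # stop recreated despite the frameshift
        expect_identical(substr(aa_mut, 30, 30), "*")
      if (i == 16)  # premature stop at codon 15
        expect_identical(substr(aa_mut, 15, 15), "*")
      if (i == 17)  # duplicated Ala
        expect_identical(substr(aa_mut, 1, 4), "MAAA")
    }
  }
})

test_that("incomplete terminal codon, NMD tag, non-coding and miRNA biotypes", {
  tg <- toy_gene("+")
  co <- tg$coords
  # CDS stretched by one base: length 91, partial terminal codon
  g2 <- tg$genome
  g2$genes[[1]]$transcripts[[1]]$cds[3, 2] <-
    g2$genes[[1]]$transcripts[[1]]$cds[3, 2] + 1L
  nk <- normalize_variants("chrT", co$e3s + 29L,
                           substr(g2$seq[["chrT"]], co$e3s + 29L,
                                  co$e3s + 30L),
                           substr(g2$seq[["chrT"]], co$e3s + 29L,
                                  co$e3s + 29L), g2)
  ann <- annotate_variants(nk, g2)
  expect_true("incomplete_terminal_codon_variant" %in% term_set(ann$terms))
  # NMD-tagged transcript
  g3 <- tg$genome
  g3$genes[[1]]$tags <- "NMD"
  nk3 <- normalize_variants("chrT", 6089, substr(g3$seq[["chrT"]], 6089, 6091),
                            substr(g3$seq[["chrT"]], 6089, 6089), g3)
  ann3 <- annotate_variants(nk3, g3)
  expect_setequal(term_set(ann3$terms),
                  c("intron_variant", "NMD_transcript_variant"))
  # non-coding biotype: exon and intron
  g4 <- tg$genome
  g4$genes[[1]]$biotype <- "non_coding"
  g4$genes[[1]]$transcripts[[1]]$cds <- NULL
  nk4 <- normalize_variants("chrT", 6020, substr(g4$seq[["chrT"]], 6020, 6021),
                            substr(g4$seq[["chrT"]], 6020, 6020), g4)
  ann4 <- annotate_variants(nk4, g4)
  expect_equal(term_set(ann4$terms), "non_coding_transcript_exon_variant")
  ann5 <- annotate_variants(normalize_variants("chrT", 6089,
                                               substr(g4$seq[["chrT"]], 6089,
                                                      6090),
                                               substr(g4$seq[["chrT"]], 6089,
                                                      6089), g4), g4)
  expect_setequal(term_set(ann5$terms),
                  c("intron_variant", "non_coding_transcript_variant"))
  # miRNA biotype, exonic
  g6 <- g4
  g6$genes[[1]]$biotype <- "miRNA"
  ann6 <- annotate_variants(nk4, g6)
  expect_equal(term_set(ann6$terms), "mature_miRNA_variant")
  # unknown chromosome errors
  expect_error(annotate_variants(data.frame(chrom = "nope", pos = 5,
                                            ref = "AA", alt = "A"),
                                 tg$genome), "unknown chromosome")
  # SNP input rejected
  expect_error(annotate_variants(data.frame(chrom = "chrT", pos = 5,
                                            ref = "A", alt = "C"),
                                 tg$genome), "indels only")
})

test_that("frameshift law and strand symmetry hold over random CDS indels", {
  set.seed(99)
  tgs <- list(toy_gene("+"), toy_gene("-"))
  seg_bounds <- list(c(10L, 30L), c(35L, 60L), c(65L, 84L))  # cds offsets
  for (rep in 1:250) {
    tg <- tgs[[1]]
    len <- sample(1:5, 1)
    del <- runif(1) < 0.5
    b <- seg_bounds[[sample(3, 1)]]
    # anchor k: the edit (k+1 .. k+len for deletions) stays inside one
    # exon segment of the CDS
    hi <- if (del) b[2] - len else b[2] - 1L
    if (hi < b[1]) next
    k <- sample(b[1]:hi, 1)
    gpos <- tg$cds_g(k)
    s <- tg$genome$seq[["chrT"]]
    if (del) {
      ref <- substr(s, gpos, gpos + len)
      alt <- substr(s, gpos, gpos)
    } else {
      ref <- substr(s, gpos, gpos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = ""))
    }
    nk <- normalize_variants("chrT", gpos, ref, alt, tg$genome)
    ann <- annotate_variants(nk, tg$genome)
    terms <- term_set(ann$terms[1])
    coding_classified <- any(c("frameshift_variant", "inframe_deletion",
                               "inframe_insertion") %in% terms)
    if (coding_classified) {
      expect_equal("frameshift_variant" %in% terms, len %% 3 != 0,
                   info = sprintf("k=%d len=%d del=%d", k, len, del))
    } else {
      # the normalized edit must have straddled an exon boundary
      expect_true(any(grepl("splice|coding_sequence", terms)),
                  info = sprintf("k=%d len=%d del=%d", k, len, del))
    }
    # strand symmetry: the same physical edit on the reverse-complemented
    # world, re-anchored (not re-normalized: left-alignment direction is a
    # representation choice, the annotated footprint must be identical)
    tgm <- tgs[[2]]
    L <- tg$coords$L
    mseq <- tgm$genome$seq[["chrT"]]
    if (nchar(nk$ref) > nchar(nk$alt)) {       # deletion of [pos+1, b]
      b <- nk$pos + nchar(nk$ref) - 1L
      pos_m <- L - b
      ref_m <- substr(mseq, pos_m, pos_m + nchar(nk$ref) - 1L)
      alt_m <- substr(mseq, pos_m, pos_m)
    } else {                                   # insertion after pos
      pos_m <- L - nk$pos
      ref_m <- substr(mseq, pos_m, pos_m)
      alt_m <- paste0(ref_m,
                      indelscan:::revcomp(substr(nk$alt, 2,
                                                 nchar(nk$alt))))
    }
    nkm <- data.frame(chrom = "chrT", pos = pos_m, ref = ref_m, alt = alt_m,
                      stringsAsFactors = FALSE)
    annm <- annotate_variants(nkm, tgm$genome)
    expect_equal(term_set(annm$terms[1]), term_set(ann$terms[1]),
                 info = sprintf("strand k=%d len=%d del=%d", k, len, del))
  }
})

test_that("severity map is frozen and aggregation is the documented maximum", {
  m <- severity_map()
  expect_equal(unname(m[c("frameshift_variant", "splice_acceptor_variant",
                          "splice_donor_variant", "start_lost", "stop_gained",
                          "stop_lost")]), rep("High", 6))
  expect_equal(unname(m[c("inframe_deletion", "inframe_insertion",
                          "protein_altering_variant")]), rep("Moderate", 3))
  expect_equal(unname(m[c("splice_region_variant", "stop_retained_variant",
                          "incomplete_terminal_codon_variant")]),
               rep("Low", 3))
  expect_equal(sum(m == "Modifier"), 11L)
  expect_length(m, 23L)
  expect_equal(severity_of(c("frameshift_variant", "stop_retained_variant")),
               "High")
  expect_equal(severity_of("intron_variant"), "Modifier")
  expect_equal(severity_of(c("splice_region_variant", "intron_variant")),
               "Low")
  expect_error(severity_of("made_up_term"), "unknown")
  # monotone under union, property-checked
  set.seed(3)
  for (i in 1:40) {
    a <- sample(names(m), sample(1:4, 1))
    b <- sample(names(m), sample(1:4, 1))
    lv <- c("Modifier", "Low", "Moderate", "High")
    expect_gte(match(severity_of(union(a, b)), lv),
               match(severity_of(a), lv))
  }
})

test_that("annotation count grows with overlapping transcripts", {
  tg <- toy_gene("+")
  g <- tg$genome
  tx2 <- g$genes[[1]]$transcripts[[1]]
  tx2$transcript_id <- "toy.t2"
  g$genes[[1]]$transcripts[[2]] <- tx2
  nk <- normalize_variants("chrT", 6089, substr(g$seq[["chrT"]], 6089, 6091),
                           substr(g$seq[["chrT"]], 6089, 6089), g)
  ann <- annotate_variants(nk, g)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$transcript_id, c("toy.t1", "toy.t2"))
})

test_that("protein_change_string handles the documented notations", {
  # hand case: ATG GCT GCA TAA minus codon 2
  expect_equal(protein_change_string(translate_cds("ATGGCTGCATAA"),
                                     translate_cds("ATGGCATAA")),
               "p.Ala2del")
  # duplication of codon 2
  expect_equal(protein_change_string(translate_cds("ATGGCTGCATAA"),
                                     translate_cds("ATGGCTGCTGCATAA")),
               "p.Ala2dup")
  # plain insertion
  expect_equal(protein_change_string("MKYW*", "MKYDW*"),
               "p.Tyr3_Trp4insAsp")
  # multi-residue deletion
  expect_equal(protein_change_string("MKYDW*", "MKW*"), "p.Tyr3_Asp4del")
  expect_null(protein_change_string("MKYW*", "MKYW*"))
})
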