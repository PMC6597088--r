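#' Left-align and minimalize an indel or SNP representation
#'
#' Reduces a VCF-style (chrom, pos, ref, alt) record to its canonical
#' normalized key: identical trailing bases are trimmed; whenever an allele
#' would become empty the preceding genome base is prepended and trimming
#' resumes, which walks the record to its leftmost equivalent position;
#' finally shared leading bases are trimmed down to a single anchor base.
#' Two records describe the same edit if and only if they normalize to the
#' same key, which is what makes call-sets from different callers
#' intersectable.
#'
#' @param chrom,pos,ref,alt vectors describing one record per element;
#'   `pos` is 1-based and for indels points at the anchor base (the base
#'   preceding the inserted/deleted sequence).
#' @param genome a `sim_genome` object or any named character vector of
#'   chromosome sequences.
#' @return a data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`
#'   (the string `chrom:pos:ref:alt`).
#' @examples
#' g <- list(seq = c(chr1 = "GGCAAATTT"))
#' class(g) <- "sim_genome"
#' # deletion of one A in the A-homopolymer, given right-shifted:
#' normalize_variants("chr1", 5, "AA", "A", g) # -> pos 3, ref CA, alt C
#' @export
normalize_variants <- function(chrom, pos, ref, alt, genome) {
  seqs <- genome_seqs(genome)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      key = character(), stringsAsFactors = FALSE))
  }
  if (any(ref == alt))
    stop("ref and alt alleles must differ")
  bad <- !(chrom %in% names(seqs))
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  # validate ref against genome
  obs <- substr_at(seqs, chrom, pos, nchar(ref))
  mm <- which(obs != ref)
  if (length(mm))
    stop(sprintf("reference allele mismatch at %s:%d (genome '%s' vs record '%s')",
                 chrom[mm[1]], pos[mm[1]], obs[mm[1]], ref[mm[1]]))
  # fast path: already minimal & left-aligned -- last bases differ, at most one
  # shared leading anchor base, and no further left extension possible
  rl <- nchar(ref); al <- nchar(alt)
  last_r <- substr(ref, rl, rl); last_a <- substr(alt, al, al)
  minimal <- last_r != last_a & (rl == 1L | al == 1L | substr(ref, 1, 1) != substr(alt, 1, 1))
  # a minimal record can still be shiftable only if one allele has length >1
  # and shares its first base with the other; handled above, so `minimal`
  # records are final except SNP-like multi-base cases:
  need_work <- !minimal
  pos <- as.integer(pos)
  for (i in which(need_work)) {
    v <- normalize_one(seqs[[chrom[i]]], pos[i], ref[i], alt[i])
    pos[i] <- v$pos; ref[i] <- v$ref; alt[i] <- v$alt
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

normalize_one <- function(seq, pos, ref, alt) {
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L && substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      next
    }
    if (rl == 0L || al == 0L) {
      if (pos <= 1L)
        stop("cannot left-extend past the start of the chromosome at pos 1")
      b <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
      next
    }
    break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a normalized indel as insertion or deletion
#'
#' @param ref,alt normalized allele strings (vectors allowed).
#' @return data.frame with columns `class` ("deletion"/"insertion") and
#'   `length` (absolute ref/alt length difference). SNP input is an error.
#' @export
variant_class <- function(ref, alt) {
  d <- nchar(ref) - nchar(alt)
  if (any(d == 0L))
    stop("variant_class() is defined for indels only; got same-length alleles")
  data.frame(class = ifelse(d > 0L, "deletion", "insertion"),
             length = abs(d), stringsAsFactors = FALSE)
}

# Apply one normalized variant to a chromosome sequence (reference oracle
# duties and mutant-CDS construction both funnel through this).
apply_variant_to_seq <- function(seq, pos, ref, alt) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
    stop("ref allele does not match the sequence at pos ", pos)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq, type = "bytes")))
}

# Re-express a left-aligned indel in an equivalent right-shifted (or padded)
# representation. Used by the caller simulator to emulate placement
# disagreement between variant callers. Returns a list(pos, ref, alt).
shift_representation <- function(seq, pos, ref, alt, max_shift = 30L) {
  if (nchar(ref) == nchar(alt)) stop("shift_representation needs an indel")
  del <- nchar(ref) > nchar(alt)
  core <- if (del) substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
  k <- nchar(core)
  L <- nchar(seq, type = "bytes")  # O(1); nchar() scans the whole string
  shifted <- 0L
  while (shifted < max_shift) {
    nxt_pos <- pos + 1L + (if (del) k else 0L)
    if (nxt_pos > L) break
    nxt <- substr(seq, nxt_pos, nxt_pos)
    if (nxt != substr(core, 1L, 1L)) break
    core <- paste0(substr(core, 2L, k), nxt)
    pos <- pos + 1L
    shifted <- shifted + 1L
  }
  anchor <- substr(seq, pos, pos)
  if (shifted == 0L) {
    # non-repetitive context: pad with one extra trailing genome base instead
    tail_pos <- pos + nchar(ref)
    if (tail_pos <= L) {
      b <- substr(seq, tail_pos, tail_pos)
      return(list(pos = pos, ref = paste0(ref, b), alt = paste0(alt, b)))
    }
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (del) {
    list(pos = pos, ref = paste0(anchor, core), alt = anchor)
  } else {
    list(pos = pos, ref = anchor, alt = paste0(anchor, core))
  }
}

# vectorized substring over a named sequence vector
substr_at <- function(seqs, chrom, pos, len) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- substring(seqs[[ch]], pos[i], pos[i] + len[i] - 1L)
  }
  out
}

genome_seqs <- function(genome) {
  if (inherits(genome, "sim_genome")) genome$seq
  else if (is.character(genome) && !is.null(names(genome))) genome
  else stop("genome must be a sim_genome or a named character vector of sequences")
}
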