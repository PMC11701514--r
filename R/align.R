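#' Alignment scoring scheme
#'
#' Affine-gap scores for aligning amplicon reads to the reference array. A
#' gap of length L costs `gap_open + (L - 1) * gap_extend`. The default
#' extension penalty is deliberately small: recorder alleles routinely carry
#' deletions tens of nucleotides long, and a near-linear long-gap cost would
#' let spurious end matching outscore the true deletion.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).
#' @return A named list.
#' @export
align_scoring <- function(match = 2, mismatch = -2, gap_open = -6,
                          gap_extend = -0.2) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Align one amplicon read to the barcode reference
#'
#' Affine-gap (Gotoh) alignment of `seq` against the reference amplicon. The
#' read is aligned end to end; by default the trailing portion of the
#' reference may be left unaligned at no cost (`free_ref_tail`), modelling a
#' fixed-cycle read that stops before the amplicon's end. Tie-breaking is
#' deterministic, and gap runs are post-normalized to their leftmost
#' equivalent placement, so equivalent alignments yield identical alleles.
#'
#' A read is unmappable (`mapped = FALSE`, no ops) when it is shorter than
#' `min_read_len` (short amplicons produced by large deletions cannot be
#' placed unambiguously) or when its aligned identity — the fraction of read
#' bases matching the reference — falls below `identity_floor`. Identity is
#' taken over read bases rather than reference columns so that genuine long
#' deletions (which remove reference columns) do not depress it, while
#' chimeric or foreign reads (whose bases cannot all be matched) do.
#'
#' @param seq Read nucleotide string (A/C/G/T/N; N never matches).
#' @param ref A [saber_reference()].
#' @param scoring An [align_scoring()] list.
#' @param min_read_len Minimum read length for mappability (nt).
#' @param identity_floor Minimum aligned identity for mappability.
#' @param free_ref_tail Leave a trailing reference suffix unpenalized.
#' @return A list of class `saber_alignment`: `mapped`, `score`, `ops`
#'   (data.frame `op`/`len`/`ref_start`/`read_start`), `matches`,
#'   `mismatches`, `identity`, `ref_aligned_end`, `read_length`.
#' @export
align_read <- function(seq, ref, scoring = align_scoring(),
                       min_read_len = 50L, identity_floor = 0.75,
                       free_ref_tail = TRUE) {
  seq <- toupper(seq)
  if (is.na(seq) || !nzchar(seq)) stop("empty read sequence")
  if (!grepl("^[ACGTN]+$", seq)) stop("read contains non-ACGTN characters")
  refseq <- ref_amplicon(ref)
  unmapped <- function(score = NA_real_) {
    structure(list(mapped = FALSE, score = score,
                   ops = data.frame(op = character(), len = integer(),
                                    ref_start = integer(), read_start = integer()),
                   matches = 0L, mismatches = 0L, identity = NA_real_,
                   ref_aligned_end = NA_integer_, read_length = nchar(seq)),
              class = "saber_alignment")
  }
  if (nchar(seq) < min_read_len) return(unmapped())
  a <- .gotoh_align_cpp(seq, refseq, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend, free_ref_tail)
  ops <- data.frame(op = a$op, len = a$len, ref_start = a$ref_start,
                    read_start = a$read_start, stringsAsFactors = FALSE)
  ident <- a$matches / nchar(seq)
  if (ident < identity_floor) return(unmapped(a$score))
  structure(list(mapped = TRUE, score = a$score, ops = ops,
                 matches = a$matches, mismatches = a$mismatches,
                 identity = ident, ref_aligned_end = a$ref_aligned_end,
                 read_length = nchar(seq)),
            class = "saber_alignment")
}

#' Extract the allele carried by an aligned read
#'
#' Converts each gap run of a mapped alignment into one edit event (deletions
#' from `D` runs, insertions from `I` runs; substitutions are treated as
#' sequencing noise, not edits), left-normalizes gap placement, and summarizes
#' the result via [allele_summary()]. Coordinates are reported on the full
#' reference `sequence` (amplicon offset applied).
#'
#' @param aln A mapped `saber_alignment`.
#' @param ref The [saber_reference()] it was aligned to.
#' @param read_seq The read sequence (required to recover inserted bases when
#'   the alignment contains `I` runs).
#' @return `list(events, canonical, edited_sites, status)`.
#' @export
extract_allele <- function(aln, ref, read_seq = NULL) {
  if (!isTRUE(aln$mapped)) stop("extract_allele() requires a mapped alignment")
  ev <- ops_to_events(aln$ops, ref, read_seq,
                      offset = ref$primer_sites$start[1])
  s <- allele_summary(ev, ref)
  c(list(events = ev), s)
}

ops_to_events <- function(ops, ref, read_seq, offset = 0L) {
  gaps <- ops[ops$op %in% c("D", "I"), , drop = FALSE]
  if (nrow(gaps) == 0L) return(empty_events())
  seqs <- character(nrow(gaps))
  if (any(gaps$op == "I")) {
    if (is.null(read_seq)) stop("read_seq needed to recover inserted bases")
    ins <- gaps$op == "I"
    seqs[ins] <- substr(rep(toupper(read_seq), sum(ins)),
                        gaps$read_start[ins] + 1L,
                        gaps$read_start[ins] + gaps$len[ins])
  }
  ev <- edit_event(gaps$op, gaps$ref_start + offset, gaps$len, seqs)
  normalize_events(ev, ref$sequence)
}

# Canonical representation of an edited array molecule: align the full
# edited sequence back to the reference (global, both ends anchored) and
# read the events off the optimal alignment. This is the same normal form
# the caller produces, so simulated truth and called alleles are directly
# comparable; it also merges event combinations that are indistinguishable
# at the sequence level (e.g. two deletions separated by one repeated base).
infer_canonical_events <- function(edited_seq, ref, scoring = align_scoring()) {
  if (edited_seq == ref$sequence) return(empty_events())
  a <- .gotoh_align_cpp(edited_seq, ref$sequence, scoring$match,
                        scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, FALSE)
  ops <- data.frame(op = a$op, len = a$len, ref_start = a$ref_start,
                    read_start = a$read_start, stringsAsFactors = FALSE)
  ops_to_events(ops, ref, edited_seq, offset = 0L)
}

#' Align and call alleles for a batch of read sequences
#'
#' Vectorized front end over [align_read()]/[extract_allele()]: unique
#' sequences are aligned once and results propagated, which makes calling on
#' deeply duplicated amplicon libraries (UMI-duplicated reads, homoplastic
#' alleles) fast.
#'
#' @param seqs Character vector of read sequences.
#' @inheritParams align_read
#' @return data.frame with one row per input sequence: `seq`, `mapped`,
#'   `score`, `identity`, `canonical`, `edited_sites`, `status` (`unmappable`
#'   for unmapped reads).
#' @export
call_read_alleles <- function(seqs, ref, scoring = align_scoring(),
                              min_read_len = 50L, identity_floor = 0.75,
                              free_ref_tail = TRUE) {
  uniq <- unique(seqs)
  res <- lapply(uniq, function(s) {
    aln <- align_read(s, ref, scoring, min_read_len, identity_floor, free_ref_tail)
    if (!aln$mapped) {
      return(list(mapped = FALSE, score = aln$score, identity = aln$identity,
                  canonical = NA_character_, edited_sites = NA_character_,
                  status = "unmappable"))
    }
    al <- extract_allele(aln, ref, read_seq = s)
    list(mapped = TRUE, score = aln$score, identity = aln$identity,
         canonical = al$canonical, edited_sites = format_sites(al$edited_sites),
         status = al$status)
  })
  tab <- data.frame(
    seq = uniq,
    mapped = vapply(res, `[[`, logical(1), "mapped"),
    score = vapply(res, `[[`, numeric(1), "score"),
    identity = vapply(res, `[[`, numeric(1), "identity"),
    canonical = vapply(res, `[[`, character(1), "canonical"),
    edited_sites = vapply(res, `[[`, character(1), "edited_sites"),
    status = vapply(res, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  tab[match(seqs, uniq), , drop = FALSE]
}
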