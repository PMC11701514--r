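#' Collapse per-read allele calls to per-cell consensus records
#'
#' Two-stage majority vote: reads are first collapsed within each UMI
#' (majority allele among the UMI's mappable reads), then UMI alleles are
#' collapsed within each cell. Ties are broken by higher total read support,
#' then by lexicographic canonical string. A cell is flagged
#' (`conflict_flag`) when two or more distinct alleles survive per-UMI
#' consensus — with a single recorder integration these are detection
#' artifacts worth inspecting, so they are flagged rather than dropped.
#' Cells whose reads are all unmappable are reported with status
#' `unmappable` and are excluded from edited-fraction denominators
#' downstream.
#'
#' @param reads data.frame with one row per read: `cell_barcode`, `umi`,
#'   `canonical`, `edited_sites`, `status` (as from [call_read_alleles()],
#'   joined to the parsed read 1 fields).
#' @return data.frame with one row per cell: `cell_barcode`,
#'   `canonical_allele`, `edited_sites`, `status`, `n_umis` (mappable UMIs),
#'   `n_reads` (all reads), `conflict_flag`.
#' @export
collapse_cells <- function(reads) {
  needed <- c("cell_barcode", "umi", "canonical", "edited_sites", "status")
  if (!all(needed %in% names(reads))) {
    stop("reads must carry columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(reads) == 0L) {
    return(data.frame(cell_barcode = character(), canonical_allele = character(),
                      edited_sites = character(), status = character(),
                      n_umis = integer(), n_reads = integer(),
                      conflict_flag = logical(), stringsAsFactors = FALSE))
  }
  majority <- function(alleles) {
    tab <- sort(table(alleles), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    sort(top)[1]  # lexicographic tie-break
  }
  total_reads <- table(reads$cell_barcode)
  mappable <- reads[reads$status != "unmappable", , drop = FALSE]

  cells <- unique(reads$cell_barcode)
  n <- length(cells)
  canon_out <- rep(NA_character_, n)
  sites_out <- rep(NA_character_, n)
  status_out <- rep("unmappable", n)
  numis_out <- integer(n)
  conflict_out <- logical(n)
  map_split <- split(seq_len(nrow(mappable)), mappable$cell_barcode)
  sites_lookup <- mappable$edited_sites[!duplicated(mappable$canonical)]
  names(sites_lookup) <- mappable$canonical[!duplicated(mappable$canonical)]
  for (ci in seq_len(n)) {
    cb <- cells[ci]
    idx <- map_split[[cb]]
    if (is.null(idx) || length(idx) == 0L) next
    sub_canon <- mappable$canonical[idx]
    sub_umi <- mappable$umi[idx]
    per_umi <- vapply(split(sub_canon, sub_umi), majority, character(1))
    tab <- table(per_umi)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      support <- table(sub_canon)
      sup <- support[top]
      top <- top[sup == max(sup)]
      top <- sort(top)[1]
    }
    canon_out[ci] <- top
    sites_out[ci] <- if (top == "-") "" else unname(sites_lookup[top])
    status_out[ci] <- if (top == "-") "unedited" else "edited"
    numis_out[ci] <- length(per_umi)
    conflict_out[ci] <- length(tab) >= 2L
  }
  data.frame(cell_barcode = cells, canonical_allele = canon_out,
             edited_sites = sites_out, status = status_out,
             n_umis = numis_out,
             n_reads = as.integer(total_reads[cells]),
             conflict_flag = conflict_out, stringsAsFactors = FALSE)
}

#' Match cell records against a transcriptome cell-barcode whitelist
#'
#' Exact intersection on the (already error-corrected) cell barcode. The
#' recovery rate is the fraction of whitelisted (transcriptome-profiled)
#' cells for which a barcode record was recovered.
#'
#' @param records Per-cell records (from [collapse_cells()]).
#' @param whitelist Character vector of cell barcodes.
#' @return `list(matched = <records subset>, n_input, n_matched,
#'   n_unmatched, recovery_rate)`. An empty intersection is valid and
#'   produces a warning.
#' @export
match_cell_barcodes <- function(records, whitelist) {
  whitelist <- unique(as.character(whitelist))
  if (length(whitelist) == 0L) stop("whitelist is empty")
  keep <- records$cell_barcode %in% whitelist
  if (!any(keep) && nrow(records) > 0L) {
    warning("no cell barcodes matched the whitelist")
  }
  matched <- records[keep, , drop = FALSE]
  rownames(matched) <- NULL
  list(matched = matched,
       n_input = nrow(records),
       n_matched = nrow(matched),
       n_unmatched = nrow(records) - nrow(matched),
       recovery_rate = nrow(matched) / length(whitelist))
}

read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("FASTQ file is empty: ", path)
  as.character(x)
}

#' Call per-cell consensus alleles from paired FASTQ
#'
#' End-to-end single-cell calling: parse cell barcode and UMI from read 1,
#' align read 2 to the reference amplicon, extract and left-normalize edit
#' events, collapse to per-cell consensus alleles, and (optionally) match
#' against a transcriptome whitelist. Every input read is accounted for as
#' matched-mappable, matched-unmappable, or whitelist-unmatched.
#'
#' @param r1_path,r2_path Gzipped FASTQ paths (barcode read, amplicon read).
#' @param ref A [saber_reference()].
#' @param whitelist Optional character vector of error-corrected cell
#'   barcodes; `NULL` keeps all cells.
#' @param cb_length,umi_length Read-1 structure, nt.
#' @inheritParams align_read
#' @return `list(cells = <per-cell records>, summary = <list>)`. The summary
#'   reports reads in, mappable percentage, cells, and the whitelist
#'   recovery rate when a whitelist is given.
#' @export
call_alleles <- function(r1_path, r2_path, ref = default_saber_reference(),
                         whitelist = NULL, cb_length = 16L, umi_length = 12L,
                         scoring = align_scoring(), min_read_len = 50L,
                         identity_floor = 0.75) {
  r1 <- read_fastq_seqs(r1_path)
  r2 <- read_fastq_seqs(r2_path)
  if (length(r1) != length(r2)) stop("read 1 and read 2 differ in length")
  cb <- substr(r1, 1L, cb_length)
  umi <- substr(r1, cb_length + 1L, cb_length + umi_length)
  calls <- call_read_alleles(r2, ref, scoring, min_read_len, identity_floor)
  reads <- data.frame(cell_barcode = cb, umi = umi,
                      canonical = calls$canonical,
                      edited_sites = calls$edited_sites,
                      status = calls$status, stringsAsFactors = FALSE)

  whitelist_unmatched_reads <- 0L
  if (!is.null(whitelist)) {
    in_wl <- reads$cell_barcode %in% whitelist
    whitelist_unmatched_reads <- sum(!in_wl)
    reads_kept <- reads[in_wl, , drop = FALSE]
  } else {
    reads_kept <- reads
  }
  cells <- collapse_cells(reads_kept)
  recovery_rate <- NA_real_
  if (!is.null(whitelist)) {
    recovery_rate <- nrow(cells) / length(unique(whitelist))
  }
  n_mappable_reads <- sum(reads_kept$status != "unmappable")
  summary <- list(
    reads_in = length(r2),
    reads_whitelist_unmatched = whitelist_unmatched_reads,
    reads_matched_mappable = n_mappable_reads,
    reads_matched_unmappable = nrow(reads_kept) - n_mappable_reads,
    cells = nrow(cells),
    cells_mappable = sum(cells$status != "unmappable"),
    cells_conflict = sum(cells$conflict_flag),
    mappable_pct = if (nrow(reads_kept) > 0L) {
      100 * n_mappable_reads / nrow(reads_kept)
    } else NA_real_,
    recovery_rate = recovery_rate)
  list(cells = cells, summary = summary)
}

#' Call per-molecule alleles from bulk UMI-tagged amplicon FASTQ
#'
#' Strips the leading UMI, aligns the remaining amplicon sequence, and takes
#' a per-UMI majority allele. Returns one record per UMI molecule, the input
#' for tissue-level edited fractions.
#'
#' @param fastq_path Gzipped FASTQ path.
#' @param ref A [saber_reference()].
#' @param umi_length Leading UMI length, nt.
#' @inheritParams align_read
#' @return data.frame: `umi`, `canonical_allele`, `edited_sites`, `status`,
#'   `n_reads`.
#' @export
call_bulk_alleles <- function(fastq_path, ref = default_saber_reference(),
                              umi_length = 10L, scoring = align_scoring(),
                              min_read_len = 50L, identity_floor = 0.75) {
  seqs <- read_fastq_seqs(fastq_path)
  umi <- substr(seqs, 1L, umi_length)
  amp <- substr(seqs, umi_length + 1L, nchar(seqs))
  calls <- call_read_alleles(amp, ref, scoring, min_read_len, identity_floor,
                             free_ref_tail = TRUE)
  majority <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    sort(names(tab)[tab == tab[1]])[1]
  }
  out <- lapply(split(seq_along(umi), umi), function(idx) {
    st <- calls$status[idx]
    mp <- st != "unmappable"
    if (!any(mp)) {
      return(data.frame(umi = umi[idx[1]], canonical_allele = NA_character_,
                        edited_sites = NA_character_, status = "unmappable",
                        n_reads = length(idx), stringsAsFactors = FALSE))
    }
    canon <- majority(calls$canonical[idx][mp])
    i <- idx[mp][match(canon, calls$canonical[idx][mp])]
    data.frame(umi = umi[idx[1]], canonical_allele = canon,
               edited_sites = calls$edited_sites[i],
               status = if (canon == "-") "unedited" else "edited",
               n_reads = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
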