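#' Synthetic stand-in: single-cell brain barcode cohort
#'
#' A deterministic, fully synthetic per-cell barcode table emulating the
#' scale and allele-frequency structure of a juvenile-brain recorder
#' experiment pooled over three animals. It is a stand-in built in code (the
#' original per-cell records are not bundled): the marginal statistics are
#' planted by construction — `n_mappable` mappable cells of which
#' `round(edited_fraction * n_mappable)` are edited, spread over `n_alleles`
#' distinct edited alleles with a single dominant homoplastic allele holding
#' `modal_share` of mappable cells, plus `n_unmappable` short-amplicon
#' records. Allele strings are valid deletions on the default reference
#' (every deletion window is longer than an inter-site spacer, so each
#' touches at least one target site).
#'
#' @param n_mappable,n_unmappable Record counts.
#' @param edited_fraction Planted edited fraction among mappable records.
#' @param n_alleles Number of distinct edited alleles.
#' @param modal_share Planted share of the most abundant allele among
#'   mappable records.
#' @param ref A [saber_reference()] (default reference geometry assumed for
#'   allele validity).
#' @return A per-cell records data.frame with the standard columns
#'   (`cell_barcode`, `canonical_allele`, `edited_sites`, `status`,
#'   `n_umis`, `n_reads`, `conflict_flag`).
#' @export
synthetic_brain_cohort <- function(n_mappable = 5351L, n_unmappable = 1259L,
                                   edited_fraction = 0.834, n_alleles = 277L,
                                   modal_share = 0.23,
                                   ref = default_saber_reference()) {
  n_edited <- round(edited_fraction * n_mappable)
  n_modal <- round(modal_share * n_mappable)
  stopifnot(n_modal < n_edited, n_alleles >= 2L,
            n_edited - n_modal >= n_alleles - 1L)
  # deterministic distinct deletion alleles, each touching >= 1 site
  k <- seq_len(n_alleles) - 1L
  starts <- 21L + (k %% 95L)
  lens <- 9L + 6L * (k %/% 95L)
  canon <- sprintf("%dD+%d", lens, starts)
  stopifnot(!anyDuplicated(canon), all(starts + lens <= nchar(ref$sequence)))
  sites <- vapply(seq_len(n_alleles), function(i) {
    format_sites(site_overlap(edit_event("D", starts[i], lens[i]), ref)$sites)
  }, character(1))
  stopifnot(all(nzchar(sites)))
  # geometric-decay counts for the non-modal alleles, each >= 1
  rest <- n_edited - n_modal
  w <- 0.98^(seq_len(n_alleles - 1L) - 1L)
  extra <- floor(w / sum(w) * (rest - (n_alleles - 1L)))
  counts <- 1L + extra
  short <- rest - sum(counts)
  if (short > 0L) counts[seq_len(short)] <- counts[seq_len(short)] + 1L
  counts <- c(n_modal, counts)
  stopifnot(sum(counts) == n_edited, max(counts) == n_modal)

  allele_idx <- rep.int(seq_len(n_alleles), counts)
  n_total <- n_mappable + n_unmappable
  cb <- int_to_dna(seq_len(n_total) * 977L, 16L)
  data.frame(
    cell_barcode = cb,
    canonical_allele = c(canon[allele_idx],
                         rep("-", n_mappable - n_edited),
                         rep(NA_character_, n_unmappable)),
    edited_sites = c(sites[allele_idx],
                     rep("", n_mappable - n_edited),
                     rep(NA_character_, n_unmappable)),
    status = c(rep("edited", n_edited),
               rep("unedited", n_mappable - n_edited),
               rep("unmappable", n_unmappable)),
    n_umis = c(rep(3L, n_mappable), rep(0L, n_unmappable)),
    n_reads = rep(30L, n_total),
    conflict_flag = FALSE,
    stringsAsFactors = FALSE)
}

#' Synthetic stand-in: barcoded cohort matched to a cell-type atlas
#'
#' A deterministic synthetic counterpart of a barcode-to-cell-type matching
#' experiment against a 137-cluster brain atlas. Cluster-level structure is
#' planted by construction: 10 rare clusters receive no barcoded cells
#' (sampling dropout), 21 clusters are recovered at three times and 22
#' clusters at one fifth of the dataset-wide recovery rate (detection bias),
#' and the remainder are recovered at the global rate. Edited fractions sit
#' at the global rate everywhere except three planted divergent subtypes:
#' `PurN_6` (fully edited), and `GC_3` / `TL_2` (depressed). All cell
#' barcodes are unique and the barcoded cells are a subset of the atlas.
#'
#' @param ref A [saber_reference()] used to stamp a valid allele string on
#'   edited cells.
#' @return `list(annotations, records, atlas_counts, barcoded_counts,
#'   planted)` where `annotations` covers every atlas cell, `records` is the
#'   per-cell barcode table, the two count vectors are per-cluster totals,
#'   and `planted` names the constructed cluster groups.
#' @export
synthetic_atlas_cohort <- function(ref = default_saber_reference()) {
  missing_cl <- c("Pineal", "OB_1", "OB_2", "Unk_1", "Unk_2",
                  "POA_7", "Hyp_9", "DHab_9", "VHab_6", "RG_8")
  higher_cl <- c(paste0("RG_", 1:7), paste0("Epend_", 1:3),
                 paste0("Peri_", 1:2), paste0("Olig_", 1:3),
                 paste0("Prog_", 1:6))
  lower_cl <- c(paste0("GC_", c(1:2, 4:9)), paste0("TL_", c(1, 3)),
                paste0("Pal_", 1:6), paste0("SubPal_", 1:6))
  null_cl <- c("PurN_6", "GC_3", "TL_2", paste0("PurN_", c(1:5, 7)),
               paste0("Hyp_", 1:8), paste0("DHab_", 1:8),
               paste0("VHab_", 1:5), paste0("POA_", 1:6),
               paste0("Pal_", 7:11), paste0("Neu_", 1:34),
               paste0("NonNeu_", 1:9))
  stopifnot(length(missing_cl) == 10L, length(higher_cl) == 21L,
            length(lower_cl) == 22L, length(null_cl) == 84L)
  clusters <- c(missing_cl, higher_cl, lower_cl, null_cl)
  stopifnot(!anyDuplicated(clusters), length(clusters) == 137L)
  atlas_n <- c(rep(60L, 10L), rep(800L, 21L), rep(2000L, 22L),
               rep(1200L, 84L))
  barcoded_n <- c(rep(0L, 10L), rep(107L, 21L), rep(18L, 22L),
                  rep(53L, 84L))
  names(atlas_n) <- names(barcoded_n) <- clusters

  edited_n <- round(0.834 * barcoded_n)
  edited_n["PurN_6"] <- barcoded_n["PurN_6"]
  edited_n[c("GC_3", "TL_2")] <- 29L

  total_atlas <- sum(atlas_n)
  cb <- int_to_dna(seq_len(total_atlas) * 613L, 16L)
  annotations <- data.frame(cell_barcode = cb,
                            cluster = rep.int(clusters, atlas_n),
                            stringsAsFactors = FALSE)
  # barcoded cells: the first barcoded_n cells of each cluster; edited cells
  # first within those
  rec <- do.call(rbind, lapply(clusters[barcoded_n > 0L], function(cl) {
    rows <- which(annotations$cluster == cl)[seq_len(barcoded_n[[cl]])]
    ne <- edited_n[[cl]]
    data.frame(cell_barcode = annotations$cell_barcode[rows],
               edited = seq_along(rows) <= ne, stringsAsFactors = FALSE)
  }))
  canon <- sprintf("%dD+%d", 20L, ref$cut_positions[2])
  csites <- format_sites(site_overlap(
    edit_event("D", ref$cut_positions[2], 20L), ref)$sites)
  records <- data.frame(
    cell_barcode = rec$cell_barcode,
    canonical_allele = ifelse(rec$edited, canon, "-"),
    edited_sites = ifelse(rec$edited, csites, ""),
    status = ifelse(rec$edited, "edited", "unedited"),
    n_umis = 3L, n_reads = 30L, conflict_flag = FALSE,
    stringsAsFactors = FALSE)
  list(annotations = annotations, records = records,
       atlas_counts = atlas_n, barcoded_counts = barcoded_n,
       planted = list(missing = missing_cl, higher = higher_cl,
                      lower = lower_cl, null = null_cl))
}
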