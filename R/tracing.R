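record_is_mappable <- function(records) {
  records$status != "unmappable" & !is.na(records$status)
}

record_is_edited <- function(records) {
  sites <- records$edited_sites
  !is.na(sites) & nzchar(sites)
}

#' Fraction of mappable barcodes with at least one edited target site
#'
#' Unmappable records are excluded from both numerator and denominator; a
#' barcode counts as edited when its `edited_sites` set is non-empty.
#'
#' @param records data.frame with `status` and `edited_sites` columns (cell
#'   records, bulk UMI records, or a ground-truth table).
#' @return Numeric scalar in `[0, 1]`.
#' @export
edited_fraction <- function(records) {
  mp <- record_is_mappable(records)
  if (!any(mp)) stop("no mappable records: edited fraction undefined")
  mean(record_is_edited(records)[mp])
}

#' Allele frequency table over mappable records
#'
#' @param records As in [edited_fraction()], with a `canonical_allele`
#'   column.
#' @return data.frame sorted by descending count: `canonical_allele`,
#'   `count`, `share` (of mappable records).
#' @export
allele_frequencies <- function(records) {
  mp <- record_is_mappable(records)
  canon <- records$canonical_allele[mp]
  tab <- sort(table(canon), decreasing = TRUE)
  data.frame(canonical_allele = names(tab), count = as.integer(tab),
             share = as.integer(tab) / sum(mp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Deletion spectrum of a mappable allele cohort
#'
#' Three summaries of the edit spectrum. `per_position`: for each reference
#' nucleotide, the fraction of alleles whose deletions cover it (deletions
#' only, matching how editing profiles are drawn). `per_site_counts`: for
#' each target site and allele, whether the site is intra-edited (touched by
#' an event lying entirely within one site), inter-edited (touched by a
#' spanning event), or unedited; a site touched by both kinds counts as
#' inter. `link_matrix`: a 4x4 matrix counting, per deletion event, the pair
#' (leftmost touched site, rightmost touched site); the diagonal holds
#' intra-site deletions; deletions touching no site are counted in
#' `n_offsite`.
#'
#' @param alleles Character vector of canonical allele strings (mappable
#'   cohort), or a records data.frame with `canonical_allele` (its mappable
#'   rows are used).
#' @param ref A [saber_reference()].
#' @return `list(per_position, per_site_counts, link_matrix, n_alleles,
#'   n_offsite)`.
#' @export
edit_spectrum <- function(alleles, ref = default_saber_reference()) {
  if (is.data.frame(alleles)) {
    alleles <- alleles$canonical_allele[record_is_mappable(alleles)]
  }
  L <- nchar(ref$sequence)
  cover <- numeric(L)
  link <- matrix(0L, 4L, 4L,
                 dimnames = list(paste0("site", 1:4), paste0("site", 1:4)))
  per_site <- matrix(0L, 4L, 3L,
                     dimnames = list(paste0("site", 1:4),
                                     c("intra", "inter", "unedited")))
  n_offsite <- 0L
  n_alleles <- length(alleles)
  for (canon in alleles) {
    ev <- parse_allele(canon)
    site_kind <- rep("unedited", 4L)
    if (nrow(ev) > 0L) {
      for (k in seq_len(nrow(ev))) {
        ov <- site_overlap(ev[k, ], ref)
        if (ev$kind[k] == "D") {
          span <- (ev$start[k] + 1L):(ev$start[k] + ev$length[k])
          cover[span] <- cover[span] + 1
          if (length(ov$sites) > 0L) {
            i <- min(ov$sites); j <- max(ov$sites)
            link[i, j] <- link[i, j] + 1L
          } else {
            n_offsite <- n_offsite + 1L
          }
        }
        for (s in ov$sites) {
          site_kind[s] <- if (ov$category == "inter" ||
                                site_kind[s] == "inter") "inter" else "intra"
        }
      }
    }
    for (s in 1:4) {
      per_site[s, site_kind[s]] <- per_site[s, site_kind[s]] + 1L
    }
  }
  list(per_position = if (n_alleles > 0L) cover / n_alleles else cover,
       per_site_counts = per_site, link_matrix = link,
       n_alleles = n_alleles, n_offsite = n_offsite)
}

exact_binom_p <- function(x, n, p0) {
  stats::binom.test(x, n, p0, alternative = "two.sided")$p.value
}

#' Per-cluster divergence of edited fractions from the pooled rate
#'
#' For every cluster with at least `min_cells` barcoded (mappable) cells, a
#' two-sided exact binomial test of the cluster's edited count against the
#' pooled edited fraction over all barcoded cells (optionally excluding the
#' focal cluster). No multiple-testing correction drives the `significant`
#' flag (the raw-threshold convention of this assay); a Benjamini-Hochberg
#' column is reported alongside for users who want it.
#'
#' @param records Per-cell records (mappable and unmappable; the latter are
#'   dropped).
#' @param annotations data.frame `cell_barcode`, `cluster`, covering the
#'   profiled cells. Records without an annotation are excluded and counted
#'   in the `n_unannotated` attribute.
#' @param min_cells Minimum barcoded cells for a cluster to be tested.
#' @param alpha Significance threshold on the raw p-value.
#' @param exclude_focal Compute the null rate leaving the focal cluster out.
#' @return data.frame, one row per cluster with any barcoded cell:
#'   `cluster`, `n_barcoded`, `n_edited`, `fraction`, `p_value` (NA below
#'   `min_cells`), `p_adj`, `direction` ("higher"/"lower"/"none"),
#'   `significant`. Attributes: `p0` (pooled fraction), `n_unannotated`.
#' @export
cluster_divergence <- function(records, annotations, min_cells = 20L,
                               alpha = 0.05, exclude_focal = FALSE) {
  mp <- records[record_is_mappable(records), , drop = FALSE]
  cl <- annotations$cluster[match(mp$cell_barcode, annotations$cell_barcode)]
  n_unannotated <- sum(is.na(cl))
  if (n_unannotated > 0L) {
    message(n_unannotated, " barcoded cells lack an annotation; excluded")
  }
  keep <- !is.na(cl)
  edited <- record_is_edited(mp)[keep]
  cl <- cl[keep]
  if (length(cl) == 0L) stop("no annotated barcoded cells")
  n_b <- tapply(edited, cl, length)
  n_e <- tapply(edited, cl, sum)
  clusters <- names(n_b)
  tot_b <- sum(n_b); tot_e <- sum(n_e)
  p0 <- tot_e / tot_b
  res <- data.frame(cluster = clusters,
                    n_barcoded = as.integer(n_b),
                    n_edited = as.integer(n_e),
                    fraction = as.numeric(n_e / n_b),
                    p_value = NA_real_, p_adj = NA_real_,
                    direction = "none", significant = FALSE,
                    stringsAsFactors = FALSE)
  testable <- res$n_barcoded >= min_cells
  for (i in which(testable)) {
    p_null <- if (exclude_focal) {
      (tot_e - res$n_edited[i]) / (tot_b - res$n_barcoded[i])
    } else p0
    res$p_value[i] <- exact_binom_p(res$n_edited[i], res$n_barcoded[i], p_null)
    if (res$fraction[i] > p_null) res$direction[i] <- "higher"
    if (res$fraction[i] < p_null) res$direction[i] <- "lower"
  }
  res$p_adj[testable] <- stats::p.adjust(res$p_value[testable], "BH")
  res$significant <- testable & !is.na(res$p_value) & res$p_value < alpha
  res$direction[res$n_edited == 0L & !res$significant] <- "none"
  res$direction[!testable] <- "none"
  attr(res, "p0") <- p0
  attr(res, "n_unannotated") <- n_unannotated
  res
}

#' Detection bias of cell types in the barcode library
#'
#' Tests whether each cluster's cells are recovered in the barcode dataset
#' more or less often than the dataset-wide recovery rate: a two-sided exact
#' binomial test of `barcoded_counts[c]` successes in `atlas_counts[c]`
#' trials against `p0 = sum(barcoded) / sum(atlas)`.
#'
#' @param barcoded_counts Named integer vector: barcoded cells per cluster.
#'   Clusters absent from the vector count as zero.
#' @param atlas_counts Named integer vector: total atlas cells per cluster;
#'   must cover every cluster in `barcoded_counts` with at least as many
#'   cells.
#' @param alpha Significance threshold.
#' @return data.frame per atlas cluster: `cluster`, `n_atlas`, `n_barcoded`,
#'   `rate`, `p_value`, `p_adj`, `direction`, `significant`. Attribute `p0`.
#' @export
detection_bias <- function(barcoded_counts, atlas_counts, alpha = 0.05) {
  extra <- setdiff(names(barcoded_counts), names(atlas_counts))
  if (length(extra) > 0L) {
    stop("clusters absent from the atlas: ", paste(extra, collapse = ", "))
  }
  clusters <- names(atlas_counts)
  b <- ifelse(clusters %in% names(barcoded_counts),
              as.integer(barcoded_counts[clusters]), 0L)
  a <- as.integer(atlas_counts[clusters])
  if (any(b > a)) stop("barcoded counts exceed atlas counts")
  p0 <- sum(b) / sum(a)
  p <- mapply(exact_binom_p, b, a, MoreArgs = list(p0 = p0))
  rate <- b / a
  dir <- ifelse(rate > p0, "higher", ifelse(rate < p0, "lower", "none"))
  res <- data.frame(cluster = clusters, n_atlas = a, n_barcoded = b,
                    rate = rate, p_value = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    direction = dir, significant = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$direction[!res$significant & res$n_barcoded == 0L] <- "none"
  attr(res, "p0") <- p0
  res
}

#' Edited fractions per tissue, normalized to a reference tissue
#'
#' @param per_tissue_records Named list of record tables (e.g. from
#'   [call_bulk_alleles()]), one per tissue.
#' @param reference_tissue Name of the tissue whose edited fraction maps to
#'   1 (must be present with a nonzero edited fraction).
#' @return Named numeric vector of normalized fractions.
#' @export
tissue_normalized_fractions <- function(per_tissue_records, reference_tissue) {
  if (!reference_tissue %in% names(per_tissue_records)) {
    stop("reference tissue not present: ", reference_tissue)
  }
  fr <- vapply(per_tissue_records, edited_fraction, numeric(1))
  if (fr[[reference_tissue]] == 0) {
    stop("reference tissue has zero edited fraction; normalization undefined")
  }
  fr / fr[[reference_tissue]]
}

#' Atlas coverage of the barcode dataset
#'
#' Counts how many annotated cell types contain at least one barcoded cell,
#' and lists the missed clusters with their atlas sizes.
#'
#' @param records Per-cell barcode records.
#' @param annotations Full atlas annotation table (`cell_barcode`,
#'   `cluster`), carrying the complete cluster label set.
#' @return `list(n_clusters_hit, n_clusters_total, missing = <data.frame
#'   cluster, n_atlas>)`.
#' @export
coverage_report <- function(records, annotations) {
  hit <- unique(annotations$cluster[annotations$cell_barcode %in%
                                      records$cell_barcode])
  sizes <- table(annotations$cluster)
  all_clusters <- names(sizes)
  missing <- setdiff(all_clusters, hit)
  list(n_clusters_hit = length(intersect(all_clusters, hit)),
       n_clusters_total = length(all_clusters),
       missing = data.frame(cluster = missing,
                            n_atlas = as.integer(sizes[missing]),
                            stringsAsFactors = FALSE, row.names = NULL))
}
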