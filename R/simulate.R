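#' Simulation configuration
#'
#' Parameters of the synthetic signal-recording experiment. The defaults
#' describe the reference recording condition: heat-shock cycling exposes
#' cells to `n_rounds = 17` editing opportunities; the per-site per-round cut
#' probability `p_cut = 0.075` and the fraction of signal-active lineages
#' `signal_active_fraction = 0.84` jointly reproduce the observed edited
#' fractions (about 83% of barcodes edited under cycling, about 22% under a
#' single induction pulse, via `a * (1 - (1 - p_cut)^(4 * n_rounds))`).
#' `detection_rate = 0.22` matches the optimized barcode-library recovery.
#'
#' @param n_cells Number of terminal cells to simulate.
#' @param cluster_proportions Named numeric vector of cell-type proportions
#'   (must sum to 1).
#' @param signal_active_fraction Probability that a cell's ancestor was
#'   signal-active: a single number, or a named vector with one entry per
#'   cluster.
#' @param n_rounds Editing opportunities (induction pulses) per active
#'   lineage.
#' @param p_cut Per-site, per-round cut probability while the site is intact.
#' @param p_joint Probability that two or more cuts occurring in the same
#'   round resolve as one deletion spanning the leftmost to rightmost cut.
#' @param deletion_length_mean Mean of the geometric extension of a deletion
#'   beyond the cut, per flank, nt.
#' @param p_insertion Probability that a single-cut repair yields a short
#'   insertion instead of a deletion.
#' @param insertion_length_mean Mean insertion length, nt (lengths are
#'   1 + geometric).
#' @param detection_rate Probability that a cell's barcode is recovered in
#'   the barcode library.
#' @param detection_multiplier Optional named vector of per-cluster
#'   multipliers on `detection_rate` (capped at probability 1).
#' @param reads_per_cell Reads sequenced per UMI molecule.
#' @param umis_per_cell Barcode UMI molecules recovered per detected cell.
#' @param seq_error_rate Per-base substitution probability on the amplicon
#'   read.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 5000L,
                              cluster_proportions = c(progenitor = 0.2,
                                                      neuron = 0.6,
                                                      glia = 0.2),
                              signal_active_fraction = 0.84,
                              n_rounds = 17L,
                              p_cut = 0.075,
                              p_joint = 0.5,
                              deletion_length_mean = 4,
                              p_insertion = 0.05,
                              insertion_length_mean = 2,
                              detection_rate = 0.22,
                              detection_multiplier = NULL,
                              reads_per_cell = 10L,
                              umis_per_cell = 3L,
                              seq_error_rate = 0.005,
                              seed = 1L) {
  if (length(cluster_proportions) == 0L || is.null(names(cluster_proportions))) {
    stop("cluster_proportions must be a non-empty named vector")
  }
  if (abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("cluster_proportions must sum to 1")
  }
  probs <- c(signal_active_fraction, p_cut, p_joint, p_insertion,
             detection_rate, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (!is.null(detection_multiplier) &&
      (is.null(names(detection_multiplier)) || any(detection_multiplier < 0))) {
    stop("detection_multiplier must be a named non-negative vector")
  }
  structure(list(
    n_cells = as.integer(n_cells),
    cluster_proportions = cluster_proportions,
    signal_active_fraction = signal_active_fraction,
    n_rounds = as.integer(n_rounds), p_cut = p_cut, p_joint = p_joint,
    deletion_length_mean = deletion_length_mean, p_insertion = p_insertion,
    insertion_length_mean = insertion_length_mean,
    detection_rate = detection_rate,
    detection_multiplier = detection_multiplier,
    reads_per_cell = as.integer(reads_per_cell),
    umis_per_cell = as.integer(umis_per_cell),
    seq_error_rate = seq_error_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

# deterministic per-stage seed derived from the global seed; kept < 2^31
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 9973) %% 2147483647
}

int_to_dna <- function(i, width) {
  base <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(i), ncol = width)
  x <- as.numeric(i)
  for (k in seq_len(width)) {
    out[, width - k + 1L] <- base[(x %% 4) + 1L]
    x <- x %/% 4
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# geometric with given mean (>= 0); mean 0 degenerates to 0
rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(integer(n))
  stats::rgeom(n, prob = 1 / (1 + mean))
}

# One signal-active lineage's editing history: n_rounds of cutting over the
# 4-site array. A site is cut-eligible while no prior event overlaps its
# interval (an indel destroys protospacer recognition). Multiple cuts in one
# round resolve jointly (one spanning deletion) with probability p_joint,
# else independently. All deletions receive geometric flank extensions.
simulate_cell_edits <- function(ref, config) {
  ts <- ref$target_sites
  cp <- ref$cut_positions
  L <- nchar(ref$sequence)
  events <- empty_events()
  dmean <- config$deletion_length_mean
  for (round in seq_len(config$n_rounds)) {
    eligible <- vapply(1:4, function(k) {
      if (nrow(events) == 0L) return(TRUE)
      del <- events$kind == "D"
      hit_del <- any(del & events$start < ts$end[k] &
                       events$start + events$length > ts$start[k])
      hit_ins <- any(!del & events$start > ts$start[k] &
                       events$start <= ts$end[k])
      !(hit_del || hit_ins)
    }, logical(1))
    cut <- which(eligible & stats::runif(4) < config$p_cut)
    if (length(cut) == 0L) next
    if (length(cut) >= 2L && stats::runif(1) < config$p_joint) {
      s <- max(0L, min(cp[cut]) - rgeom_mean(1, dmean))
      e <- min(L, max(cp[cut]) + 1L + rgeom_mean(1, dmean))
      events <- merge_deletion(events, s, e)
    } else {
      for (k in cut) {
        if (stats::runif(1) < config$p_insertion) {
          len <- 1L + rgeom_mean(1, config$insertion_length_mean - 1)
          events <- rbind(events,
                          edit_event("I", cp[k], len, random_dna(1, len)))
          events <- sort_events(events)
        } else {
          s <- max(0L, cp[k] - rgeom_mean(1, dmean))
          e <- min(L, cp[k] + 1L + rgeom_mean(1, dmean))
          events <- merge_deletion(events, s, e)
        }
      }
    }
  }
  rownames(events) <- NULL
  events
}

# add deletion [s, e), absorbing overlapping deletions and swallowing
# insertions whose point falls strictly inside
merge_deletion <- function(events, s, e) {
  if (nrow(events) > 0L) {
    del <- events$kind == "D"
    ov <- del & events$start < e & events$start + events$length > s
    if (any(ov)) {
      s <- min(s, events$start[ov])
      e <- max(e, events$start[ov] + events$length[ov])
    }
    swallowed <- !del & events$start > s & events$start < e
    events <- events[!(ov | swallowed), , drop = FALSE]
  }
  sort_events(rbind(events, edit_event("D", s, e - s)))
}

#' Simulate a population of recorder-bearing cells
#'
#' Each terminal cell independently carries the edited array of its ancestor
#' (lineage expansion is collapsed: barcodes are read as binary signal marks,
#' not clones). Cluster labels are drawn from `cluster_proportions`;
#' signal-active lineages undergo the multi-round cut-and-repair process of
#' the recorder; detection is Bernoulli with an optional per-cluster bias.
#'
#' @param config A [simulation_config()].
#' @param ref A [saber_reference()].
#' @return data.frame (the ground-truth table): `cell_barcode` (16 nt,
#'   unique), `cluster`, `signal_active`, `detected`, `canonical_allele`,
#'   `edited_sites`, `status`.
#' @export
simulate_population <- function(config, ref = default_saber_reference()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_cells
  labels <- names(config$cluster_proportions)
  cluster <- sample(labels, n, replace = TRUE, prob = config$cluster_proportions)
  af <- config$signal_active_fraction
  p_active <- if (length(af) == 1L) rep(af, n) else {
    if (!all(labels %in% names(af))) stop("signal_active_fraction misses clusters")
    unname(af[cluster])
  }
  active <- stats::runif(n) < p_active
  mult <- rep(1, n)
  if (!is.null(config$detection_multiplier)) {
    mm <- config$detection_multiplier
    has <- cluster %in% names(mm)
    mult[has] <- unname(mm[cluster[has]])
  }
  detected <- stats::runif(n) < pmin(1, config$detection_rate * mult)
  cell_barcode <- int_to_dna(sample.int(2^30, n), 16L)

  canonical <- rep("-", n)
  sites <- rep("", n)
  for (i in which(active)) {
    ev <- simulate_cell_edits(ref, config)
    # truth alleles use the caller's alignment-based normal form, so any
    # edit histories that produce the same molecule encode identically
    if (nrow(ev) > 0L) {
      ev <- infer_canonical_events(apply_events(ref$sequence, ev), ref)
    }
    if (nrow(ev) > 0L) {
      s <- allele_summary(ev, ref)
      canonical[i] <- s$canonical
      sites[i] <- format_sites(s$edited_sites)
    }
  }
  data.frame(cell_barcode = cell_barcode, cluster = cluster,
             signal_active = active, detected = detected,
             canonical_allele = canonical, edited_sites = sites,
             status = ifelse(canonical == "-", "unedited", "edited"),
             stringsAsFactors = FALSE)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  widths <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), widths, rate)
  hit <- which(nerr > 0L)
  base <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(widths[i], nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(base, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

write_fastq_gz <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(w) strrep("I", w), character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(x, quals)
  Biostrings::writeQualityScaledXStringSet(q, path, compress = TRUE)
  invisible(path)
}

#' Generate paired single-cell FASTQ reads for detected cells
#'
#' Emulates the 10x-style barcode library: read 1 carries the 16-nt cell
#' barcode followed by a 12-nt UMI (28 cycles); read 2 carries the edited
#' amplicon from the upstream primer, truncated to `read2_length` cycles.
#' Substitution errors at `seq_error_rate` are applied to read 2 only (the
#' barcode read is emitted error-free, standing in for the upstream
#' pipeline's barcode error correction). Identical seeds give byte-identical
#' output.
#'
#' @param cells Ground-truth table from [simulate_population()]; only rows
#'   with `detected = TRUE` produce reads.
#' @param config The [simulation_config()] used to simulate them.
#' @param ref The [saber_reference()].
#' @param r1_path,r2_path Output gzipped FASTQ paths.
#' @param read2_length Amplicon read length (sequencing cycles).
#' @param umi_length UMI length on read 1, nt.
#' @return Invisibly, `list(n_reads, r1_path, r2_path)`.
#' @export
generate_reads <- function(cells, config, ref = default_saber_reference(),
                           r1_path, r2_path, read2_length = 151L,
                           umi_length = 12L) {
  set.seed(derive_seed(config$seed, 2L))
  det <- cells[cells$detected, , drop = FALSE]
  offset <- ref$primer_sites$start[1]
  amp_cache <- new.env(parent = emptyenv())
  amplicon_of <- function(canon) {
    key <- if (canon == "-") "." else canon
    if (!is.null(amp_cache[[key]])) return(amp_cache[[key]])
    edited <- apply_events(ref$sequence, parse_allele(canon))
    # amplicon: from the upstream primer through whatever remains downstream
    amp <- substr(edited, offset + 1L, nchar(edited))
    amp_cache[[key]] <- amp
    amp
  }
  n_cells <- nrow(det)
  u <- config$umis_per_cell
  r <- config$reads_per_cell
  n_mol <- n_cells * u
  umis <- random_dna(n_mol, umi_length)
  cell_idx <- rep(seq_len(n_cells), each = u)
  amps <- vapply(det$canonical_allele, amplicon_of, character(1),
                 USE.NAMES = FALSE)
  mol_r2 <- substr(amps[cell_idx], 1L, read2_length)
  read_mol <- rep(seq_len(n_mol), each = r)
  r1 <- paste0(det$cell_barcode[cell_idx][read_mol], umis[read_mol])
  r2 <- apply_substitutions(mol_r2[read_mol], config$seq_error_rate)
  ids <- sprintf("sim:%s:%s:%d", det$cell_barcode[cell_idx][read_mol],
                 umis[read_mol], sequence(rep(r, n_mol)))
  write_fastq_gz(r1, ids, r1_path)
  write_fastq_gz(r2, ids, r2_path)
  invisible(list(n_reads = length(r1), r1_path = r1_path, r2_path = r2_path))
}

#' Generate UMI-tagged bulk amplicon reads per tissue
#'
#' Emulates the genomic-DNA assay: each tissue's amplicon pool is tagged by
#' primer extension with a random 10-nt UMI and sequenced without cell
#' barcodes. Reads carry the UMI followed by the (merged) amplicon sequence.
#' Tissues differ through their configs, typically in
#' `signal_active_fraction`.
#'
#' @param tissue_configs Named list of [simulation_config()], one per tissue.
#' @param ref A [saber_reference()].
#' @param out_dir Directory for `<tissue>.fastq.gz` files.
#' @param umi_length Bulk UMI length, nt.
#' @return Named character vector of FASTQ paths.
#' @export
generate_bulk_amplicons <- function(tissue_configs,
                                    ref = default_saber_reference(),
                                    out_dir, umi_length = 10L) {
  if (is.null(names(tissue_configs)) || length(tissue_configs) == 0L) {
    stop("tissue_configs must be a non-empty named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tissue in names(tissue_configs)) {
    config <- tissue_configs[[tissue]]
    cells <- simulate_population(config, ref)
    set.seed(derive_seed(config$seed, 3L))
    offset <- ref$primer_sites$start[1]
    amps <- vapply(cells$canonical_allele, function(canon) {
      edited <- apply_events(ref$sequence, parse_allele(canon))
      substr(edited, offset + 1L, nchar(edited))
    }, character(1), USE.NAMES = FALSE)
    u <- config$umis_per_cell
    r <- config$reads_per_cell
    n_mol <- nrow(cells) * u
    umis <- random_dna(n_mol, umi_length)
    cell_idx <- rep(seq_len(nrow(cells)), each = u)
    read_mol <- rep(seq_len(n_mol), each = r)
    seqs <- paste0(umis[read_mol],
                   apply_substitutions(amps[cell_idx][read_mol],
                                       config$seq_error_rate))
    ids <- sprintf("bulk:%s:%s:%d", tissue, umis[read_mol],
                   sequence(rep(r, n_mol)))
    path <- file.path(out_dir, paste0(tissue, ".fastq.gz"))
    write_fastq_gz(seqs, ids, path)
    paths[tissue] <- path
  }
  paths
}
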