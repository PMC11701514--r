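#' Read and write pipeline tables
#'
#' All intermediate tables are UTF-8 tab-separated files with a header row;
#' they round-trip losslessly through these helpers (logical and integer
#' columns preserved, empty strings distinct from NA).
#'
#' @param df A data.frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` a data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, colClasses = NA,
                    fileEncoding = "UTF-8")
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

manifest_entry <- function(paths) {
  lapply(paths, function(p) list(file = basename(p),
                                 md5 = unname(tools::md5sum(p)),
                                 bytes = unname(file.size(p))))
}

#' Run the simulation stage
#'
#' Simulates a cell population, writes the reference description, the
#' ground-truth table, the cell-barcode whitelist (all profiled cells),
#' paired FASTQ for detected cells, and a manifest with file hashes and
#' counts. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created).
#' @param ref A [saber_reference()].
#' @return Invisibly, a named list of output paths.
#' @export
run_simulate <- function(config, out_dir, ref = default_saber_reference()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- simulate_population(config, ref)
  paths <- list(
    reference = file.path(out_dir, "reference.yaml"),
    truth = file.path(out_dir, "truth.tsv"),
    whitelist = file.path(out_dir, "whitelist.tsv"),
    r1 = file.path(out_dir, "reads_R1.fastq.gz"),
    r2 = file.path(out_dir, "reads_R2.fastq.gz"),
    manifest = file.path(out_dir, "simulate_manifest.json"))
  write_saber_reference(ref, paths$reference)
  write_tsv(cells, paths$truth)
  writeLines(cells$cell_barcode, paths$whitelist)
  gen <- generate_reads(cells, config, ref, paths$r1, paths$r2)
  write_json_summary(list(
    stage = "simulate", seed = config$seed,
    n_cells = nrow(cells), n_detected = sum(cells$detected),
    n_reads = gen$n_reads,
    config = unclass(config),
    outputs = manifest_entry(paths[c("truth", "whitelist", "r1", "r2")])),
    paths$manifest)
  invisible(paths)
}

#' Run the allele-calling stage
#'
#' @param r1_path,r2_path Paired FASTQ from sequencing or [run_simulate()].
#' @param ref_path Reference description YAML.
#' @param whitelist_path One barcode per line.
#' @param out_dir Output directory.
#' @param ... Passed to [call_alleles()] (scoring, thresholds).
#' @return Invisibly, a named list of output paths.
#' @export
run_call <- function(r1_path, r2_path, ref_path, whitelist_path, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_saber_reference(ref_path)
  whitelist <- readLines(whitelist_path)
  if (length(whitelist) == 0L) stop("whitelist is empty: ", whitelist_path)
  res <- call_alleles(r1_path, r2_path, ref, whitelist = whitelist, ...)
  paths <- list(alleles = file.path(out_dir, "alleles.tsv"),
                summary = file.path(out_dir, "call_summary.json"))
  write_tsv(res$cells, paths$alleles)
  write_json_summary(c(list(stage = "call"), res$summary,
                       list(outputs = manifest_entry(paths["alleles"]))),
                     paths$summary)
  invisible(paths)
}

#' Run the signal-tracing stage
#'
#' Joins the allele table to cluster annotations and writes the cluster
#' divergence table, the edit-spectrum tables (per-position deletion
#' profile; per-site intra/inter/unedited counts; long-format site link
#' matrix), the coverage report and a JSON summary.
#'
#' @param alleles_path Allele table TSV (from [run_call()]).
#' @param annotations_path Annotation TSV with `cell_barcode`, `cluster`.
#' @param out_dir Output directory.
#' @param ref A [saber_reference()] for the spectrum.
#' @param min_cells,alpha Divergence-test thresholds.
#' @return Invisibly, a named list of output paths.
#' @export
run_trace <- function(alleles_path, annotations_path, out_dir,
                      ref = default_saber_reference(), min_cells = 20L,
                      alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_tsv(alleles_path)
  annotations <- read_tsv(annotations_path)
  records$edited_sites[is.na(records$edited_sites) &
                         records$status == "unedited"] <- ""
  div <- cluster_divergence(records, annotations, min_cells, alpha)
  spec <- edit_spectrum(records, ref)
  cov <- coverage_report(records, annotations)
  paths <- list(
    clusters = file.path(out_dir, "cluster_stats.tsv"),
    profile = file.path(out_dir, "deletion_profile.tsv"),
    site_counts = file.path(out_dir, "site_counts.tsv"),
    links = file.path(out_dir, "site_links.tsv"),
    summary = file.path(out_dir, "trace_summary.json"))
  write_tsv(div, paths$clusters)
  write_tsv(data.frame(position = seq_along(spec$per_position) - 1L,
                       deletion_fraction = spec$per_position),
            paths$profile)
  write_tsv(data.frame(site = rownames(spec$per_site_counts),
                       spec$per_site_counts, row.names = NULL),
            paths$site_counts)
  links <- expand.grid(site_i = 1:4, site_j = 1:4)
  links$count <- as.integer(spec$link_matrix[as.matrix(links)])
  links <- links[links$site_i <= links$site_j, ]
  write_tsv(links, paths$links)
  write_json_summary(list(
    stage = "trace",
    n_records = nrow(records),
    edited_fraction = edited_fraction(records),
    pooled_fraction = attr(div, "p0"),
    n_clusters_tested = sum(!is.na(div$p_value)),
    n_significant = sum(div$significant),
    coverage = list(hit = cov$n_clusters_hit, total = cov$n_clusters_total,
                    missing = cov$missing$cluster),
    outputs = manifest_entry(paths[c("clusters", "profile", "site_counts",
                                     "links")])),
    paths$summary)
  invisible(paths)
}

#' Run simulate, call and trace end to end
#'
#' Desk-scale driver: simulates a population, calls alleles from the
#' generated reads against the simulated whitelist, and traces signal using
#' the simulated cluster labels as annotations. Each stage derives its own
#' seed from `config$seed`, so re-running any stage from saved intermediates
#' reproduces downstream outputs exactly.
#'
#' @param config A [simulation_config()].
#' @param out_dir Run directory; stages write to `simulate/`, `call/`,
#'   `trace/` subdirectories.
#' @param ref A [saber_reference()].
#' @param min_cells,alpha Tracing thresholds.
#' @return Invisibly, a nested list of stage output paths.
#' @export
run_pipeline <- function(config, out_dir, ref = default_saber_reference(),
                         min_cells = 20L, alpha = 0.05) {
  sim <- run_simulate(config, file.path(out_dir, "simulate"), ref)
  call <- run_call(sim$r1, sim$r2, sim$reference, sim$whitelist,
                   file.path(out_dir, "call"))
  truth <- read_tsv(sim$truth)
  ann_path <- file.path(out_dir, "simulate", "annotations.tsv")
  write_tsv(truth[, c("cell_barcode", "cluster")], ann_path)
  trace <- run_trace(call$alleles, ann_path, file.path(out_dir, "trace"),
                     ref, min_cells, alpha)
  invisible(list(simulate = sim, call = call, trace = trace,
                 annotations = ann_path))
}

#' Summarize a run directory
#'
#' Collects the per-stage JSON summaries of a [run_pipeline()] directory
#' into one list.
#'
#' @param run_dir Run directory.
#' @return Named list of parsed stage summaries.
#' @export
summarize_run <- function(run_dir) {
  files <- c(simulate = file.path(run_dir, "simulate", "simulate_manifest.json"),
             call = file.path(run_dir, "call", "call_summary.json"),
             trace = file.path(run_dir, "trace", "trace_summary.json"))
  present <- files[file.exists(files)]
  if (length(present) == 0L) stop("no stage summaries found under ", run_dir)
  lapply(present, jsonlite::read_json)
}
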