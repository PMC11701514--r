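test_that("edited_fraction matches an exhaustive tally and excludes unmappable", {
  pop <- simulate_population(simulation_config(n_cells = 600, seed = 91))
  # independent tally
  n_ed <- 0L; n_map <- 0L
  for (i in seq_len(nrow(pop))) {
    if (pop$status[i] != "unmappable") {
      n_map <- n_map + 1L
      if (nzchar(pop$edited_sites[i])) n_ed <- n_ed + 1L
    }
  }
  expect_identical(edited_fraction(pop), n_ed / n_map)

  rec <- data.frame(status = c("edited", "unedited", "unmappable"),
                    edited_sites = c("1,2", "", NA))
  expect_identical(edited_fraction(rec), 0.5)
  none <- data.frame(status = "unmappable", edited_sites = NA)
  expect_error(edited_fraction(none), "no mappable")
  all_un <- data.frame(status = rep("unedited", 5), edited_sites = rep("", 5))
  expect_identical(edited_fraction(all_un), 0)
})

test_that("edit_spectrum counts footprints, site classes and links", {
  ref <- default_saber_reference()
  ts <- ref$target_sites
  span <- sprintf("%dD+%d", ts$end[4] - ts$start[1], ts$start[1])
  sp <- edit_spectrum(span, ref)
  expect_identical(sp$link_matrix["site1", "site4"], 1L)
  expect_identical(sum(sp$link_matrix), 1L)
  covered <- (ts$start[1] + 1):(ts$end[4])
  expect_true(all(sp$per_position[covered] == 1))
  expect_true(all(sp$per_position[-covered] == 0))
  expect_true(all(sp$per_site_counts[, "inter"] == 1L))

  sp0 <- edit_spectrum(rep("-", 10), ref)
  expect_true(all(sp0$link_matrix == 0L))
  expect_true(all(sp0$per_position == 0))
  expect_true(all(sp0$per_site_counts[, "unedited"] == 10L))

  intra <- sprintf("3D+%d", ref$cut_positions[2])
  spi <- edit_spectrum(c(intra, "-"), ref)
  expect_identical(spi$link_matrix["site2", "site2"], 1L)
  expect_identical(unname(spi$per_site_counts["site2", "intra"]), 1L)
})

test_that("per-site spectrum rows always sum to the allele count", {
  ref <- default_saber_reference()
  pop <- simulate_population(simulation_config(n_cells = 400, seed = 92), ref)
  sp <- edit_spectrum(pop, ref)
  expect_true(all(rowSums(sp$per_site_counts) == sp$n_alleles))
  expect_true(all(sp$per_position >= 0 & sp$per_position <= 1))
})

test_that("divergence p-values equal direct PMF summation", {
  withr::local_seed(406)
  for (k in 1:40) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    p0 <- stats::runif(1, 0.05, 0.95)
    expect_equal(saberseq:::exact_binom_p(x, n, p0), binom_p_oracle(x, n, p0),
                 tolerance = 1e-12)
  }
  # the published-style case: a fully edited cluster of 30 against 0.834
  expect_equal(saberseq:::exact_binom_p(30, 30, 0.834),
               binom_p_oracle(30, 30, 0.834), tolerance = 1e-12)
})

test_that("cluster_divergence flags planted divergent clusters only", {
  # balanced null clusters at the pooled rate, one planted high, one low
  mk <- function(cl, n, n_ed) {
    data.frame(cell_barcode = paste0(cl, "_", seq_len(n)),
               status = c(rep("edited", n_ed), rep("unedited", n - n_ed)),
               edited_sites = c(rep("1", n_ed), rep("", n - n_ed)),
               cluster = cl, stringsAsFactors = FALSE)
  }
  tabs <- rbind(mk("null1", 60, 30), mk("null2", 60, 30), mk("null3", 60, 30),
                mk("high", 40, 40), mk("low", 40, 2), mk("tiny", 5, 5))
  records <- tabs[, c("cell_barcode", "status", "edited_sites")]
  ann <- tabs[, c("cell_barcode", "cluster")]
  res <- cluster_divergence(records, ann, min_cells = 20, alpha = 0.05)
  expect_identical(sum(res$n_barcoded), nrow(tabs))
  expect_true(res$significant[res$cluster == "high"])
  expect_identical(res$direction[res$cluster == "high"], "higher")
  expect_true(res$significant[res$cluster == "low"])
  expect_identical(res$direction[res$cluster == "low"], "lower")
  expect_false(any(res$significant[grepl("null", res$cluster)]))
  tiny <- res[res$cluster == "tiny", ]
  expect_false(tiny$significant)
  expect_true(is.na(tiny$p_value))
  # oracle agreement for every tested cluster
  p0 <- attr(res, "p0")
  for (i in which(!is.na(res$p_value))) {
    expect_equal(res$p_value[i],
                 binom_p_oracle(res$n_edited[i], res$n_barcoded[i], p0),
                 tolerance = 1e-12)
  }
})

test_that("min_cells only filters clusters; surviving p-values are unchanged", {
  pop <- simulate_population(simulation_config(
    n_cells = 800, seed = 93,
    cluster_proportions = c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)))
  records <- pop[, c("cell_barcode", "status", "edited_sites")]
  ann <- pop[, c("cell_barcode", "cluster")]
  all_in <- cluster_divergence(records, ann, min_cells = 1, alpha = 1)
  expect_identical(nrow(all_in), length(unique(ann$cluster)))
  expect_true(all(all_in$significant | is.na(all_in$p_value) |
                    all_in$p_value >= 1))
  strict <- cluster_divergence(records, ann, min_cells = 50, alpha = 1)
  kept <- strict$cluster[!is.na(strict$p_value)]
  expect_true(all(kept %in% all_in$cluster[!is.na(all_in$p_value)]))
  for (cl in kept) {
    expect_identical(strict$p_value[strict$cluster == cl],
                     all_in$p_value[all_in$cluster == cl])
  }
})

test_that("detection bias recovers planted per-cluster recovery multipliers", {
  cfg <- simulation_config(
    n_cells = 5000, seed = 94, detection_rate = 0.2,
    cluster_proportions = c(boost = 0.15, drop = 0.15, base1 = 0.35,
                            base2 = 0.35),
    detection_multiplier = c(boost = 3, drop = 0.2))
  pop <- simulate_population(cfg)
  barcoded <- table(pop$cluster[pop$detected])
  atlas <- table(pop$cluster)
  res <- detection_bias(barcoded, atlas)
  expect_true(res$significant[res$cluster == "boost"])
  expect_identical(res$direction[res$cluster == "boost"], "higher")
  expect_true(res$significant[res$cluster == "drop"])
  expect_identical(res$direction[res$cluster == "drop"], "lower")
  expect_error(detection_bias(c(extra = 5), atlas), "absent")
})

test_that("uniform recovery produces no biased clusters", {
  cfg <- simulation_config(
    n_cells = 3000, seed = 95, detection_rate = 0.25,
    cluster_proportions = c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
  pop <- simulate_population(cfg)
  # a strict threshold: occasional raw p < 0.05 is expected noise across
  # four null tests, but nothing should approach strong evidence
  res <- detection_bias(table(pop$cluster[pop$detected]), table(pop$cluster),
                        alpha = 0.001)
  expect_false(any(res$significant))
})

test_that("tissue fractions normalize to the reference tissue", {
  mk <- function(frac, n = 400) {
    ne <- round(frac * n)
    data.frame(status = c(rep("edited", ne), rep("unedited", n - ne)),
               edited_sites = c(rep("1", ne), rep("", n - ne)))
  }
  per <- list(brain = mk(0.8), eye = mk(0.4), skin = mk(0.008), fin = mk(0))
  norm <- tissue_normalized_fractions(per, "brain")
  expect_identical(unname(norm["brain"]), 1)
  expect_equal(unname(norm["eye"]), 0.5)
  expect_identical(unname(norm["fin"]), 0)
  expect_equal(unname(norm["skin"]), 0.01, tolerance = 0.3)
  expect_error(tissue_normalized_fractions(per, "gill"), "not present")
  expect_error(tissue_normalized_fractions(list(brain = mk(0), skin = mk(0)),
                                           "brain"), "zero edited")
})

test_that("coverage_report counts hit clusters and lists planted misses", {
  ann <- data.frame(cell_barcode = sprintf("C%03d", 1:90),
                    cluster = rep(c("a", "b", "c"), each = 30))
  rec_all <- data.frame(cell_barcode = sprintf("C%03d", c(1, 31, 61)),
                        status = "edited", edited_sites = "1")
  cov <- coverage_report(rec_all, ann)
  expect_identical(cov$n_clusters_hit, 3L)
  expect_identical(cov$n_clusters_total, 3L)
  expect_identical(nrow(cov$missing), 0L)

  rec_partial <- rec_all[1:2, ]
  cov2 <- coverage_report(rec_partial, ann)
  expect_identical(cov2$n_clusters_hit, 2L)
  expect_identical(cov2$missing$cluster, "c")
  expect_identical(cov2$missing$n_atlas, 30L)
})
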