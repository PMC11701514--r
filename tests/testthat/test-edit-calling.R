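test_that("a perfect read aligns gap-free with the full match score", {
  ref <- default_saber_reference()
  amp <- ref_amplicon(ref)
  a <- align_read(amp, ref)
  expect_true(a$mapped)
  expect_identical(a$score, 2 * nchar(amp))
  expect_identical(unique(a$ops$op), "M")
  al <- extract_allele(a, ref, amp)
  expect_identical(al$status, "unedited")
  expect_identical(al$canonical, "-")
})

test_that("an excised target site is recovered as one deletion event", {
  ref <- default_saber_reference()
  ts <- ref$target_sites
  edited <- apply_events(ref$sequence, edit_event("D", ts$start[2], 23L))
  a <- align_read(substr(edited, 1, 151), ref)
  al <- extract_allele(a, ref, substr(edited, 1, 151))
  expect_identical(nrow(al$events), 1L)
  expect_identical(al$events$length, 23L)
  expect_identical(al$edited_sites, 2L)
  # oracle agreement on the same instance
  o <- gotoh_oracle(substr(edited, 1, 151), ref_amplicon(ref),
                    free_ref_tail = TRUE)
  expect_equal(a$score, o$score)
})

test_that("two disjoint intra-site deletions give edited_sites {1,3}", {
  ref <- default_saber_reference()
  ev <- rbind(edit_event("D", ref$cut_positions[1] - 1L, 4L),
              edit_event("D", ref$cut_positions[3] - 1L, 4L))
  edited <- apply_events(ref$sequence, ev)
  read <- substr(edited, 1, 151)
  al <- extract_allele(align_read(read, ref), ref, read)
  expect_identical(al$edited_sites, c(1L, 3L))
  expect_identical(nrow(al$events), 2L)
})

test_that("short reads and junk sequences are unmappable", {
  ref <- default_saber_reference()
  a49 <- align_read(substr(ref_amplicon(ref), 1, 49), ref)
  expect_false(a49$mapped)
  expect_identical(nrow(a49$ops), 0L)
  a50 <- align_read(substr(ref_amplicon(ref), 1, 50), ref)
  expect_true(a50$mapped)
  withr::local_seed(404)
  junk <- random_seq(120)
  expect_false(align_read(junk, ref)$mapped)
  expect_error(align_read("ACGU-ACGT", ref), "non-ACGTN")
  expect_error(align_read("", ref), "empty")
})

test_that("alignment matches the exhaustive DP oracle on random pairs", {
  withr::local_seed(405)
  ref <- default_saber_reference()
  sc <- align_scoring()
  for (k in 1:120) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    read <- random_seq(n1)
    # half the cases: reads derived from the target by mutation, so
    # realistic near-alignments are covered, not only random pairs
    target <- if (k %% 2 == 0) random_seq(n2) else {
      paste0(substr(read, 1, sample(n1, 1)), random_seq(sample(0:6, 1)))
    }
    free <- k %% 3 == 0
    got <- saberseq:::.gotoh_align_cpp(read, target, sc$match, sc$mismatch,
                                       sc$gap_open, sc$gap_extend, free)
    want <- gotoh_oracle(read, target, sc$match, sc$mismatch,
                         sc$gap_open, sc$gap_extend, free)
    expect_equal(got$score, want$score)
    got_ops <- data.frame(op = got$op, len = got$len, ref_start = got$ref_start,
                          read_start = got$read_start, stringsAsFactors = FALSE)
    expect_identical(got_ops, want$ops)
    expect_identical(reconstruct_read(target, got_ops, read),
                     reconstruct_read(target, want$ops, read))
  }
})

test_that("equivalent homopolymer gap placements canonicalize identically", {
  # reference with an A-run spanning a site boundary region
  base <- tiny_ref()
  seqc <- paste0(substr(base$sequence, 1, 12), "AAAAAA",
                 substr(base$sequence, 19, nchar(base$sequence)))
  ref <- saber_reference(seqc, base$target_sites, base$cut_positions,
                         base$primer_sites)
  # delete two bases at different positions inside the run: same molecule
  r1 <- apply_events(seqc, edit_event("D", 13, 2))
  r2 <- apply_events(seqc, edit_event("D", 16, 2))
  expect_identical(r1, r2)
  a <- align_read(r1, ref, min_read_len = 10L)
  al <- extract_allele(a, ref, r1)
  norm <- normalize_events(edit_event("D", 16, 2), seqc)
  expect_identical(al$canonical, canonicalize_events(norm))
})

test_that("cell consensus follows the UMI-majority and tie-break rules", {
  # 3 UMIs, same allele
  r <- rbind(read_row("CB1", "U1", "4D+40", 3), read_row("CB1", "U2", "4D+40", 2),
             read_row("CB1", "U3", "4D+40", 1))
  rec <- collapse_cells(r)
  expect_identical(rec$canonical_allele, "4D+40")
  expect_false(rec$conflict_flag)
  expect_identical(rec$n_umis, 3L)
  expect_identical(rec$n_reads, 6L)

  # 2 UMIs of A (5 reads) vs 1 UMI of B (1 read): A wins, conflict flagged
  r <- rbind(read_row("CB2", "U1", "4D+40", 3), read_row("CB2", "U2", "4D+40", 2),
             read_row("CB2", "U3", "7D+90", 1))
  rec <- collapse_cells(r)
  expect_identical(rec$canonical_allele, "4D+40")
  expect_true(rec$conflict_flag)

  # UMI tie broken by total read support
  r <- rbind(read_row("CB3", "U1", "4D+40", 3), read_row("CB3", "U2", "7D+90", 1))
  rec <- collapse_cells(r)
  expect_identical(rec$canonical_allele, "4D+40")

  # full tie broken lexicographically
  r <- rbind(read_row("CB4", "U1", "7D+90", 2), read_row("CB4", "U2", "4D+40", 2))
  rec <- collapse_cells(r)
  expect_identical(rec$canonical_allele, "4D+40")

  # within-UMI majority beats a noisy read
  r <- rbind(read_row("CB5", "U1", "4D+40", 4), read_row("CB5", "U1", "9D+10", 1))
  rec <- collapse_cells(r)
  expect_identical(rec$canonical_allele, "4D+40")
  expect_false(rec$conflict_flag)
})

test_that("cells with only unmappable reads are excluded from fractions", {
  r <- rbind(read_row("CBgood", "U1", "4D+40", 2),
             read_row("CBbad", "U1", NA_character_, 2))
  rec <- collapse_cells(r)
  bad <- rec[rec$cell_barcode == "CBbad", ]
  expect_identical(bad$status, "unmappable")
  expect_identical(bad$n_umis, 0L)
  expect_identical(edited_fraction(rec), 1)
})

test_that("whitelist matching reports recovery and handles edge cases", {
  rec <- collapse_cells(rbind(read_row("AAAA", "U1", "-"),
                              read_row("CCCC", "U1", "4D+40")))
  all_in <- match_cell_barcodes(rec, c("AAAA", "CCCC", "GGGG", "TTTT"))
  expect_identical(all_in$n_matched, 2L)
  expect_identical(all_in$recovery_rate, 0.5)
  expect_warning(none <- match_cell_barcodes(rec, c("GGGG")), "no cell barcodes")
  expect_identical(none$n_matched, 0L)
  expect_error(match_cell_barcodes(rec, character(0)), "empty")
})

test_that("every input read is accounted for across categories", {
  ref <- default_saber_reference()
  cfg <- simulation_config(n_cells = 150, seed = 71, detection_rate = 0.5,
                           umis_per_cell = 2, reads_per_cell = 3,
                           seq_error_rate = 0)
  pop <- simulate_population(cfg, ref)
  td <- withr::local_tempdir()
  r1 <- file.path(td, "R1.fastq.gz"); r2 <- file.path(td, "R2.fastq.gz")
  generate_reads(pop, cfg, ref, r1, r2)
  # whitelist covering only part of the population
  wl <- pop$cell_barcode[seq_len(100)]
  res <- call_alleles(r1, r2, ref, whitelist = wl)
  s <- res$summary
  expect_identical(s$reads_in,
                   s$reads_whitelist_unmatched + s$reads_matched_mappable +
                     s$reads_matched_unmappable)
  expect_identical(s$cells, nrow(res$cells))
  expect_true(all(res$cells$cell_barcode %in% wl))
})

test_that("consensus equals simulated truth, exactly without errors and for
          nearly all cells at 1% error", {
  ref <- default_saber_reference()
  check <- function(err, n) {
    cfg <- simulation_config(n_cells = n, seed = 81, seq_error_rate = err,
                             umis_per_cell = 3, reads_per_cell = 10)
    pop <- simulate_population(cfg, ref)
    td <- withr::local_tempdir()
    r1 <- file.path(td, "R1.fastq.gz"); r2 <- file.path(td, "R2.fastq.gz")
    generate_reads(pop, cfg, ref, r1, r2)
    res <- call_alleles(r1, r2, ref, whitelist = pop$cell_barcode)
    m <- merge(res$cells, pop, by = "cell_barcode")
    mean(m$canonical_allele.x == m$canonical_allele.y)
  }
  expect_identical(check(0, 250), 1)
  expect_gte(check(0.01, 500), 0.99)
})
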