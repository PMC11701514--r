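# Small fixtures built in code.

# A 46-nt reference with four 6-nt target sites, 2-nt spacers and short
# flanks, used where hand-checkable coordinates matter.
tiny_ref <- function() {
  saber_reference(
    sequence = "ACGTACGGATCCTAGCATTGCAGGTTCACGATGACCTGATACGGTA",
    target_sites = data.frame(start = c(4L, 12L, 20L, 28L),
                              end = c(10L, 18L, 26L, 34L)),
    cut_positions = c(7L, 15L, 23L, 31L),
    primer_sites = data.frame(start = c(0L, 34L), end = c(4L, 46L)))
}

# Random valid (sorted, non-overlapping) event lists for property tests.
random_events <- function(ref_len, n_events) {
  events <- empty_events()
  pos <- 0L
  for (k in seq_len(n_events)) {
    gap <- sample(1:6, 1)
    start <- pos + gap
    if (start >= ref_len - 2L) break
    if (stats::runif(1) < 0.3) {
      len <- sample(1:5, 1)
      events <- rbind(events, edit_event("I", start, len, random_seq(len)))
      pos <- start
    } else {
      len <- sample(1:min(8L, ref_len - start), 1)
      events <- rbind(events, edit_event("D", start, len))
      pos <- start + len
    }
  }
  events
}

# Minimal per-read table for consensus tests.
read_row <- function(cb, umi, canonical, n = 1L) {
  sites <- if (is.na(canonical) || canonical == "-") "" else "1"
  status <- if (is.na(canonical)) "unmappable" else {
    if (canonical == "-") "unedited" else "edited"
  }
  data.frame(cell_barcode = rep(cb, n), umi = rep(umi, n),
             canonical = rep(canonical, n),
             edited_sites = rep(sites, n), status = rep(status, n),
             stringsAsFactors = FALSE)
}
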