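#' Construct edit events
#'
#' Edit events are rows of a data.frame with columns `kind` ("D" for deletion,
#' "I" for insertion), `start` (0-based reference coordinate; for insertions,
#' the inserted bases sit immediately before this position), `length`
#' (positive) and `seq` (inserted bases; `""` for deletions). Within an
#' allele, events are sorted by `start` and non-overlapping; an insertion may
#' abut a deletion boundary but not fall strictly inside it.
#'
#' @param kind "D" or "I" (recycled).
#' @param start 0-based coordinate(s).
#' @param length Event length(s); for insertions must equal `nchar(seq)`.
#' @param seq Inserted sequence(s); ignored for deletions.
#' @return A data.frame of events.
#' @export
edit_event <- function(kind, start, length, seq = "") {
  df <- data.frame(kind = as.character(kind), start = as.integer(start),
                   length = as.integer(length), seq = as.character(seq),
                   stringsAsFactors = FALSE)
  df$seq[df$kind == "D"] <- ""
  df
}

#' @rdname edit_event
#' @export
empty_events <- function() {
  data.frame(kind = character(), start = integer(), length = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

sort_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  # an insertion at the same coordinate as a deletion start precedes it
  ord <- order(events$start, events$kind != "I")
  events[ord, , drop = FALSE]
}

#' Validate an event list against a reference length
#'
#' Checks kinds, bounds, positive lengths, insertion sequences, ordering and
#' non-overlap. Returns the sorted events invisibly; stops on violation.
#'
#' @param events Event data.frame (see [edit_event()]).
#' @param ref_length Reference length in nt.
#' @export
validate_events <- function(events, ref_length) {
  if (nrow(events) == 0L) return(invisible(events))
  if (!all(events$kind %in% c("D", "I"))) stop("event kind must be 'D' or 'I'")
  if (any(events$length <= 0L)) stop("event lengths must be positive")
  ins <- events$kind == "I"
  if (any(ins & (nchar(events$seq) != events$length |
                   !grepl("^[ACGT]+$", events$seq)))) {
    stop("insertions need an A/C/G/T sequence matching their length")
  }
  del <- !ins
  if (any(events$start < 0L) ||
      any(events$start[del] + events$length[del] > ref_length) ||
      any(events$start[ins] > ref_length)) {
    stop("event outside reference bounds")
  }
  events <- sort_events(events)
  # occupancy: deletion [start, end); insertion is a point, conflicting only
  # if strictly inside a deletion or coincident with another insertion
  dels <- events[events$kind == "D", , drop = FALSE]
  if (nrow(dels) > 1L) {
    e <- dels$start + dels$length
    if (any(dels$start[-1] < e[-nrow(dels)])) stop("overlapping deletions")
  }
  inspts <- events$start[ins]
  if (anyDuplicated(inspts)) stop("duplicate insertion points")
  if (nrow(dels) > 0L && length(inspts) > 0L) {
    for (p in inspts) {
      if (any(dels$start < p & p < dels$start + dels$length)) {
        stop("insertion inside a deletion")
      }
    }
  }
  invisible(events)
}

#' Canonical allele string encoding
#'
#' Deterministic, injective encoding of a sorted event list: `"-"` for an
#' intact allele; a deletion of length L at position P as `"<L>D+<P>"`; an
#' insertion as `"<L>I+<P>+<seq>"`; multiple events joined with `"&"`.
#' `parse_allele()` inverts the encoding losslessly.
#'
#' @param events Event data.frame.
#' @return Character scalar.
#' @examples
#' canonicalize_events(edit_event("D", 112, 35))
#' parse_allele("35D+112&4I+150+ACGT")
#' @export
canonicalize_events <- function(events) {
  events <- validate_events(events, ref_length = .Machine$integer.max)
  if (nrow(events) == 0L) return("-")
  enc <- ifelse(events$kind == "D",
                sprintf("%dD+%d", events$length, events$start),
                sprintf("%dI+%d+%s", events$length, events$start, events$seq))
  paste(enc, collapse = "&")
}

#' @rdname canonicalize_events
#' @param canonical Canonical allele string.
#' @export
parse_allele <- function(canonical) {
  if (is.na(canonical) || canonical == "-" || canonical == "") {
    return(empty_events())
  }
  parts <- strsplit(canonical, "&", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)([DI])\\+([0-9]+)(\\+([ACGT]+))?$", parts))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) stop("malformed canonical allele: ", canonical)
  ev <- do.call(rbind, lapply(m, function(g) {
    edit_event(g[3], as.integer(g[4]), as.integer(g[2]), g[6])
  }))
  validate_events(ev, ref_length = .Machine$integer.max)
  ev
}

#' Apply edit events to a sequence
#'
#' Reconstructs the edited array: deletions remove their interval, insertions
#' add their bases immediately before their coordinate. Used by the read
#' simulator and by round-trip tests.
#'
#' @param sequence Reference nucleotide string.
#' @param events Event data.frame, valid against `nchar(sequence)`.
#' @return Edited nucleotide string.
#' @export
apply_events <- function(sequence, events) {
  events <- validate_events(events, nchar(sequence))
  if (nrow(events) == 0L) return(sequence)
  out <- character(0)
  pos <- 0L  # consumed reference prefix (0-based)
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    if (ev$start > pos) out <- c(out, substr(sequence, pos + 1L, ev$start))
    if (ev$kind == "I") {
      out <- c(out, ev$seq)
      pos <- max(pos, ev$start)
    } else {
      pos <- ev$start + ev$length
    }
  }
  if (pos < nchar(sequence)) out <- c(out, substr(sequence, pos + 1L, nchar(sequence)))
  paste(out, collapse = "")
}

#' Left-normalize events against the reference
#'
#' Gaps adjacent to repeated reference bases admit several equivalent
#' placements; alignments are normalized by shifting every deletion (and
#' rotating every insertion) to its leftmost equivalent position so that
#' equivalent alignments canonicalize identically. Deletions that become
#' adjacent after shifting are merged.
#'
#' @param events Event data.frame.
#' @param sequence Reference nucleotide string.
#' @return Normalized, sorted event data.frame.
#' @export
normalize_events <- function(events, sequence) {
  events <- validate_events(events, nchar(sequence))
  if (nrow(events) == 0L) return(events)
  chars <- strsplit(sequence, "")[[1]]
  prev_end <- 0L  # leftmost admissible coordinate given already-placed events
  for (k in seq_len(nrow(events))) {
    s <- events$start[k]
    if (events$kind[k] == "D") {
      L <- events$length[k]
      while (s > prev_end && chars[s] == chars[s + L]) s <- s - 1L
      events$start[k] <- s
      prev_end <- s + L
    } else {
      ins <- strsplit(events$seq[k], "")[[1]]
      while (s > prev_end && ins[length(ins)] == chars[s]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])
        s <- s - 1L
      }
      events$start[k] <- s
      events$seq[k] <- paste(ins, collapse = "")
      prev_end <- s
    }
  }
  events <- sort_events(events)
  # merge deletions that now touch
  if (nrow(events) > 1L) {
    keep <- rep(TRUE, nrow(events))
    for (k in 2:nrow(events)) {
      j <- max(which(keep[1:(k - 1)]))
      if (events$kind[k] == "D" && events$kind[j] == "D" &&
          events$start[j] + events$length[j] == events$start[k]) {
        events$length[j] <- events$length[j] + events$length[k]
        keep[k] <- FALSE
      }
    }
    events <- events[keep, , drop = FALSE]
  }
  rownames(events) <- NULL
  events
}

#' Summarize an event list as an allele
#'
#' Computes the canonical string, the set of edited target sites (union of
#' [site_overlap()] over events) and the status (`edited` when any event is
#' present, `unedited` otherwise; mappability is decided upstream by the
#' aligner, never here).
#'
#' @param events Event data.frame.
#' @param ref A [saber_reference()].
#' @return `list(canonical, edited_sites (integer vector), status)`.
#' @export
allele_summary <- function(events, ref) {
  events <- validate_events(events, nchar(ref$sequence))
  if (nrow(events) == 0L) {
    return(list(canonical = "-", edited_sites = integer(0), status = "unedited"))
  }
  sites <- sort(unique(unlist(lapply(seq_len(nrow(events)), function(k) {
    site_overlap(events[k, ], ref)$sites
  }))))
  list(canonical = canonicalize_events(events),
       edited_sites = as.integer(sites), status = "edited")
}

format_sites <- function(sites) paste(sites, collapse = ",")

parse_sites <- function(x) {
  if (is.na(x) || x == "") integer(0) else as.integer(strsplit(x, ",")[[1]])
}
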