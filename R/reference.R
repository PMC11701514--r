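#' Barcode array reference
#'
#' A `saber_reference` describes the recorder amplicon: the array sequence,
#' four ordered sgRNA target-site intervals, one expected Cas9 cut position
#' per site, and the two primer-binding flanks. All coordinates are 0-based,
#' half-open on `sequence`.
#'
#' @param sequence Nucleotide string (A/C/G/T) of the full amplicon.
#' @param target_sites Integer matrix or data.frame with columns `start`,
#'   `end` (0-based half-open), one row per target site, ordered 5' to 3'.
#' @param cut_positions Integer vector, one 0-based coordinate per site; each
#'   must lie inside its site interval. Cas9 cuts between `cut` - 1 and `cut`,
#'   and the simulator deletes starting at base `cut`.
#' @param primer_sites Two-row matrix/data.frame (`start`, `end`): upstream
#'   and downstream primer-binding regions flanking the target block.
#' @return An object of class `saber_reference`.
#' @examples
#' ref <- default_saber_reference()
#' nchar(ref$sequence)
#' ref$target_sites
#' @export
saber_reference <- function(sequence, target_sites, cut_positions, primer_sites) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("reference sequence must contain only A/C/G/T")
  }
  ts <- as.data.frame(target_sites)
  if (!all(c("start", "end") %in% names(ts))) names(ts)[1:2] <- c("start", "end")
  ts$start <- as.integer(ts$start); ts$end <- as.integer(ts$end)
  if (nrow(ts) != 4L) stop("exactly 4 target sites are required")
  ts$site <- seq_len(4L)
  L <- nchar(sequence)
  if (any(ts$start < 0L) || any(ts$end > L) || any(ts$end <= ts$start)) {
    stop("target sites must be non-empty intervals inside the sequence")
  }
  if (any(diff(ts$start) <= 0) || any(ts$start[-1] < ts$end[-4])) {
    stop("target sites must be strictly ordered and non-overlapping")
  }
  cp <- as.integer(cut_positions)
  if (length(cp) != 4L) stop("one cut position per site is required")
  if (any(cp < ts$start) || any(cp >= ts$end)) {
    stop("each cut position must lie inside its target site")
  }
  ps <- as.data.frame(primer_sites)
  if (!all(c("start", "end") %in% names(ps))) names(ps)[1:2] <- c("start", "end")
  ps$start <- as.integer(ps$start); ps$end <- as.integer(ps$end)
  if (nrow(ps) != 2L) stop("two primer sites (upstream, downstream) are required")
  if (any(ps$start < 0L) || any(ps$end > L) || any(ps$end <= ps$start)) {
    stop("primer sites must be non-empty intervals inside the sequence")
  }
  if (ps$end[1] > ts$start[1] || ps$start[2] < ts$end[4]) {
    stop("primer sites must flank the target block")
  }
  structure(
    list(sequence = sequence, target_sites = ts[, c("site", "start", "end")],
         cut_positions = cp, primer_sites = ps[, c("start", "end")]),
    class = "saber_reference")
}

#' @export
print.saber_reference <- function(x, ...) {
  cat(sprintf("saber_reference: %d nt, 4 target sites\n", nchar(x$sequence)))
  for (k in 1:4) {
    cat(sprintf("  site %d: [%d, %d), cut at %d\n", k,
                x$target_sites$start[k], x$target_sites$end[k],
                x$cut_positions[k]))
  }
  cat(sprintf("  primers: [%d, %d) / [%d, %d)\n",
              x$primer_sites$start[1], x$primer_sites$end[1],
              x$primer_sites$start[2], x$primer_sites$end[2]))
  invisible(x)
}

#' Default synthetic barcode reference
#'
#' A configurable stand-in for the real recorder array (whose sequence is not
#' bundled): four 23-nt protospacer+PAM target sites separated by 8-nt
#' spacers, a 20-nt upstream and 60-nt downstream primer flank (196 nt
#' total). The downstream flank is long enough that a 151-cycle amplicon read
#' always covers the full target block. Cut positions sit 3 nt 5' of each
#' PAM (blunt SpCas9 cut). The sequence is generated deterministically from
#' a fixed internal seed, so every session sees the same reference.
#'
#' @param site_length Target-site length in nt (protospacer + PAM).
#' @param spacer_length Spacer length between consecutive sites, nt.
#' @param upstream_flank,downstream_flank Primer flank lengths, nt.
#' @return A [saber_reference()].
#' @export
default_saber_reference <- function(site_length = 23L, spacer_length = 8L,
                                    upstream_flank = 20L, downstream_flank = 60L) {
  starts <- upstream_flank + (0:3) * (site_length + spacer_length)
  ends <- starts + site_length
  total <- ends[4] + downstream_flank
  base <- c("A", "C", "G", "T")
  # fixed pseudo-random (Park-Miller) sequence, independent of the session
  # RNG and free of long repeats that would make alignment ambiguous
  x <- 20240625
  idx <- integer(total)
  for (k in seq_len(total)) {
    x <- (16807 * x) %% 2147483647
    idx[k] <- x %% 4L + 1L
  }
  seqc <- paste(base[idx], collapse = "")
  saber_reference(
    sequence = seqc,
    target_sites = data.frame(start = starts, end = ends),
    cut_positions = ends - 6L,  # 3 nt 5' of a 3-nt PAM
    primer_sites = data.frame(start = c(0L, ends[4]),
                              end = c(upstream_flank, total)))
}

#' Read or write a barcode reference description file
#'
#' References are stored as plain YAML: `sequence`, `target_sites` (list of
#' `start`/`end`), `cut_positions` and `primer_sites`.
#'
#' @param path File path.
#' @param ref A [saber_reference()].
#' @return `read_saber_reference` returns a `saber_reference`;
#'   `write_saber_reference` returns `path` invisibly.
#' @export
read_saber_reference <- function(path) {
  x <- yaml::read_yaml(path)
  saber_reference(
    sequence = x$sequence,
    target_sites = do.call(rbind, lapply(x$target_sites, as.data.frame)),
    cut_positions = unlist(x$cut_positions),
    primer_sites = do.call(rbind, lapply(x$primer_sites, as.data.frame)))
}

#' @rdname read_saber_reference
#' @export
write_saber_reference <- function(ref, path) {
  stopifnot(inherits(ref, "saber_reference"))
  x <- list(
    sequence = ref$sequence,
    target_sites = lapply(seq_len(4L), function(k) list(
      start = ref$target_sites$start[k], end = ref$target_sites$end[k])),
    cut_positions = as.list(ref$cut_positions),
    primer_sites = lapply(1:2, function(k) list(
      start = ref$primer_sites$start[k], end = ref$primer_sites$end[k])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Attribute an edit event to target sites
#'
#' A deletion's footprint is its deleted interval; an insertion's footprint is
#' its insertion point. An event is `intra` when the footprint lies entirely
#' within one target site, and `inter` when it spans two or more sites or
#' extends outside the site intervals. An insertion exactly at the junction
#' of two intervals is attributed to the left (5') site.
#'
#' @param event One edit event: a list or one-row data.frame with fields
#'   `kind` ("D" or "I"), `start` (0-based), `length`, and `seq` (insertions).
#' @param ref A [saber_reference()].
#' @return `list(sites = <integer vector>, category = "intra"|"inter")`.
#' @examples
#' ref <- default_saber_reference()
#' site_overlap(edit_event("D", ref$cut_positions[2], 4), ref)
#' @export
site_overlap <- function(event, ref) {
  event <- as.list(event)
  ts <- ref$target_sites
  L <- nchar(ref$sequence)
  start <- as.integer(event$start)
  len <- as.integer(event$length)
  if (event$kind == "D") {
    if (start < 0L || start + len > L) stop("deletion outside reference bounds")
    end <- start + len
    hit <- which(ts$start < end & start < ts$end)
    intra <- any(ts$start <= start & end <= ts$end)
  } else {
    if (start < 0L || start > L) stop("insertion point outside reference bounds")
    # contained iff site_start < point <= site_end; junction point goes left
    hit <- which(ts$start < start & start <= ts$end)
    if (length(hit) > 1L) hit <- hit[1L]
    intra <- length(hit) == 1L
  }
  list(sites = as.integer(hit), category = if (intra) "intra" else "inter")
}

#' The amplicon sequence between (and including) the primer flanks
#' @param ref A [saber_reference()].
#' @return Character scalar.
#' @export
ref_amplicon <- function(ref) {
  substr(ref$sequence, ref$primer_sites$start[1] + 1L, ref$primer_sites$end[2])
}
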