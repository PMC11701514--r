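# Independent oracles, written without reference to the package internals.

# Plain-R Gotoh dynamic program over explicit (n+1) x (m+1) state matrices.
# Mirrors the documented tie-break contract (end cell prefers the largest
# reference column; state preference M > D > I; an open gap prefers to
# extend) so op-level agreement can be asserted, but shares no code with the
# compiled implementation.
gotoh_oracle <- function(read, ref, match = 2, mismatch = -2,
                         gap_open = -6, gap_extend = -0.2,
                         free_ref_tail = FALSE) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  n <- length(rd); m <- length(rf)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); D <- M; I <- M
  pM <- matrix(NA_integer_, n + 1, m + 1); pD <- pM; pI <- pM
  M[1, 1] <- 0
  if (m > 0) {
    D[1, 2:(m + 1)] <- gap_open + (0:(m - 1)) * gap_extend
    pD[1, 2:(m + 1)] <- c(0L, rep(1L, m - 1))
  }
  if (n > 0) {
    I[2:(n + 1), 1] <- gap_open + (0:(n - 1)) * gap_extend
    pI[2:(n + 1), 1] <- c(0L, rep(2L, n - 1))
  }
  pick <- function(vals, order) {
    # vals named by state index 0/1/2; order = preference on ties
    best <- max(vals)
    for (st in order) if (vals[[as.character(st)]] == best) return(st)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (rd[i] == rf[j]) match else mismatch
      v <- c(`0` = M[i, j], `1` = D[i, j], `2` = I[i, j])
      w <- pick(v, c(0L, 1L, 2L))
      if (max(v) > NEG / 2) { M[i + 1, j + 1] <- max(v) + s; pM[i + 1, j + 1] <- w }
      v <- c(`0` = M[i + 1, j] + gap_open, `1` = D[i + 1, j] + gap_extend,
             `2` = I[i + 1, j] + gap_open)
      w <- pick(v, c(1L, 0L, 2L))
      if (max(v) > NEG / 2) { D[i + 1, j + 1] <- max(v); pD[i + 1, j + 1] <- w }
      v <- c(`0` = M[i, j + 1] + gap_open, `1` = D[i, j + 1] + gap_open,
             `2` = I[i, j + 1] + gap_extend)
      w <- pick(v, c(2L, 0L, 1L))
      if (max(v) > NEG / 2) { I[i + 1, j + 1] <- max(v); pI[i + 1, j + 1] <- w }
    }
  }
  end_j <- m; end_state <- 0L; best <- NEG
  cells <- if (free_ref_tail) m:0 else m
  for (j in cells) {
    v <- c(`0` = M[n + 1, j + 1], `1` = D[n + 1, j + 1], `2` = I[n + 1, j + 1])
    st <- pick(v, c(0L, 1L, 2L))
    if (max(v) > best) { best <- max(v); end_j <- j; end_state <- st }
  }
  # traceback
  path <- character(0)
  i <- n; j <- end_j; st <- end_state
  while (i > 0 || j > 0) {
    if (st == 0L) {
      if (i == 0 && j == 0) break
      prev <- pM[i + 1, j + 1]
      path <- c(if (rd[i] == rf[j]) "M" else "X", path)
      i <- i - 1; j <- j - 1; st <- prev
    } else if (st == 1L) {
      prev <- pD[i + 1, j + 1]
      path <- c("D", path)
      j <- j - 1; st <- prev
    } else {
      prev <- pI[i + 1, j + 1]
      path <- c("I", path)
      i <- i - 1; st <- prev
    }
    if (i == 0 && j == 0) break
  }
  r <- rle(path)
  starts_ref <- integer(length(r$values)); starts_read <- integer(length(r$values))
  ri <- 0L; rj <- 0L
  for (k in seq_along(r$values)) {
    starts_ref[k] <- rj; starts_read[k] <- ri
    L <- r$lengths[k]
    if (r$values[k] %in% c("M", "X")) { ri <- ri + L; rj <- rj + L }
    else if (r$values[k] == "D") rj <- rj + L
    else ri <- ri + L
  }
  list(score = best,
       ops = data.frame(op = r$values, len = as.integer(r$lengths),
                        ref_start = starts_ref, read_start = starts_read,
                        stringsAsFactors = FALSE))
}

# Reconstructs the read from the reference and an op table (any aligner's),
# used as a conservation check on alignments.
reconstruct_read <- function(ref, ops, read) {
  out <- character(0)
  for (k in seq_len(nrow(ops))) {
    o <- ops[k, ]
    if (o$op %in% c("M", "X")) {
      out <- c(out, substr(read, o$read_start + 1, o$read_start + o$len))
    } else if (o$op == "I") {
      out <- c(out, substr(read, o$read_start + 1, o$read_start + o$len))
    }
  }
  paste(out, collapse = "")
}

# Direct probability-mass summation for the two-sided exact binomial test
# (all outcomes at most as probable as the observed one).
binom_p_oracle <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Monte-Carlo oracle for the edited fraction among signal-active lineages:
# re-enumerates the per-round, per-site cut process (a lineage is edited as
# soon as any intact site is cut).
mc_edited_fraction <- function(p_cut, n_rounds, n = 10000) {
  edited <- logical(n)
  for (i in seq_len(n)) {
    intact <- rep(TRUE, 4)
    for (r in seq_len(n_rounds)) {
      cut <- intact & stats::runif(4) < p_cut
      if (any(cut)) { edited[i] <- TRUE; intact[cut] <- FALSE }
    }
  }
  mean(edited)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
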