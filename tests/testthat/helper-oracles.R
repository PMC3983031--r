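# Independent oracles used across the suite. The aligner oracle enumerates
# every (position, split, gap) placement through Biostrings pattern
# matching -- a separate code path from the package's scan -- and the
# Poisson oracle sums the pmf directly.

oracle_ungapped <- function(read, genome, max_mm = 4L) {
  pat <- Biostrings::DNAString(read)
  hits <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, genome[[chrom]], max.mismatch = max_mm)
      if (length(m) == 0L) next
      st <- BiocGenerics::start(m)
      mm <- Biostrings::neditStartingAt(p, genome[[chrom]], starting.at = st)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, strand = strand, b1_start = st,
        b1_end = st + length(p) - 1L,
        b2_start = NA_integer_, b2_end = NA_integer_,
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, hits)
  df[df$mismatches == min(df$mismatches), , drop = FALSE]
}

oracle_gapped <- function(read, genome, max_mm = 3L, min_gap = 10L,
                          max_gap = 20000L, min_anchor = 12L) {
  L <- nchar(read)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (strand in c("+", "-")) {
      r <- if (strand == "+") read else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
      for (s in seq(min_anchor, L - min_anchor)) {
        pre <- Biostrings::DNAString(substr(r, 1L, s))
        suf <- Biostrings::DNAString(substr(r, s + 1L, L))
        mp <- Biostrings::matchPattern(pre, subj, max.mismatch = max_mm)
        if (length(mp) == 0L) next
        ms <- Biostrings::matchPattern(suf, subj, max.mismatch = max_mm)
        if (length(ms) == 0L) next
        ps <- BiocGenerics::start(mp)
        qs <- BiocGenerics::start(ms)
        mmp <- Biostrings::neditStartingAt(pre, subj, starting.at = ps)
        mms <- Biostrings::neditStartingAt(suf, subj, starting.at = qs)
        for (i in seq_along(ps)) {
          gap <- qs - (ps[i] + s)
          ok <- gap >= min_gap & gap <= max_gap & (mmp[i] + mms) <= max_mm
          for (j in which(ok)) {
            hits[[length(hits) + 1L]] <- data.frame(
              chrom = chrom, strand = strand,
              b1_start = ps[i], b1_end = ps[i] + s - 1L,
              b2_start = qs[j], b2_end = qs[j] + (L - s) - 1L,
              mismatches = mmp[i] + mms[j], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, hits)
  df[df$mismatches == min(df$mismatches), , drop = FALSE]
}

# full two-step policy on one read; returns NULL (discarded/unaligned) or
# data.frame of kept locations with a `step` column
oracle_map_read <- function(read, genome, max_locations = 2L) {
  a1 <- oracle_ungapped(read, genome)
  if (!is.null(a1)) {
    if (nrow(a1) <= max_locations) { a1$step <- "ungapped"; return(a1) }
    return(NULL)
  }
  a2 <- oracle_gapped(read, genome)
  if (!is.null(a2) && nrow(a2) <= max_locations) {
    a2$step <- "gapped"
    return(a2)
  }
  NULL
}

# canonical row ordering for comparing alignment tables
sort_aln <- function(df) {
  df <- df[, c("chrom", "strand", "b1_start", "b1_end",
               "b2_start", "b2_end", "mismatches", "step")]
  df <- df[order(df$chrom, df$strand, df$b1_start, df$b1_end,
                 df$b2_start, df$b2_end, na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# P(X >= k) for X ~ Poisson(lam) by direct pmf summation until the term
# underflows
oracle_pois_upper <- function(lam, k) {
  if (k == 0L) return(1)
  if (lam == 0) return(0)
  tot <- 0
  i <- k
  repeat {
    term <- exp(i * log(lam) - lam - lgamma(i + 1))
    tot <- tot + term
    if (term < 1e-18 && i > lam) break
    i <- i + 1L
    if (i > k + 10000L) break
  }
  tot
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_read <- function(read, n_mut) {
  if (n_mut == 0L) return(read)
  s <- strsplit(read, "")[[1L]]
  at <- sample.int(length(s), n_mut)
  for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}
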