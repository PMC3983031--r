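#' Position-frequency matrix of equal-length sequences
#'
#' Tallies per-position base frequencies over `{A, C, G, T}` with an
#' optional pseudocount: `freq = (count + pseudocount) /
#' (n + 4 * pseudocount)`. Sequences containing `N` are excluded and
#' counted. One sequence per unique event, not per supporting read, so the
#' matrix summarises splice sites rather than read depth.
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @param pseudocount Added to every cell before normalisation (default 0).
#' @return List of class `pfm`: `width`, `freqs` (4 x width matrix, rows
#'   A/C/G/T, columns summing to 1), `n_seqs`, `n_excluded`.
#' @export
build_pfm <- function(seqs, pseudocount = 0) {
  if (length(seqs) == 0L) stop("no sequences")
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must all have the same length")
  has_n <- grepl("N", seqs, fixed = TRUE)
  n_excluded <- sum(has_n)
  seqs <- seqs[!has_n]
  if (length(seqs) == 0L) stop("no N-free sequences")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) stop("non-ACGT character in sequences")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab)
  }, numeric(4L))
  dimnames(counts) <- list(c("A", "C", "G", "T"), NULL)
  freqs <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  dimnames(freqs) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(width = w, freqs = freqs, n_seqs = length(seqs),
                 n_excluded = n_excluded),
            class = "pfm")
}

#' Per-position information content of a PFM
#'
#' Shannon information in bits at each position:
#' `ic_j = 2 + sum_b f_bj * log2(f_bj)` with `0 * log(0) = 0`
#' (logo letter heights). An optional small-sample correction subtracts
#' `3 / (2 * ln(2) * n)` from each position (floored at 0); it is off by
#' default.
#'
#' @param pfm A `pfm` from [build_pfm].
#' @param small_sample_correction Apply the correction (default FALSE)?
#' @return Numeric vector of per-position bits in `[0, 2]`.
#' @export
info_content <- function(pfm, small_sample_correction = FALSE) {
  f <- pfm$freqs
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) {
    ic <- pmax(0, ic - 3 / (2 * log(2) * pfm$n_seqs))
  }
  ic
}

#' Write a PFM (frequencies + information content) to TSV
#'
#' @param pfm A `pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = seq_len(pfm$width),
                   t(pfm$freqs),
                   bits = info_content(pfm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
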