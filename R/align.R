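BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

encode_dna <- function(s) {
  v <- BASE_CODE[strsplit(toupper(s), "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) {
    bad <- unique(strsplit(toupper(s), "")[[1L]])
    bad <- bad[!bad %in% names(BASE_CODE)]
    stop("read contains non-ACGTN character(s): ", paste(bad, collapse = ", "))
  }
  unname(v)
}

encode_genome <- function(genome) {
  lapply(as.character(genome), function(s) {
    v <- BASE_CODE[strsplit(s, "", fixed = TRUE)[[1L]]]
    unname(v)
  })
}

#' Ungapped exhaustive alignment of one read
#'
#' Scans every position of both strands of every chromosome and returns all
#' locations achieving the minimum mismatch count, provided that minimum is
#' at most `max_mismatch`; otherwise an empty table. Score is the mismatch
#' count (no gaps, no indels). This is step 1 of the two-step mapping
#' policy: up to four mismatches, no gaps.
#'
#' @param read DNA string (A/C/G/T/N), length >= 20.
#' @param genome Genome [Biostrings::DNAStringSet], or the pre-encoded
#'   result of the internal encoder (used by [map_library] to avoid
#'   re-encoding per read).
#' @param max_mismatch Maximum mismatches (default 4).
#' @return Alignment data.frame (see [alignment-table]); `n_best` on every
#'   row is the number of equal-best locations.
#' @export
align_ungapped <- function(read, genome, max_mismatch = 4L) {
  scan_read(read, genome, step = "ungapped", max_mismatch = max_mismatch)
}

#' Single-gap exhaustive spliced alignment of one read
#'
#' Searches every split of the read into a prefix and suffix (each at least
#' `min_anchor` nucleotides) placed with a single gap of length in
#' `[min_gap, max_gap]` between them, on both strands of every chromosome.
#' Returns all placements achieving the minimum total mismatch count if
#' that minimum is at most `max_mismatch`. Placements whose gap would be
#' shorter than `min_gap` are never produced: contiguous placements belong
#' to step 1, and sub-threshold gaps are excluded by the mapping policy
#' ("no gap smaller than ten nucleotides").
#'
#' @inheritParams align_ungapped
#' @param max_mismatch Maximum mismatches (default 3).
#' @param min_gap,max_gap Allowed gap (intron) length range, default 10 to
#'   20000 nt.
#' @param min_anchor Minimum aligned length on each side of the gap
#'   (default 12 nt).
#' @export
align_gapped <- function(read, genome, max_mismatch = 3L,
                         min_gap = 10L, max_gap = 20000L, min_anchor = 12L) {
  scan_read(read, genome, step = "gapped", max_mismatch = max_mismatch,
            min_gap = min_gap, max_gap = max_gap, min_anchor = min_anchor)
}

scan_read <- function(read, genome, step, max_mismatch,
                      min_gap = 10L, max_gap = 20000L, min_anchor = 12L,
                      read_id = "read") {
  read <- toupper(as.character(read))
  if (nchar(read) < 20L) stop("read shorter than 20 nt")
  enc <- encode_dna(read)
  enc_rc <- rev(3L - enc)          # A<->T, C<->G; N (4) maps to -1 ...
  enc_rc[enc_rc < 0L] <- 4L        # ... restore N
  if (is(genome, "DNAStringSet")) genome <- encode_genome(genome)
  hits <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    for (strand in c("+", "-")) {
      r <- if (strand == "+") enc else enc_rc
      if (step == "ungapped") {
        m <- scan_ungapped_cpp(r, g, as.integer(max_mismatch))
        if (nrow(m) > 0L) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, strand = strand,
            b1_start = m[, "pos"], b1_end = m[, "pos"] + length(r) - 1L,
            b2_start = NA_integer_, b2_end = NA_integer_,
            mismatches = m[, "mm"], stringsAsFactors = FALSE)
        }
      } else {
        m <- scan_gapped_cpp(r, g, as.integer(max_mismatch),
                             as.integer(min_gap), as.integer(max_gap),
                             as.integer(min_anchor))
        if (nrow(m) > 0L) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, strand = strand,
            b1_start = m[, "pos"], b1_end = m[, "pos"] + m[, "split"] - 1L,
            b2_start = m[, "qpos"],
            b2_end = m[, "qpos"] + (length(r) - m[, "split"]) - 1L,
            mismatches = m[, "mm"], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) return(alignment_table())
  df <- do.call(rbind, hits)
  best <- min(df$mismatches)
  df <- df[df$mismatches == best, , drop = FALSE]
  out <- alignment_table(
    read_id = rep(read_id, nrow(df)), sample = rep(NA_character_, nrow(df)),
    chrom = df$chrom, strand = df$strand,
    b1_start = df$b1_start, b1_end = df$b1_end,
    b2_start = df$b2_start, b2_end = df$b2_end,
    mismatches = df$mismatches, n_best = rep(nrow(df), nrow(df)),
    step = rep(step, nrow(df)))
  rownames(out) <- NULL
  out
}

#' Map a read library with the two-step policy
#'
#' Step 1 aligns every read ungapped (up to `max_mismatch_ungapped`
#' mismatches); only reads with no step-1 placement at all proceed to the
#' gapped step 2 (up to `max_mismatch_gapped` mismatches, one gap of
#' `min_gap`..`max_gap` nt). In either step a read is kept only if its
#' best-score location count is at most `max_locations`; kept multi-mapping
#' reads contribute one row per location and are flagged through
#' `n_best > 1`. A read with step-1 placements at too many locations is
#' discarded, not retried gapped (it did not "fail to align" in step 1).
#'
#' @param reads Either a path to a FASTQ file, a named character vector of
#'   read sequences, or a [Biostrings::DNAStringSet].
#' @param genome Genome [Biostrings::DNAStringSet].
#' @param sample Sample label attached to accepted alignments.
#' @param max_mismatch_ungapped,max_mismatch_gapped Mismatch ceilings for
#'   the two steps (defaults 4 and 3).
#' @param min_gap,max_gap,min_anchor Gapped-step geometry (defaults 10,
#'   20000, 12 nt).
#' @param max_locations Maximum equal-best locations for a read to be kept
#'   (default 2).
#' @return List with `alignments` (accepted placements, see
#'   [alignment-table]) and `report` (named integer vector of totals per
#'   step and filter).
#' @export
map_library <- function(reads, genome, sample = "sample",
                        max_mismatch_ungapped = 4L, max_mismatch_gapped = 3L,
                        min_gap = 10L, max_gap = 20000L, min_anchor = 12L,
                        max_locations = 2L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  seqs <- setNames(as.character(reads), names(reads))
  if (length(seqs) > 0L && is.null(names(seqs))) {
    names(seqs) <- paste0("read", seq_along(seqs))
  }
  enc_genome <- encode_genome(genome)
  report <- c(n_reads = length(seqs), step1_accepted = 0L,
              step1_multi_rejected = 0L, step2_aligned = 0L,
              step2_accepted = 0L, step2_multi_rejected = 0L,
              unaligned = 0L)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    a1 <- scan_read(seqs[[i]], enc_genome, "ungapped",
                    max_mismatch_ungapped, read_id = names(seqs)[i])
    if (nrow(a1) > 0L) {
      if (nrow(a1) <= max_locations) {
        a1$sample <- sample
        out[[i]] <- a1
        report["step1_accepted"] <- report["step1_accepted"] + 1L
      } else {
        report["step1_multi_rejected"] <- report["step1_multi_rejected"] + 1L
      }
      next
    }
    a2 <- scan_read(seqs[[i]], enc_genome, "gapped", max_mismatch_gapped,
                    min_gap = min_gap, max_gap = max_gap,
                    min_anchor = min_anchor, read_id = names(seqs)[i])
    if (nrow(a2) > 0L) {
      report["step2_aligned"] <- report["step2_aligned"] + 1L
      if (nrow(a2) <= max_locations) {
        a2$sample <- sample
        out[[i]] <- a2
        report["step2_accepted"] <- report["step2_accepted"] + 1L
      } else {
        report["step2_multi_rejected"] <- report["step2_multi_rejected"] + 1L
      }
    } else {
      report["unaligned"] <- report["unaligned"] + 1L
    }
  }
  alignments <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(alignments)) alignments <- alignment_table()
  rownames(alignments) <- NULL
  list(alignments = alignments, report = report)
}
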