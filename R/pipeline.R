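#' Annotate junctions with PTC classification
#'
#' For every junction assigned to an intron-containing gene, builds the
#' splice product in the otherwise-canonical transcript and fills in
#' `is_ptc`, `is_frameshift`, `utr3_len`, `nmd_candidate` and
#' `protein_delta` columns. Junctions outside ICGs, in genes excluded from
#' PTC analysis, or whose excision overlaps several annotated introns are
#' left `NA` (the latter flagged in `ptc_note`).
#'
#' @param junctions Classified junction data.frame
#'   (from [classify_events]).
#' @param genes Named list of [gene_model] objects.
#' @param genome Genome [Biostrings::DNAStringSet].
#' @param utr3_threshold Passed to [call_ptc].
#' @return The junction table with PTC columns added.
#' @export
annotate_ptc <- function(junctions, genes, genome, utr3_threshold = 0L) {
  n <- nrow(junctions)
  junctions$is_ptc <- NA
  junctions$is_frameshift <- NA
  junctions$utr3_len <- NA_integer_
  junctions$nmd_candidate <- NA
  junctions$protein_delta <- NA_character_
  junctions$ptc_note <- NA_character_
  for (j in seq_len(n)) {
    if (is.na(junctions$gene_id[j]) ||
        !junctions$status[j] %in% c("annotated", "alternative")) next
    gene <- genes[[junctions$gene_id[j]]]
    if (gene$ptc_excluded || is.na(gene$cds_start)) {
      junctions$ptc_note[j] <- "ptc_excluded"
      next
    }
    prod <- tryCatch(
      build_splice_product(gene, junctions[j, ], genome),
      error = function(e) conditionMessage(e))
    if (is.character(prod)) {
      junctions$ptc_note[j] <- prod
      next
    }
    prod <- call_ptc(prod, gene, utr3_threshold = utr3_threshold)
    prod <- protein_consequence(prod, gene, genome)
    junctions$is_ptc[j] <- prod$is_ptc
    junctions$is_frameshift[j] <- prod$is_frameshift
    junctions$utr3_len[j] <- prod$utr3_len
    junctions$nmd_candidate[j] <- prod$nmd_candidate
    junctions$protein_delta[j] <- prod$protein_delta
    if (prod$start_lost) junctions$ptc_note[j] <- "start_lost"
  }
  junctions
}

#' Reshape junction counts for enrichment testing
#'
#' Converts the wide per-sample `count_<sample>` columns of a junction
#' table into the long `(unit_id, sample, count)` form [enrichment_table]
#' consumes. With `unique_events = TRUE` (the default for event-level
#' enrichment) every junction contributes presence/absence (0/1) per
#' sample rather than its read support.
#'
#' @param junctions Junction data.frame.
#' @param unique_events Count unique events (TRUE) or read support (FALSE)?
#' @return Long data.frame with `unit_id`, `sample`, `count`.
#' @export
junction_counts_long <- function(junctions, unique_events = TRUE) {
  cnt_cols <- grep("^count_", names(junctions), value = TRUE)
  samples <- sub("^count_", "", cnt_cols)
  key <- paste(junctions$chrom, junctions$intron_start,
               junctions$intron_end, sep = ":")
  out <- do.call(rbind, lapply(seq_along(samples), function(i) {
    cnt <- junctions[[cnt_cols[i]]]
    if (unique_events) cnt <- as.integer(cnt > 0L)
    data.frame(unit_id = key, sample = samples[i], count = cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Site-sequence sets for consensus analysis
#'
#' Splits classified junctions into canonical (annotated) and alternative
#' sets and returns their donor and acceptor sequences, ready for
#' [build_pfm]. Truncated (short-intron) windows are dropped.
#'
#' @param junctions Junction table after [site_sequences].
#' @return List with `canonical` and `alternative`, each containing
#'   `donor` and `acceptor` character vectors.
#' @export
site_sets <- function(junctions) {
  ok <- !junctions$short_intron
  pick <- function(status) {
    sel <- ok & junctions$status == status
    list(donor = junctions$donor_seq[sel],
         acceptor = junctions$acceptor_window[sel])
  }
  list(canonical = pick("annotated"), alternative = pick("alternative"))
}
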