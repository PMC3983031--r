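#' Write junction events to BED6 and TSV
#'
#' Serialises a junction table to two files: `<prefix>.bed`, a BED6 file of
#' intron intervals (BED is the only 0-based half-open surface: `chromStart`
#' is `intron_start - 1`), and `<prefix>.tsv`, a tab-separated table with
#' one row per junction carrying gene, status, donor/acceptor sequences,
#' per-sample raw and depth-normalised counts and the PTC flag. All internal
#' coordinates stay 1-based inclusive.
#'
#' @param junctions Junction data.frame from [extract_junctions] /
#'   [classify_events].
#' @param prefix Output path prefix (files `<prefix>.bed`, `<prefix>.tsv`).
#' @return Character vector of the two paths, invisibly.
#' @export
write_junctions <- function(junctions, prefix) {
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  cnt_cols <- grep("^count_", names(junctions), value = TRUE)
  if (nrow(junctions) > 0L) {
    total <- if (length(cnt_cols)) rowSums(junctions[, cnt_cols, drop = FALSE]) else 0L
    name <- ifelse(is.na(junctions$gene_id) | junctions$gene_id == "",
                   "NA", junctions$gene_id)
    bed <- paste(junctions$chrom, junctions$intron_start - 1L,
                 junctions$intron_end, name, total,
                 ifelse(is.na(junctions$strand), ".", junctions$strand),
                 sep = "\t")
  } else {
    bed <- character(0)
  }
  writeLines(bed, bed_path)
  write.table(junctions, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a junction TSV written by [write_junctions]
#'
#' @param path Path to the TSV file.
#' @return Junction data.frame.
#' @export
read_junctions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("intron_start", "intron_end")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}
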