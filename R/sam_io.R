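#' Spliced-alignment tables
#'
#' Alignments are held in a plain data.frame with one row per aligned read
#' placement: `read_id`, `sample`, `chrom`, `strand`, block coordinates
#' (`b1_start`, `b1_end` and, for gapped placements, `b2_start`, `b2_end`;
#' 1-based inclusive reference intervals), `mismatches`, `n_best` (number of
#' equal-best locations) and `step` (`"ungapped"` or `"gapped"`). At most one
#' inter-block gap is allowed, matching a two-step mapping policy in which a
#' read aligns either contiguously or across a single intron.
#'
#' @name alignment-table
NULL

alignment_table <- function(read_id = character(), sample = character(),
                            chrom = character(), strand = character(),
                            b1_start = integer(), b1_end = integer(),
                            b2_start = integer(), b2_end = integer(),
                            mismatches = integer(), n_best = integer(),
                            step = character()) {
  data.frame(read_id = read_id, sample = sample, chrom = chrom,
             strand = strand, b1_start = b1_start, b1_end = b1_end,
             b2_start = b2_start, b2_end = b2_end,
             mismatches = mismatches, n_best = n_best, step = step,
             stringsAsFactors = FALSE)
}

#' Read spliced alignments from a SAM file
#'
#' Parses a plain-text SAM file into an alignment table. CIGAR strings may
#' contain `M`, `=`, `X`, `N` and `S` operators; `N` lengths become the
#' single inter-block gap and soft clips are excluded from blocks. Records
#' with `I`/`D` operators (indels) or more than one `N` gap are rejected and
#' counted, as are unmapped records; malformed CIGARs are logged and
#' skipped. Mismatch counts are taken from `NM` tags and location counts
#' from `NH` tags when present.
#'
#' @param path Path to a SAM file.
#' @param sample Sample label attached to every record; defaults to the
#'   file name without extension.
#' @return Alignment data.frame (see [alignment-table]) with a `report`
#'   attribute counting skipped records by reason.
#' @export
read_alignments <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  report <- c(total = length(lines), kept = 0L, unmapped = 0L,
              indel = 0L, multi_gap = 0L, malformed = 0L)
  if (length(lines) == 0L) {
    out <- alignment_table()
    attr(out, "report") <- report
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(f)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- f[[i]]
    if (length(x) < 11L) { report["malformed"] <- report["malformed"] + 1L; next }
    flag <- suppressWarnings(as.integer(x[2L]))
    if (is.na(flag)) { report["malformed"] <- report["malformed"] + 1L; next }
    if (bitwAnd(flag, 4L) != 0L) { report["unmapped"] <- report["unmapped"] + 1L; next }
    cigar <- x[6L]
    ops <- tryCatch(parse_cigar(cigar),
                    error = function(e) NULL)
    if (is.null(ops)) { report["malformed"] <- report["malformed"] + 1L; next }
    if (any(ops$op %in% c("I", "D"))) { report["indel"] <- report["indel"] + 1L; next }
    if (any(!ops$op %in% c("M", "=", "X", "N", "S", "H"))) {
      report["malformed"] <- report["malformed"] + 1L; next
    }
    if (sum(ops$op == "N") > 1L) { report["multi_gap"] <- report["multi_gap"] + 1L; next }
    pos <- as.integer(x[4L])
    blocks <- cigar_blocks(ops, pos)
    tags <- x[-(1:11)]
    nm <- tag_value(tags, "NM"); nh <- tag_value(tags, "NH")
    rows[[i]] <- data.frame(
      read_id = x[1L], sample = sample, chrom = x[3L],
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      b1_start = blocks[1L, 1L], b1_end = blocks[1L, 2L],
      b2_start = if (nrow(blocks) > 1L) blocks[2L, 1L] else NA_integer_,
      b2_end = if (nrow(blocks) > 1L) blocks[2L, 2L] else NA_integer_,
      mismatches = if (is.na(nm)) 0L else nm,
      n_best = if (is.na(nh)) 1L else nh,
      step = if (nrow(blocks) > 1L) "gapped" else "ungapped",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- alignment_table()
  report["kept"] <- nrow(out)
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  list(op = ops, len = lens)
}

# reference-space blocks from parsed CIGAR (M/=/X consume; N gaps; S/H skip)
cigar_blocks <- function(ops, pos) {
  blocks <- NULL
  cur_start <- pos; cur <- pos
  open <- FALSE
  for (i in seq_along(ops$op)) {
    o <- ops$op[i]; l <- ops$len[i]
    if (o %in% c("M", "=", "X")) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + l
    } else if (o == "N") {
      if (open) blocks <- rbind(blocks, c(cur_start, cur - 1L))
      open <- FALSE
      cur <- cur + l
    }
    # S/H consume no reference space
  }
  if (open) blocks <- rbind(blocks, c(cur_start, cur - 1L))
  blocks
}

tag_value <- function(tags, name) {
  hit <- tags[startsWith(tags, paste0(name, ":i:"))]
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(sub("^..:i:", "", hit[1L]))
}

#' Write spliced alignments to a SAM file
#'
#' Emits plain-text SAM with `@SQ` headers taken from the genome, CIGARs
#' rebuilt from the block coordinates (`<m>M<gap>N<m>M` for gapped records),
#' and `NM`/`NH` tags carrying mismatch and equal-best-location counts.
#'
#' @param alignments Alignment data.frame (see [alignment-table]).
#' @param path Output path.
#' @param genome Genome [Biostrings::DNAStringSet] for `@SQ` lines.
#' @param seqs Optional named character vector of read sequences (by
#'   `read_id`); written as `*` when absent.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, genome, seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(names(genome), function(ch) {
             sprintf("@SQ\tSN:%s\tLN:%d", ch, length(genome[[ch]]))
           }, character(1)))
  n <- nrow(alignments)
  body <- character(n)
  for (i in seq_len(n)) {
    a <- alignments[i, ]
    gapped <- !is.na(a$b2_start)
    cigar <- if (gapped) {
      sprintf("%dM%dN%dM", a$b1_end - a$b1_start + 1L,
              a$b2_start - a$b1_end - 1L, a$b2_end - a$b2_start + 1L)
    } else {
      sprintf("%dM", a$b1_end - a$b1_start + 1L)
    }
    seq <- if (!is.null(seqs) && a$read_id %in% names(seqs)) seqs[[a$read_id]] else "*"
    body[i] <- paste(a$read_id,
                     if (a$strand == "-") 16L else 0L,
                     a$chrom, a$b1_start, 255L, cigar, "*", 0L, 0L,
                     seq, "*",
                     sprintf("NM:i:%d", a$mismatches),
                     sprintf("NH:i:%d", a$n_best),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
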