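STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build the splice product of an alternative event
#'
#' Constructs the mRNA obtained by applying one observed junction to the
#' otherwise-canonical transcript: the single annotated intron the event
#' overlaps is replaced by the event's excision, every other intron is
#' spliced canonically, and any exonic sequence inside the event's interval
#' is removed. The product keeps the canonical start codon anchored at the
#' annotated CDS start; if the event excises the start codon the product is
#' flagged `start_lost`.
#'
#' @param gene A [gene_model] (intron-containing, with a CDS).
#' @param event List or one-row data.frame with `intron_start` and
#'   `intron_end` (1-based inclusive genomic interval of the excision).
#' @param genome Genome [Biostrings::DNAStringSet].
#' @return A `splice_product` list: `gene_id`, `event` interval, `mrna_seq`,
#'   kept genomic intervals, `delta` (excision-length change vs the
#'   annotated intron), `cds_start_product` and `canon_stop_product`
#'   (product transcript coordinates), `start_lost`.
#' @export
build_splice_product <- function(gene, event, genome) {
  if (!gene$is_icg) stop("gene ", gene$gene_id, " has no introns")
  es <- as.integer(event$intron_start); ee <- as.integer(event$intron_end)
  introns <- gene$introns
  ov <- which(pmax(introns[, 1L], es) <= pmin(introns[, 2L], ee))
  if (length(ov) != 1L) {
    stop("unsupported event: excision [", es, ",", ee, "] overlaps ",
         length(ov), " annotated introns of ", gene$gene_id)
  }
  other <- introns[-ov, , drop = FALSE]
  span <- gene_span(gene)
  excised <- rbind(other, c(es, ee))
  kept <- interval_complement(span, excised)
  parts <- vapply(seq_len(nrow(kept)), function(i) {
    fetch_seq(genome, gene$chrom, kept[i, 1L], kept[i, 2L], "+")
  }, character(1))
  mrna <- paste(parts, collapse = "")
  if (gene$strand == "-") mrna <- revcomp(mrna)
  delta <- (ee - es + 1L) - (introns[ov, 2L] - introns[ov, 1L] + 1L)

  g_start <- genomic_from_tx(gene, gene$cds_start)
  g_stop1 <- genomic_from_tx(gene, gene$cds_stop - 2L)  # stop codon 1st base
  cds_start_product <- product_pos(kept, gene$strand, g_start, snap = FALSE)
  canon_stop_product <- product_pos(kept, gene$strand, g_stop1, snap = TRUE)
  structure(list(gene_id = gene$gene_id, event = c(es, ee),
                 mrna_seq = mrna, kept = kept, delta = delta,
                 cds_start_product = cds_start_product,
                 canon_stop_product = canon_stop_product,
                 start_lost = is.na(cds_start_product)),
            class = "splice_product")
}

# product transcript coordinate of genomic position g; with snap = TRUE an
# excised position maps to the next kept base in transcript direction
product_pos <- function(kept, strand, g, snap = FALSE) {
  kept <- unname(kept)
  ord <- if (strand == "+") seq_len(nrow(kept)) else rev(seq_len(nrow(kept)))
  off <- 0L
  for (i in ord) {
    lo <- kept[i, 1L]; hi <- kept[i, 2L]
    w <- hi - lo + 1L
    inside <- g >= lo && g <= hi
    before <- if (strand == "+") g < lo else g > hi
    if (inside) {
      d <- if (strand == "+") g - lo else hi - g
      return(off + d + 1L)
    }
    if (before) {
      return(if (snap) off + 1L else NA_integer_)
    }
    off <- off + w
  }
  if (snap) off else NA_integer_
}

#' Classify a splice product for PTC, frameshift and NMD candidacy
#'
#' Translates the product in frame from the anchored CDS start, scanning
#' for the first stop codon (TAA/TAG/TGA, standard nuclear code). A stop
#' strictly upstream of the canonical stop's mapped position is a premature
#' termination codon (PTC); a change of excised length that is not a
#' multiple of 3 is a frameshift. A product with no stop before the
#' transcript end is flagged `nonstop` (not a PTC). PTC products are NMD
#' candidates unless an optional minimum 3'-UTR length (the faux-3'-UTR
#' model) excludes them; the default threshold of 0 keeps every PTC a
#' candidate.
#'
#' @param product A `splice_product` from [build_splice_product].
#' @param gene The corresponding [gene_model].
#' @param utr3_threshold Minimum distance (nt) from the stop to the mRNA 3'
#'   end for NMD candidacy (default 0: all PTCs are candidates).
#' @return The product with `first_stop_tx_pos` (first base of the stop
#'   codon), `is_ptc`, `is_frameshift`, `utr3_len`, `nonstop` and
#'   `nmd_candidate` filled in.
#' @export
call_ptc <- function(product, gene, utr3_threshold = 0L) {
  if (gene$ptc_excluded) {
    stop("gene ", gene$gene_id, " is excluded from PTC analysis ",
         "(CDS length not divisible by 3)")
  }
  product$is_frameshift <- (product$delta %% 3L) != 0L
  if (product$start_lost) {
    product$first_stop_tx_pos <- NA_integer_
    product$is_ptc <- FALSE
    product$nonstop <- FALSE
    product$utr3_len <- NA_integer_
    product$nmd_candidate <- FALSE
    return(product)
  }
  mrna <- product$mrna_seq
  n <- nchar(mrna)
  fp <- NA_integer_
  p <- product$cds_start_product
  while (p + 2L <= n) {
    codon <- substr(mrna, p, p + 2L)
    if (codon %in% STOP_CODONS) { fp <- p; break }
    p <- p + 3L
  }
  product$first_stop_tx_pos <- fp
  if (is.na(fp)) {
    product$nonstop <- TRUE
    product$is_ptc <- FALSE
    product$utr3_len <- 0L
    product$nmd_candidate <- FALSE
    return(product)
  }
  product$nonstop <- FALSE
  product$is_ptc <- fp < product$canon_stop_product
  product$utr3_len <- n - (fp + 2L)
  product$nmd_candidate <- product$is_ptc &&
    product$utr3_len >= utr3_threshold
  product
}

#' Protein-level consequence of a splice product
#'
#' Compares the canonical protein with the product's translation (CDS start
#' to its first stop) and reports the differing stretch with flanking
#' positions: `"no change"` for identity, an in-frame deletion as
#' `"Δn aa X-Y"`, an insertion, or a replacement
#' `"<old> -> <new> at X-Y"`; PTC/frameshift products whose tail diverges
#' are additionally marked as truncations.
#'
#' @param product A `splice_product` processed by [call_ptc].
#' @param gene The corresponding [gene_model].
#' @param genome Genome [Biostrings::DNAStringSet].
#' @return The product with a `protein_delta` string.
#' @export
protein_consequence <- function(product, gene, genome) {
  if (product$start_lost) {
    product$protein_delta <- "start_lost"
    return(product)
  }
  stop_at <- if (!is.na(product$first_stop_tx_pos)) {
    product$first_stop_tx_pos - 1L
  } else {
    nchar(product$mrna_seq)
  }
  c_cds <- substr(gene_mrna_seq(gene, genome), gene$cds_start,
                  gene$cds_stop - 3L)
  p_cds <- substr(product$mrna_seq, product$cds_start_product, stop_at)
  product$protein_delta <- cds_protein_delta(c_cds, p_cds,
                                             truncated = isTRUE(product$is_ptc))
  product
}

# codon-range consequence from the nucleotide-level CDS diff: the affected
# amino-acid stretch is the codon span covering the differing nucleotides,
# which matches how splice-site shifts are reported (the protein-level
# greedy diff can swallow a shared residue at the boundary)
cds_protein_delta <- function(c_cds, p_cds, truncated = FALSE) {
  lc <- nchar(c_cds); lp <- nchar(p_cds)
  if (lc == lp && c_cds == p_cds) return("no change")
  cs <- strsplit(c_cds, "", fixed = TRUE)[[1L]]
  ps <- strsplit(p_cds, "", fixed = TRUE)[[1L]]
  na_ <- 0L
  while (na_ < min(lc, lp) && cs[na_ + 1L] == ps[na_ + 1L]) na_ <- na_ + 1L
  nb <- 0L
  while (nb < min(lc, lp) - na_ && cs[lc - nb] == ps[lp - nb]) nb <- nb + 1L
  aa_c <- translate_cds(c_cds); aa_p <- translate_cds(p_cds)
  ca <- na_ %/% 3L + 1L
  cb_c <- min((lc - nb + 2L) %/% 3L, nchar(aa_c))
  cb_p <- min((lp - nb + 2L) %/% 3L, nchar(aa_p))
  del <- if (cb_c >= ca) substr(aa_c, ca, cb_c) else ""
  ins <- if (cb_p >= ca) substr(aa_p, ca, cb_p) else ""
  txt <- if (del == "" && ins == "") {
    "no change"
  } else if (ins == "") {
    sprintf("Δ%d aa %d-%d (%s deleted)", nchar(del), ca, cb_c, del)
  } else if (del == "") {
    sprintf("%s inserted after aa %d", ins, ca - 1L)
  } else {
    sprintf("%s -> %s at %d-%d", del, ins, ca, cb_c)
  }
  if (truncated) txt <- paste0(txt, "; truncated (PTC)")
  txt
}

translate_cds <- function(seq) {
  n3 <- (nchar(seq) %/% 3L) * 3L
  if (n3 < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n3)),
    no.init.codon = TRUE, if.fuzzy.codon = "X")))
}

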