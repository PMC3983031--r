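#' Gene models for intron-containing genes
#'
#' A `gene_model` records one gene's exon/intron structure on the genome
#' together with the CDS in transcript coordinates (1-based positions on the
#' spliced canonical mRNA). Introns are always derived as the gaps between
#' consecutive exons. Minus-strand genes keep genomic intervals as stored
#' (ascending on the genome); transcript coordinates run 3' to 5' along the
#' genome for those genes.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of genomic exon intervals
#'   (1-based inclusive), ascending and non-overlapping.
#' @param cds_start,cds_stop CDS first/last base in transcript coordinates
#'   on the spliced mRNA (`cds_stop` includes the stop codon), or `NA` if
#'   the gene is non-coding / CDS unknown.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       cds_start = NA_integer_, cds_stop = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("gene ", gene_id, ": exon end < start")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  introns <- derive_introns(exons)
  mlen <- sum(exons[, 2L] - exons[, 1L] + 1L)
  ptc_excluded <- FALSE
  if (!is.na(cds_start) && !is.na(cds_stop)) {
    if (!(cds_start < cds_stop && cds_stop <= mlen)) {
      stop("gene ", gene_id, ": CDS outside mRNA (length ", mlen, ")")
    }
    if ((cds_stop - cds_start + 1L) %% 3L != 0L) {
      warning("gene ", gene_id,
              ": CDS length not divisible by 3; excluded from PTC analysis")
      ptc_excluded <- TRUE
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, introns = introns,
         cds_start = as.integer(cds_start), cds_stop = as.integer(cds_stop),
         mrna_len = as.integer(mlen),
         is_icg = nrow(introns) > 0L,
         ptc_excluded = ptc_excluded),
    class = "gene_model")
}

derive_introns <- function(exons) {
  if (nrow(exons) < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = exons[-nrow(exons), 2L] + 1L,
        end   = exons[-1L, 1L] - 1L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s) %d exon(s), %d intron(s)%s\n",
              x$gene_id, x$chrom, min(x$exons), max(x$exons), x$strand,
              nrow(x$exons), nrow(x$introns),
              if (x$is_icg) " [ICG]" else ""))
  invisible(x)
}

gene_span <- function(gene) c(min(gene$exons), max(gene$exons))

# transcript coordinate (1-based on spliced mRNA) of a genomic position;
# NA when the position is intronic/outside
tx_from_genomic <- function(gene, gpos) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L] + 1L
    if (gpos >= ex[i, 1L] && gpos <= ex[i, 2L]) {
      d <- if (gene$strand == "+") gpos - ex[i, 1L] else ex[i, 2L] - gpos
      return(unname(off + d + 1L))
    }
    off <- off + w
  }
  NA_integer_
}

# genomic position of transcript coordinate tpos
genomic_from_tx <- function(gene, tpos) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L] + 1L
    if (tpos <= off + w) {
      d <- tpos - off - 1L
      return(unname(if (gene$strand == "+") ex[i, 1L] + d else ex[i, 2L] - d))
    }
    off <- off + w
  }
  NA_integer_
}

# spliced canonical mRNA sequence (transcript orientation)
gene_mrna_seq <- function(gene, genome) {
  parts <- vapply(seq_len(nrow(gene$exons)), function(i) {
    fetch_seq(genome, gene$chrom, gene$exons[i, 1L], gene$exons[i, 2L], "+")
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Load gene annotation from GFF3
#'
#' Parses a GFF3 file (1-based inclusive coordinates) into a list of
#' [gene_model] objects. Exon and CDS features are attached to their gene
#' through `Parent` attributes, either directly or via one mRNA feature per
#' gene (only the first transcript of a gene is used). Introns are derived
#' from exon gaps; intronless genes are retained with `is_icg = FALSE`.
#' A CDS whose length is not divisible by 3 raises a warning and flags the
#' gene as excluded from PTC analysis.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gff$type))
  ids <- as.character(gff$ID)
  parents <- gff$Parent
  parent1 <- vapply(seq_along(gff), function(i) {
    p <- parents[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))

  gene_idx <- which(typ == "gene")
  if (length(gene_idx) == 0L) stop("no gene features in ", path)
  # map any feature's parent chain up to a gene id
  mrna_parent <- setNames(parent1[typ %in% c("mrna", "transcript")],
                          ids[typ %in% c("mrna", "transcript")])
  to_gene <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% ids[gene_idx]) return(p)
    if (p %in% names(mrna_parent)) return(unname(mrna_parent[[p]]))
    NA_character_
  }

  genes <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    child <- which(vapply(parent1, to_gene, character(1)) == gid)
    ex <- child[typ[child] == "exon"]
    cds <- child[typ[child] == "cds"]
    if (length(ex) == 0L) ex <- gi  # single-exon gene w/o exon rows
    exm <- cbind(GenomicRanges::start(gff)[ex], GenomicRanges::end(gff)[ex])
    strand <- as.character(GenomicRanges::strand(gff)[gi])
    if (!strand %in% c("+", "-")) strand <- "+"
    chrom <- as.character(GenomicRanges::seqnames(gff)[gi])
    cs <- NA_integer_; ce <- NA_integer_
    gm_tmp <- gene_model(gid, chrom, strand, exm)
    if (length(cds) > 0L) {
      cstart <- min(GenomicRanges::start(gff)[cds])
      cend <- max(GenomicRanges::end(gff)[cds])
      # genomic CDS extremes -> transcript coordinates
      if (strand == "+") {
        cs <- tx_from_genomic(gm_tmp, cstart); ce <- tx_from_genomic(gm_tmp, cend)
      } else {
        cs <- tx_from_genomic(gm_tmp, cend); ce <- tx_from_genomic(gm_tmp, cstart)
      }
      if (is.na(cs) || is.na(ce)) {
        stop("gene ", gid, ": CDS boundary not exonic")
      }
    }
    genes[[gid]] <- gene_model(gid, chrom, strand, exm, cs, ce)
  }
  genes
}

#' Write gene models to GFF3
#'
#' @param genes Named list of [gene_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    span <- gene_span(g)
    lines <- c(lines, paste(g$chrom, "cryptosplice", "gene", span[1L], span[2L],
                            ".", g$strand, ".", paste0("ID=", g$gene_id),
                            sep = "\t"))
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines, paste(g$chrom, "cryptosplice", "mRNA", span[1L], span[2L],
                            ".", g$strand, ".",
                            paste0("ID=", mid, ";Parent=", g$gene_id),
                            sep = "\t"))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, paste(g$chrom, "cryptosplice", "exon",
                              g$exons[i, 1L], g$exons[i, 2L],
                              ".", g$strand, ".", paste0("Parent=", mid),
                              sep = "\t"))
    }
    if (!is.na(g$cds_start)) {
      # transcript-coordinate CDS -> genomic intervals clipped to exons
      gs <- genomic_from_tx(g, g$cds_start)
      ge <- genomic_from_tx(g, g$cds_stop)
      lo <- min(gs, ge); hi <- max(gs, ge)
      for (i in seq_len(nrow(g$exons))) {
        s <- max(g$exons[i, 1L], lo); e <- min(g$exons[i, 2L], hi)
        if (s <= e) {
          lines <- c(lines, paste(g$chrom, "cryptosplice", "CDS", s, e,
                                  ".", g$strand, "0", paste0("Parent=", mid),
                                  sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
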