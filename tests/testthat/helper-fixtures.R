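# Hand-built fixtures: a two-exon gene assembled from explicit exon/intron
# strings, with the genome it lives on, for targeted splice-product tests.

make_two_exon_gene <- function(exon1, intron, exon2, strand = "+",
                               cds_start = 1L,
                               cds_stop = NULL,
                               gene_id = "TOY1", pad = 50L) {
  pre <- paste0(exon1, intron, exon2)
  if (is.null(cds_stop)) cds_stop <- nchar(exon1) + nchar(exon2)
  lead <- strrep("C", pad)
  trail <- strrep("G", pad)
  fwd <- if (strand == "+") pre else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
  genome <- Biostrings::DNAStringSet(paste0(lead, fwd, trail))
  names(genome) <- "chrT"
  gs <- pad + 1L
  ge <- pad + nchar(pre)
  e1 <- nchar(exon1); e2 <- nchar(exon2)
  if (strand == "+") {
    exons <- rbind(c(gs, gs + e1 - 1L), c(ge - e2 + 1L, ge))
  } else {
    exons <- rbind(c(gs, gs + e2 - 1L), c(ge - e1 + 1L, ge))
  }
  gene <- gene_model(gene_id, "chrT", strand, exons, cds_start, cds_stop)
  list(gene = gene, genome = genome,
       intron_start = gene$introns[1L, 1L], intron_end = gene$introns[1L, 2L])
}

# junction row in the shape classify_events/annotate_ptc produce
junction_row <- function(chrom, strand, intron_start, intron_end,
                         gene_id = NA_character_, status = "alternative") {
  data.frame(chrom = chrom, strand = strand,
             intron_start = as.integer(intron_start),
             intron_end = as.integer(intron_end),
             gene_id = gene_id, status = status,
             stringsAsFactors = FALSE)
}

codons <- function(...) paste0(...)
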