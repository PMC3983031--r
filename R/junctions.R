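#' Collapse gapped alignments into junction events
#'
#' Each distinct `(chrom, intron_start, intron_end)` gap among the gapped
#' alignments becomes one junction event; supporting reads are counted per
#' sample, with multi-mapping reads (`n_best > 1`) tallied separately in
#' `ambig_*` columns. Junction strand is left unassigned here (reads are
#' unstranded); [classify_events] inherits it from the containing gene.
#'
#' @param alignments Alignment data.frame (see [alignment-table]) carrying
#'   `sample` labels.
#' @param min_support Minimum total supporting reads for an event to be
#'   kept (default 1).
#' @return Junction data.frame: `chrom`, `strand` (NA), `intron_start`,
#'   `intron_end`, per-sample `count_<sample>` and `ambig_<sample>`
#'   columns.
#' @export
extract_junctions <- function(alignments, min_support = 1L) {
  gapped <- alignments[!is.na(alignments$b2_start), , drop = FALSE]
  samples <- sort(unique(alignments$sample))
  if (nrow(gapped) == 0L) {
    out <- data.frame(chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0("count_", s)]] <- integer()
      out[[paste0("ambig_", s)]] <- integer()
    }
    return(out)
  }
  istart <- gapped$b1_end + 1L
  iend <- gapped$b2_start - 1L
  key <- paste(gapped$chrom, istart, iend, sep = ":")
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  out <- data.frame(chrom = gapped$chrom[first], strand = NA_character_,
                    intron_start = istart[first], intron_end = iend[first],
                    stringsAsFactors = FALSE)
  for (s in samples) {
    in_s <- gapped$sample == s
    out[[paste0("count_", s)]] <-
      as.integer(tabulate(idx[in_s], nbins = length(uk)))
    out[[paste0("ambig_", s)]] <-
      as.integer(tabulate(idx[in_s & gapped$n_best > 1L], nbins = length(uk)))
  }
  cnt <- rowSums(out[, paste0("count_", samples), drop = FALSE])
  out <- out[cnt >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$intron_start, out$intron_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign junctions to genes and classify annotated vs alternative
#'
#' A junction is assigned to a gene when its intron interval lies entirely
#' within the gene's transcript span; its strand is inherited from that
#' gene. An exact match to an annotated intron is `annotated`; any other
#' junction inside an intron-containing gene is `alternative`; junctions
#' inside intronless genes or outside every gene are `outside_icg` and are
#' excluded from event statistics. Junctions contained in more than one
#' gene are assigned to each (one row per gene) and flagged `multi_gene`.
#' The classification is idempotent and independent of input order.
#'
#' @param junctions Junction data.frame from [extract_junctions].
#' @param genes Named list of [gene_model] objects.
#' @return The junction table with `gene_id`, `strand`, `status` and
#'   `multi_gene` columns filled in.
#' @export
classify_events <- function(junctions, genes) {
  n <- nrow(junctions)
  spans <- do.call(rbind, lapply(genes, function(g) {
    sp <- gene_span(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = sp[1L],
               end = sp[2L], stringsAsFactors = FALSE)
  }))
  if (n == 0L) {
    junctions$gene_id <- character(0)
    junctions$status <- character(0)
    junctions$multi_gene <- logical(0)
    return(junctions)
  }
  jr <- GenomicRanges::GRanges(junctions$chrom,
                               IRanges::IRanges(junctions$intron_start,
                                                junctions$intron_end))
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  ov <- GenomicRanges::findOverlaps(jr, gr, type = "within")
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  n_genes_per_j <- tabulate(qh, nbins = n)

  rows <- vector("list", n)
  for (j in seq_len(n)) {
    hits <- sh[qh == j]
    if (length(hits) == 0L) {
      r <- junctions[j, , drop = FALSE]
      r$gene_id <- NA_character_
      r$status <- "outside_icg"
      r$multi_gene <- FALSE
      rows[[j]] <- r
      next
    }
    sub <- lapply(hits, function(h) {
      g <- genes[[spans$gene_id[h]]]
      r <- junctions[j, , drop = FALSE]
      r$gene_id <- g$gene_id
      r$strand <- g$strand
      r$multi_gene <- length(hits) > 1L
      if (!g$is_icg) {
        r$status <- "outside_icg"
      } else if (any(g$introns[, 1L] == r$intron_start &
                     g$introns[, 2L] == r$intron_end)) {
        r$status <- "annotated"
      } else {
        r$status <- "alternative"
      }
      r
    })
    rows[[j]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Donor and acceptor sequences of junctions
#'
#' Extracts, in transcript orientation (reverse-complemented for
#' minus-strand junctions), the donor sequence (first `donor_len` intronic
#' nt, default 6, covering the GUAUGU consensus) and the acceptor window
#' (last `acceptor_len` intronic nt, default 8: polypyrimidine context plus
#' the terminal YAG). Introns shorter than `donor_len + acceptor_len` get
#' truncated windows and a `short_intron` flag.
#'
#' @param junctions Classified junction data.frame (strand filled in;
#'   unstranded junctions are read on the plus strand).
#' @param genome Genome [Biostrings::DNAStringSet].
#' @param donor_len,acceptor_len Window widths (nt).
#' @return The junction table with `donor_seq`, `acceptor_window` and
#'   `short_intron` columns.
#' @export
site_sequences <- function(junctions, genome, donor_len = 6L,
                           acceptor_len = 8L) {
  n <- nrow(junctions)
  donor <- character(n); acceptor <- character(n); short <- logical(n)
  for (j in seq_len(n)) {
    chrom <- junctions$chrom[j]
    s <- junctions$intron_start[j]; e <- junctions$intron_end[j]
    strand <- junctions$strand[j]
    if (is.na(strand)) strand <- "+"
    ilen <- e - s + 1L
    dl <- min(donor_len, ilen); al <- min(acceptor_len, ilen)
    short[j] <- ilen < donor_len + acceptor_len
    if (strand == "+") {
      donor[j] <- fetch_seq(genome, chrom, s, s + dl - 1L, "+")
      acceptor[j] <- fetch_seq(genome, chrom, e - al + 1L, e, "+")
    } else {
      donor[j] <- fetch_seq(genome, chrom, e - dl + 1L, e, "-")
      acceptor[j] <- fetch_seq(genome, chrom, s, s + al - 1L, "-")
    }
  }
  junctions$donor_seq <- donor
  junctions$acceptor_window <- acceptor
  junctions$short_intron <- short
  junctions
}

#' Overlap of event sets across strains
#'
#' Tabulates, for k strains, how many events fall in each of the
#' `2^k - 1` non-empty membership regions (the counts behind a Venn
#' diagram), keying events by `(chrom, strand, intron_start, intron_end)`.
#'
#' @param event_sets Named list of junction data.frames (or character
#'   vectors of pre-built event keys), one per strain.
#' @return data.frame with one row per non-empty membership region:
#'   one logical column per strain plus `n_events`.
#' @export
strain_overlap <- function(event_sets) {
  keys <- lapply(event_sets, function(x) {
    if (is.character(x)) return(unique(x))
    unique(paste(x$chrom, ifelse(is.na(x$strand), ".", x$strand),
                 x$intron_start, x$intron_end, sep = ":"))
  })
  strains <- names(keys)
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = length(strains),
                   dimnames = list(NULL, strains))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(strains)))
  names(combos) <- strains
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  combos$n_events <- apply(combos, 1L, function(cm) {
    sum(apply(member, 1L, function(m) all(m == as.logical(cm[strains]))))
  })
  rownames(combos) <- NULL
  combos
}
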