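#' Per-gene intronic (unspliced) read counts
#'
#' A read counts once towards a gene's unspliced signal when any of its
#' aligned blocks overlaps an intron of that gene by at least one
#' nucleotide — reads fully inside introns and reads crossing exon-intron
#' boundaries alike. Gapped (junction-spanning) reads whose gap exactly
#' equals an annotated intron of the gene are spliced transcripts and never
#' count.
#'
#' @param alignments Alignment data.frame (see [alignment-table]).
#' @param genes Named list of [gene_model] objects.
#' @return data.frame with `gene_id`, `sample` and `intronic_count`, one
#'   row per intron-containing gene and sample.
#' @export
intronic_unspliced_counts <- function(alignments, genes) {
  icgs <- Filter(function(g) g$is_icg, genes)
  samples <- sort(unique(alignments$sample))
  out <- expand.grid(gene_id = names(icgs), sample = samples,
                     stringsAsFactors = FALSE)
  out$intronic_count <- 0L
  if (nrow(alignments) == 0L || length(icgs) == 0L) return(out)
  gapped <- !is.na(alignments$b2_start)
  gap_s <- alignments$b1_end + 1L
  gap_e <- alignments$b2_start - 1L
  for (g in icgs) {
    on_chr <- alignments$chrom == g$chrom
    hit <- rep(FALSE, nrow(alignments))
    for (i in seq_len(nrow(g$introns))) {
      is_ <- g$introns[i, 1L]; ie_ <- g$introns[i, 2L]
      hit <- hit | (on_chr & alignments$b1_start <= ie_ &
                      alignments$b1_end >= is_)
      hit <- hit | (on_chr & gapped &
                      !is.na(alignments$b2_start) &
                      alignments$b2_start <= ie_ & alignments$b2_end >= is_)
    }
    spliced <- rep(FALSE, nrow(alignments))
    for (i in seq_len(nrow(g$introns))) {
      spliced <- spliced | (on_chr & gapped &
                              gap_s == g$introns[i, 1L] &
                              gap_e == g$introns[i, 2L])
    }
    hit <- hit & !spliced
    if (any(hit)) {
      tab <- table(alignments$sample[hit])
      m <- match(names(tab), out$sample)
      sel <- out$gene_id == g$gene_id & out$sample %in% names(tab)
      out$intronic_count[sel] <-
        as.integer(tab[out$sample[sel]])
    }
  }
  out
}

#' Depth-normalise per-sample counts
#'
#' Scales every sample's counts by `reference_total / sample_total` so that
#' all samples are expressed at the sequencing depth of the reference (the
#' first sample by default). Raw counts are preserved alongside. Scaling
#' preserves within-sample count ratios exactly.
#'
#' @param counts data.frame with a `sample` column and one or more numeric
#'   count columns.
#' @param totals Named vector of total mapped reads per sample.
#' @param reference Reference sample (default: first name in `totals`).
#' @param cols Count columns to normalise (default: all numeric columns).
#' @return `counts` with an added `norm_<col>` column per count column.
#' @export
depth_normalize <- function(counts, totals, reference = names(totals)[1L],
                            cols = NULL) {
  if (any(totals <= 0)) stop("total_mapped must be > 0 for every sample")
  if (is.null(cols)) {
    cols <- names(counts)[vapply(counts, is.numeric, logical(1))]
  }
  scale <- totals[[reference]] / totals[counts$sample]
  for (cl in cols) {
    counts[[paste0("norm_", cl)]] <- counts[[cl]] * as.numeric(scale)
  }
  counts
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`: the probability of observing a count
#' at least as large as `k` if the mutant count were drawn from the
#' wild-type's Poisson distribution. `k = 0` gives 1; `lam = 0` gives 0 for
#' any `k > 0`.
#'
#' @param lam Expected count (>= 0), typically the depth-scaled wild-type
#'   count.
#' @param k Observed count (integer >= 0).
#' @return Probability in `[0, 1]`; vectorised over `lam`/`k`.
#' @export
poisson_upper_p <- function(lam, k) {
  if (any(lam < 0) || any(k < 0)) stop("lam and k must be non-negative")
  if (any(k != floor(k))) stop("k must be integer")
  ifelse(k == 0L, 1, ppois(k - 1, lam, lower.tail = FALSE))
}

#' Fold enrichment vs wild type with Poisson p-values
#'
#' Depth-normalises per-unit counts (genes, events or categories) of each
#' mutant against the designated wild-type sample and reports per-unit and
#' aggregate fold enrichments `mutant / WT` with upper-tail Poisson
#' p-values, taking the depth-scaled wild-type count as the Poisson mean.
#' A wild-type zero count receives a pseudocount (default 0.5) so folds and
#' p-values stay defined; set `pseudocount = 0` to disable, in which case
#' the fold is reported as `NA` when WT is zero.
#'
#' @param counts data.frame with `unit_id`, `sample` and `count` columns.
#'   With `unique_events = TRUE` the counts are expected to already be
#'   unique-event indicators (0/1) or event tallies.
#' @param totals Named vector of total mapped reads per sample.
#' @param wt Name of the wild-type sample.
#' @param pseudocount Pseudocount for wild-type zeros (default 0.5).
#' @return List with `per_unit` (one row per unit x mutant: `wt_norm`,
#'   `mut_norm`, `fold`, `pvalue`) and `aggregate` (one row per mutant with
#'   summed counts, fold and p-value).
#' @export
enrichment_table <- function(counts, totals, wt, pseudocount = 0.5) {
  stopifnot(wt %in% counts$sample, wt %in% names(totals))
  samples <- setdiff(unique(counts$sample), wt)
  units <- unique(counts$unit_id)
  get_cnt <- function(u, s) {
    v <- counts$count[counts$unit_id == u & counts$sample == s]
    if (length(v) == 0L) 0 else sum(v)
  }
  per <- list(); agg <- list()
  for (s in samples) {
    scale <- totals[[wt]] / totals[[s]]
    wt_raw <- vapply(units, get_cnt, numeric(1), s = wt)
    mut_raw <- vapply(units, get_cnt, numeric(1), s = s)
    mut_norm <- mut_raw * scale
    lam <- ifelse(wt_raw == 0 & pseudocount > 0, pseudocount, wt_raw)
    fold <- ifelse(wt_raw == 0 & pseudocount == 0, NA_real_,
                   mut_norm / ifelse(wt_raw == 0, pseudocount, wt_raw))
    pv <- poisson_upper_p(lam, round(mut_norm))
    per[[s]] <- data.frame(unit_id = units, mutant = s,
                           wt_norm = wt_raw, mut_norm = mut_norm,
                           fold = fold, pvalue = pv,
                           stringsAsFactors = FALSE)
    wt_tot <- sum(wt_raw); mut_tot <- sum(mut_raw) * scale
    agg_fold <- if (wt_tot == 0 && pseudocount == 0) NA_real_
                else mut_tot / max(wt_tot, if (wt_tot == 0) pseudocount else wt_tot)
    agg[[s]] <- data.frame(
      mutant = s, wt_total = wt_tot, mut_total_norm = mut_tot,
      fold = agg_fold,
      pvalue = poisson_upper_p(if (wt_tot == 0) pseudocount else wt_tot,
                               round(mut_tot)),
      stringsAsFactors = FALSE)
  }
  list(per_unit = do.call(rbind, per), aggregate = do.call(rbind, agg))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / ((feature_length/1000) * (total_mapped/1e6))`.
#'
#' @param count Read count (vectorised).
#' @param feature_length_nt Feature length in nt (> 0).
#' @param total_mapped Total mapped reads (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length_nt, total_mapped) {
  if (any(feature_length_nt <= 0)) stop("feature_length_nt must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count / ((feature_length_nt / 1000) * (total_mapped / 1e6))
}

#' Abundance distribution of genes with and without alternative events
#'
#' Bins gene RPKM values into a histogram whose final bin is a catch-all
#' above `cap` (default 2300 RPKM), separately for genes with and without
#' detected alternative splicing, and reports each group's median
#' abundance.
#'
#' @param genes_rpkm data.frame with `gene_id`, `rpkm` and logical
#'   `has_alt_event` columns.
#' @param cap Catch-all threshold for the final bin (default 2300).
#' @param binwidth Histogram bin width in RPKM (default 100).
#' @return List with `bins` (data.frame: `bin_lo`, `bin_hi`, `n_alt`,
#'   `n_noalt`; the last bin is `[cap, Inf)`) and `medians` (named vector,
#'   `NA` for an empty group).
#' @export
abundance_stratification <- function(genes_rpkm, cap = 2300, binwidth = 100) {
  breaks <- c(seq(0, cap, by = binwidth), Inf)
  capped <- pmin(genes_rpkm$rpkm, cap)
  bin <- findInterval(capped, breaks, rightmost.closed = FALSE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  alt <- genes_rpkm$has_alt_event
  bins <- data.frame(
    bin_lo = breaks[seq_len(nb)], bin_hi = breaks[-1L],
    n_alt = tabulate(bin[alt], nbins = nb),
    n_noalt = tabulate(bin[!alt], nbins = nb))
  med <- function(x) if (length(x) == 0L) NA_real_ else median(x)
  list(bins = bins,
       medians = c(alt = med(genes_rpkm$rpkm[alt]),
                   no_alt = med(genes_rpkm$rpkm[!alt])))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Optional multiple-testing correction for enrichment p-values (raw
#' p-values are reported by default).
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(pvalues) stats::p.adjust(pvalues, method = "BH")
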