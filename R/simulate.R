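#' Simulation configuration
#'
#' Bundles every tunable of the toy-genome builder and read simulator. The
#' defaults describe the study conditions emulated throughout the package:
#' 75-nt single-end reads from intron-containing genes (ICGs) in an
#' NMD-competent wild type and NMD-deficient (upf-delta) genotypes, where
#' each NMD-target isoform (PTC-bearing splice products and, by default,
#' unspliced pre-mRNA) survives in the NMD-competent genotype with
#' probability `nmd_retention` and is fully restored when NMD is inactive.
#'
#' @param n_genes Number of intron-containing genes (each with one intron).
#' @param exon_len_range,intron_len_range Integer ranges (nt) for exon and
#'   intron lengths. Exons are kept at least as long as the read so a read
#'   crosses at most one junction.
#' @param utr5_len,utr3_len 5'/3' UTR lengths on the canonical mRNA
#'   (`utr3_len` is adjusted by at most 2 nt so the CDS length is a
#'   multiple of 3).
#' @param n_alt_per_gene Alternative events planted per gene (default 1);
#'   ignored when `alt_event_spec` is given.
#' @param alt_event_spec Optional list (one entry per gene) of event lists;
#'   each event is `list(kind, offset, motif)` with `kind` in
#'   `"alt5"`/`"alt3"`/`"both"`. For `"alt5"`, positive offsets move the
#'   donor into the intron (intronic retention), negative offsets into
#'   exon 1 (exon truncation; `offset <= -6` so the planted 6-mer stays
#'   exonic). For `"alt3"`, negative offsets move the acceptor into the
#'   intron, positive into exon 2 (`offset >= 3`). `"both"` takes
#'   `offset = c(offset5, offset3)` and `motif = c(motif5, motif3)`.
#' @param alt_donor_motifs,alt_acceptor_motifs Pools of degenerate motifs
#'   used by the default event generator (6-mers / 3-mers).
#' @param p_unspliced,p_alt_total Pre-decay proportion of unspliced
#'   pre-mRNA and total pre-decay proportion shared equally by a gene's
#'   alternative isoforms; the canonical isoform takes the remainder.
#' @param nmd_retention Retention factor r in (0, 1]: fraction of each
#'   NMD-target isoform surviving in the NMD-competent genotype.
#' @param unspliced_is_target Are unspliced isoforms NMD targets
#'   (default TRUE)?
#' @param expression_meanlog,expression_sdlog Log-normal parameters for
#'   per-gene transcript abundance.
#' @param read_len Read length in nt (75).
#' @param error_rate Per-base substitution probability.
#' @param library_size Reads per genotype.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L,
                       exon_len_range = c(120L, 400L),
                       intron_len_range = c(80L, 400L),
                       utr5_len = 20L, utr3_len = 60L,
                       n_alt_per_gene = 1L,
                       alt_event_spec = NULL,
                       alt_donor_motifs = c("GTTTGT", "GTACGT", "GCATGT",
                                            "GTAAGT", "GTATGA"),
                       alt_acceptor_motifs = c("AAG", "CAG", "GAG", "TAG"),
                       p_unspliced = 0.2, p_alt_total = 0.1,
                       nmd_retention = 0.5,
                       unspliced_is_target = TRUE,
                       expression_meanlog = log(50), expression_sdlog = 1,
                       read_len = 75L,
                       error_rate = 0.001,
                       library_size = 20000L,
                       seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              utr5_len = as.integer(utr5_len),
              utr3_len = as.integer(utr3_len),
              n_alt_per_gene = as.integer(n_alt_per_gene),
              alt_event_spec = alt_event_spec,
              alt_donor_motifs = alt_donor_motifs,
              alt_acceptor_motifs = alt_acceptor_motifs,
              p_unspliced = p_unspliced, p_alt_total = p_alt_total,
              nmd_retention = nmd_retention,
              unspliced_is_target = unspliced_is_target,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              read_len = as.integer(read_len),
              error_rate = error_rate,
              library_size = as.integer(library_size),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$read_len >= 20L,
            cfg$exon_len_range[1L] >= cfg$read_len,
            cfg$intron_len_range[1L] >= 50L,
            cfg$library_size >= 0L)
  if (!(cfg$nmd_retention > 0 && cfg$nmd_retention <= 1)) {
    stop("nmd_retention must be in (0, 1]")
  }
  p_c <- 1 - cfg$p_unspliced - cfg$p_alt_total
  if (p_c <= 0 || abs(p_c + cfg$p_unspliced + cfg$p_alt_total - 1) > 1e-9) {
    stop("pre-decay proportions must sum to 1 with a positive canonical share")
  }
  invisible(cfg)
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(B1 = c("T", "C", "A", "G"), B2 = c("T", "C", "A", "G"),
                    B3 = c("T", "C", "A", "G")), 1L, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

str_overwrite <- function(s, at, repl) {
  substr(s, at, at + nchar(repl) - 1L) <- repl
  s
}

# first in-frame stop (codon start, 1-based within `seq` read from pos 1);
# independent of the PTC module: uses Biostrings translation
first_stop_pos <- function(seq) {
  n3 <- (nchar(seq) %/% 3L) * 3L
  if (n3 < 3L) return(NA_integer_)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n3)), no.init.codon = TRUE))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0L) NA_integer_ else (as.integer(hit) - 1L) * 3L + 1L
}

#' Build a toy genome of intron-containing genes with planted splice sites
#'
#' Constructs one synthetic chromosome carrying `n_genes` two-exon genes
#' (both strands), each with a canonical intron (GTATGT donor, TACTAAC
#' branchpoint, polypyrimidine tract, YAG acceptor) and the configured
#' alternative splice sites planted as degenerate motifs. Intergenic
#' spacers are random sequence. The returned registry records every
#' planted event's true coordinates and its expected PTC/frameshift status,
#' computed directly from the planted sequences. Deterministic per seed.
#'
#' @param config A [sim_config].
#' @return List of class `sim_world` with elements `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (named list of [gene_model]),
#'   `registry` (data.frame of planted events), `isoforms` (per-gene
#'   isoform definitions with pre-decay proportions and NMD-target flags),
#'   `expression` (per-gene abundance weights) and `config`.
#' @export
build_toy_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, build_toy_genome_impl(config))
}

build_toy_genome_impl <- function(cfg) {
  chrom <- "chrSim"
  pieces <- character(0)
  cur <- 0L
  genes <- list()
  isoforms <- list()
  reg <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("GENE%03d", i)
    strand <- sample(c("+", "-"), 1L)
    e1 <- sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L], 1L)
    e2 <- sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L], 1L)
    ilen <- sample(cfg$intron_len_range[1L]:cfg$intron_len_range[2L], 1L)
    mlen <- e1 + e2
    utr3 <- cfg$utr3_len + (mlen - cfg$utr5_len - cfg$utr3_len) %% 3L
    cds_len <- mlen - cfg$utr5_len - utr3
    stopifnot(cds_len %% 3L == 0L, cds_len >= 30L)
    mrna <- paste0(random_dna(cfg$utr5_len),
                   "ATG",
                   paste(sample(SENSE_CODONS, cds_len / 3L - 2L,
                                replace = TRUE), collapse = ""),
                   "TAA",
                   random_dna(utr3))
    exon1s <- substr(mrna, 1L, e1)
    exon2s <- substr(mrna, e1 + 1L, mlen)
    mid_len <- ilen - 6L - 7L - 12L - 3L
    introns <- paste0("GTATGT", random_dna(mid_len), "TACTAAC",
                      paste(sample(c("C", "T"), 12L, replace = TRUE,
                                   prob = c(0.25, 0.75)), collapse = ""),
                      sample(c("TAG", "CAG"), 1L))
    events <- if (!is.null(cfg$alt_event_spec)) {
      cfg$alt_event_spec[[i]]
    } else {
      default_events(cfg, ilen)
    }
    planted <- plant_events(cfg, gid, events, exon1s, introns, exon2s)
    exon1s <- planted$exon1s; introns <- planted$intron; exon2s <- planted$exon2s
    events <- planted$events

    # canonical ORF must survive any exonic planting
    mrna <- paste0(exon1s, exon2s)
    cds_start <- cfg$utr5_len + 1L
    cds_stop <- cds_start + cds_len - 1L
    fs <- first_stop_pos(substr(mrna, cds_start, nchar(mrna)))
    if (is.na(fs) || fs != cds_len - 2L) {
      stop("config error: planted event disrupts the canonical ORF of ", gid)
    }

    spacer <- sample(200:400, 1L)
    pre <- paste0(exon1s, introns, exon2s)
    gstart <- cur + spacer + 1L
    gend <- gstart + nchar(pre) - 1L
    pieces <- c(pieces, random_dna(spacer),
                if (strand == "+") pre else revcomp(pre))
    cur <- gend
    if (strand == "+") {
      exons <- rbind(c(gstart, gstart + e1 - 1L), c(gend - e2 + 1L, gend))
    } else {
      exons <- rbind(c(gstart, gstart + e2 - 1L), c(gend - e1 + 1L, gend))
    }
    gm <- gene_model(gid, chrom, strand, exons, cds_start, cds_stop)
    genes[[gid]] <- gm

    res <- gene_isoforms(cfg, gm, events, mrna, exon1s, introns, exon2s,
                         cds_start, cds_stop)
    isoforms[[gid]] <- res$isoforms
    if (length(res$registry)) reg <- c(reg, res$registry)
  }
  pieces <- c(pieces, random_dna(sample(200:400, 1L)))
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- chrom
  registry <- if (length(reg)) do.call(rbind, reg) else NULL
  expression <- setNames(
    rlnorm(cfg$n_genes, cfg$expression_meanlog, cfg$expression_sdlog),
    names(genes))
  structure(list(genome = genome, genes = genes, registry = registry,
                 isoforms = isoforms, expression = expression,
                 config = cfg),
            class = "sim_world")
}

default_events <- function(cfg, ilen) {
  lapply(seq_len(cfg$n_alt_per_gene), function(k) {
    kind <- sample(c("alt5", "alt3"), 1L)
    if (kind == "alt5") {
      d_max <- min(30L, ilen - 16L)
      list(kind = "alt5", offset = sample(7:d_max, 1L),
           motif = sample(cfg$alt_donor_motifs, 1L))
    } else {
      list(kind = "alt3", offset = -sample(4:20, 1L),
           motif = sample(cfg$alt_acceptor_motifs, 1L))
    }
  })
}

# overwrite exon/intron strings with the planted motifs; returns updated
# strings plus events normalised to (offset5, offset3, ...) form
plant_events <- function(cfg, gid, events, exon1s, intron, exon2s) {
  ilen <- nchar(intron); e1 <- nchar(exon1s); e2 <- nchar(exon2s)
  norm <- list()
  for (ev in events) {
    kind <- ev$kind
    if (!kind %in% c("alt5", "alt3", "both")) {
      stop("config error: unknown event kind '", kind, "' in ", gid)
    }
    d5 <- 0L; d3 <- 0L; m5 <- NA_character_; m3 <- NA_character_
    if (kind %in% c("alt5", "both")) {
      d5 <- as.integer(if (kind == "both") ev$offset[1L] else ev$offset)
      m5 <- if (kind == "both") ev$motif[1L] else ev$motif
      stopifnot(nchar(m5) == 6L)
      if (d5 > 0L) {                       # donor inside the intron
        if (d5 + 6L > ilen - 25L || ilen - d5 < 10L) {
          stop("config error: alt5 offset ", d5,
               " collides with intron structure in ", gid)
        }
        intron <- str_overwrite(intron, d5 + 1L, m5)
      } else if (d5 <= -6L) {              # donor inside exon 1
        at <- e1 + d5 + 1L
        if (at < 1L) stop("config error: alt5 offset ", d5,
                          " outside exon 1 in ", gid)
        exon1s <- str_overwrite(exon1s, at, m5)
      } else {
        stop("config error: alt5 offset ", d5,
             " collides with the exon boundary in ", gid)
      }
    }
    if (kind %in% c("alt3", "both")) {
      d3 <- as.integer(if (kind == "both") ev$offset[2L] else ev$offset)
      m3 <- if (kind == "both") ev$motif[2L] else ev$motif
      stopifnot(nchar(m3) == 3L)
      if (d3 < 0L) {                       # acceptor inside the intron
        at <- ilen + d3 - 2L
        if (at <= 13L || ilen + d3 - (if (kind == "both") d5 else 0L) < 10L) {
          stop("config error: alt3 offset ", d3,
               " collides with intron structure in ", gid)
        }
        intron <- str_overwrite(intron, at, m3)
      } else if (d3 >= 3L) {               # acceptor inside exon 2
        if (d3 > e2 - 1L) stop("config error: alt3 offset ", d3,
                               " outside exon 2 in ", gid)
        exon2s <- str_overwrite(exon2s, d3 - 2L, m3)
      } else {
        stop("config error: alt3 offset ", d3,
             " collides with the exon boundary in ", gid)
      }
    }
    norm[[length(norm) + 1L]] <-
      list(kind = kind, offset5 = d5, offset3 = d3, motif5 = m5, motif3 = m3)
  }
  list(exon1s = exon1s, intron = intron, exon2s = exon2s, events = norm)
}

# isoform set (canonical, one per event, unspliced) + registry rows
gene_isoforms <- function(cfg, gm, events, mrna, exon1s, introns, exon2s,
                          cds_start, cds_stop) {
  e1 <- nchar(exon1s); ilen <- nchar(introns); e2 <- nchar(exon2s)
  is_g <- gm$introns[1L, 1L]; ie_g <- gm$introns[1L, 2L]
  span <- gene_span(gm)
  n_alt <- length(events)
  p_alt <- if (n_alt > 0L) cfg$p_alt_total / n_alt else 0
  p_c <- 1 - cfg$p_unspliced - (if (n_alt > 0L) cfg$p_alt_total else 0)

  iso <- list()
  iso[["canonical"]] <- list(
    isoform_id = "canonical", kind = "canonical", event_id = NA_character_,
    kept = gm$exons, mrna = mrna,
    junction = c(is_g, ie_g), left_len = e1,
    nmd_target = FALSE, pre_p = p_c)

  registry <- list()
  for (k in seq_along(events)) {
    ev <- events[[k]]
    eid <- paste0(gm$gene_id, ".alt", k)
    d5 <- ev$offset5; d3 <- ev$offset3
    # excised interval in pre-mRNA (transcript) coordinates
    exc_lo <- e1 + d5 + 1L
    exc_hi <- e1 + ilen + d3
    alt_mrna <- paste0(substr(paste0(exon1s, introns, exon2s), 1L, exc_lo - 1L),
                       substr(paste0(exon1s, introns, exon2s), exc_hi + 1L,
                              e1 + ilen + e2))
    delta <- (exc_hi - exc_lo + 1L) - ilen     # event minus annotated excision
    fs_rel <- first_stop_pos(substr(alt_mrna, cds_start, nchar(alt_mrna)))
    canon_stop_rel <- (cds_stop - 2L) - cds_start + 1L + (ilen - (exc_hi - exc_lo + 1L))
    is_ptc <- !is.na(fs_rel) && fs_rel < canon_stop_rel
    is_fs <- (delta %% 3L) != 0L
    # genomic alternative intron interval
    if (gm$strand == "+") {
      a_lo <- is_g + d5; a_hi <- ie_g + d3
    } else {
      a_lo <- is_g - d3; a_hi <- ie_g - d5
    }
    kept <- interval_complement(span, rbind(c(a_lo, a_hi)))
    iso[[eid]] <- list(
      isoform_id = eid, kind = "alt", event_id = eid,
      kept = kept, mrna = alt_mrna,
      junction = c(a_lo, a_hi), left_len = exc_lo - 1L,
      nmd_target = is_ptc, pre_p = p_alt)
    registry[[eid]] <- data.frame(
      gene_id = gm$gene_id, event_id = eid, kind = ev$kind,
      offset5 = d5, offset3 = d3,
      motif5 = ev$motif5, motif3 = ev$motif3,
      chrom = gm$chrom, strand = gm$strand,
      alt_intron_start = a_lo, alt_intron_end = a_hi,
      canon_intron_start = is_g, canon_intron_end = ie_g,
      delta = delta, is_frameshift = is_fs, is_ptc = is_ptc,
      nmd_target = is_ptc, stringsAsFactors = FALSE)
  }
  iso[["unspliced"]] <- list(
    isoform_id = "unspliced", kind = "unspliced", event_id = NA_character_,
    kept = rbind(span), mrna = paste0(exon1s, introns, exon2s),
    junction = NULL, left_len = NA_integer_,
    nmd_target = cfg$unspliced_is_target, pre_p = cfg$p_unspliced)
  list(isoforms = iso, registry = registry)
}

# genomic span minus the excised interval -> kept intervals (ascending)
interval_complement <- function(span, excised) {
  keep <- list()
  lo <- span[1L]
  exc <- excised[order(excised[, 1L]), , drop = FALSE]
  for (i in seq_len(nrow(exc))) {
    if (exc[i, 1L] > lo) keep[[length(keep) + 1L]] <- c(lo, exc[i, 1L] - 1L)
    lo <- exc[i, 2L] + 1L
  }
  if (lo <= span[2L]) keep[[length(keep) + 1L]] <- c(lo, span[2L])
  do.call(rbind, keep)
}

#' Post-decay isoform proportions under an NMD retention model
#'
#' In the NMD-competent genotype every NMD-target isoform's pre-decay
#' proportion is multiplied by the retention factor `r` and the vector is
#' renormalised; in an NMD-deficient genotype the pre-decay proportions are
#' returned unchanged.
#'
#' @param pre Named numeric vector of pre-decay proportions (sums to 1).
#' @param targets Logical vector: is each isoform an NMD target?
#' @param genotype `"WT"` (NMD-competent) or any other label
#'   (NMD-deficient).
#' @param retention Retention factor r in (0, 1].
#' @return Named numeric vector of post-decay proportions (sums to 1).
#' @export
isoform_abundances <- function(pre, targets, genotype, retention) {
  stopifnot(length(pre) == length(targets),
            abs(sum(pre) - 1) < 1e-9,
            retention > 0, retention <= 1)
  if (identical(genotype, "WT")) {
    post <- pre * ifelse(targets, retention, 1)
    post / sum(post)
  } else {
    pre
  }
}

sim_gene_proportions <- function(sim, gene_id, genotype,
                                 retention = sim$config$nmd_retention) {
  iso <- sim$isoforms[[gene_id]]
  pre <- vapply(iso, `[[`, numeric(1), "pre_p")
  targets <- vapply(iso, `[[`, logical(1), "nmd_target")
  isoform_abundances(pre, targets, genotype, retention)
}

# map a transcript-coordinate read interval to genomic blocks (vectorised
# over reads of one isoform); kept = ascending genomic intervals (1 or 2)
truth_blocks <- function(kept, strand, t, read_len) {
  e <- t + read_len - 1L
  n <- length(t)
  if (nrow(kept) == 1L) {
    if (strand == "+") {
      b1s <- kept[1L, 1L] + t - 1L; b1e <- kept[1L, 1L] + e - 1L
    } else {
      b1s <- kept[1L, 2L] - e + 1L; b1e <- kept[1L, 2L] - t + 1L
    }
    return(data.frame(b1_start = b1s, b1_end = b1e,
                      b2_start = NA_integer_, b2_end = NA_integer_))
  }
  # transcript order: '+' -> kept[1] then kept[2]; '-' -> kept[2] reversed
  if (strand == "+") {
    L1 <- kept[1L, 2L] - kept[1L, 1L] + 1L
    in_left <- e <= L1
    in_right <- t > L1
    b1s <- ifelse(in_left, kept[1L, 1L] + t - 1L,
           ifelse(in_right, kept[2L, 1L] + (t - L1) - 1L,
                  kept[1L, 1L] + t - 1L))
    b1e <- ifelse(in_left, kept[1L, 1L] + e - 1L,
           ifelse(in_right, kept[2L, 1L] + (e - L1) - 1L,
                  kept[1L, 2L]))
    b2s <- ifelse(in_left | in_right, NA_integer_, kept[2L, 1L])
    b2e <- ifelse(in_left | in_right, NA_integer_,
                  kept[2L, 1L] + (e - L1) - 1L)
  } else {
    L1 <- kept[2L, 2L] - kept[2L, 1L] + 1L   # transcript-first piece
    in_left <- e <= L1
    in_right <- t > L1
    # spanning reads: low-coordinate block comes from the transcript-second
    # piece (kept[1]), high-coordinate block from kept[2]
    b1s <- ifelse(in_left, kept[2L, 2L] - e + 1L,
           ifelse(in_right, kept[1L, 2L] - (e - L1) + 1L,
                  kept[1L, 2L] - (e - L1) + 1L))
    b1e <- ifelse(in_left, kept[2L, 2L] - t + 1L,
           ifelse(in_right, kept[1L, 2L] - (t - L1) + 1L,
                  kept[1L, 2L]))
    b2s <- ifelse(in_left | in_right, NA_integer_, kept[2L, 1L])
    b2e <- ifelse(in_left | in_right, NA_integer_, kept[2L, 2L] - t + 1L)
  }
  data.frame(b1_start = as.integer(b1s), b1_end = as.integer(b1e),
             b2_start = as.integer(b2s), b2_end = as.integer(b2e))
}

apply_errors <- function(seqs, n_err) {
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- sample.int(length(s), n_err[i])
    for (p in at) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate read libraries per genotype under the NMD decay model
#'
#' For every genotype: each read's gene is chosen proportionally to the
#' per-gene log-normal abundance draw, its isoform by the genotype's
#' post-decay proportions, and its start uniformly over valid positions on
#' the isoform's (pre-)mRNA. Substitution errors are i.i.d. per base. The
#' truth table gives every read's error-free genomic alignment, including
#' the gap for junction-spanning reads. Deterministic per seed.
#'
#' @param sim A `sim_world` from [build_toy_genome].
#' @param genotypes Character vector of genotype labels; `"WT"` is the
#'   NMD-competent genotype, all others are NMD-deficient.
#' @param library_size,error_rate,seed Overrides of the corresponding
#'   [sim_config] fields.
#' @return List of class `sim_reads` with `reads` (per-genotype named
#'   character vectors of read sequences), `truth` (data.frame: one row per
#'   read with gene, isoform, mRNA start and genomic blocks), and
#'   `proportions` (per gene x genotype post-decay isoform proportions).
#' @export
simulate_reads <- function(sim, genotypes = c("WT", "upf1d", "upf2d", "upf3d"),
                           library_size = sim$config$library_size,
                           error_rate = sim$config$error_rate,
                           seed = sim$config$seed) {
  if (library_size <= 0L) stop("config error: library_size must be positive")
  cfg <- sim$config
  L <- cfg$read_len
  withr::with_seed(seed + 1L, {
    reads <- list(); truth <- list(); props <- list()
    w <- sim$expression / sum(sim$expression)
    gene_ids <- names(sim$genes)
    for (gt in genotypes) {
      g_draw <- sample(gene_ids, library_size, replace = TRUE, prob = w)
      out_seq <- character(library_size)
      out_rows <- vector("list", length(gene_ids))
      ridx <- 0L
      rows_i <- 0L
      for (gid in gene_ids) {
        sel <- which(g_draw == gid)
        if (length(sel) == 0L) next
        p_post <- sim_gene_proportions(sim, gid, gt)
        props[[paste(gid, gt, sep = ".")]] <- data.frame(
          gene_id = gid, genotype = gt, isoform_id = names(p_post),
          proportion = unname(p_post), stringsAsFactors = FALSE)
        iso_draw <- sample(names(p_post), length(sel), replace = TRUE,
                           prob = p_post)
        gm <- sim$genes[[gid]]
        for (iso_id in unique(iso_draw)) {
          iso <- sim$isoforms[[gid]][[iso_id]]
          sel2 <- sel[iso_draw == iso_id]
          M <- nchar(iso$mrna)
          t <- sample.int(M - L + 1L, length(sel2), replace = TRUE)
          sseq <- substring(iso$mrna, t, t + L - 1L)
          sense <- runif(length(sel2)) < 0.5
          if (any(!sense)) {
            sseq[!sense] <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAStringSet(sseq[!sense])))
          }
          n_err <- rbinom(length(sel2), L, error_rate)
          sseq <- apply_errors(sseq, n_err)
          out_seq[sel2] <- sseq
          blk <- truth_blocks(iso$kept, gm$strand, t, L)
          rows_i <- rows_i + 1L
          out_rows[[rows_i]] <- data.frame(
            idx = sel2, gene_id = gid, isoform_id = iso_id,
            chrom = gm$chrom,
            strand = ifelse(sense, gm$strand,
                            ifelse(gm$strand == "+", "-", "+")),
            mrna_start = t, blk, n_errors = n_err,
            stringsAsFactors = FALSE)
        }
      }
      tr <- do.call(rbind, out_rows[seq_len(rows_i)])
      tr <- tr[order(tr$idx), , drop = FALSE]
      tr$read_id <- sprintf("%s_r%06d", gt, tr$idx)
      tr$sample <- gt
      tr$idx <- NULL
      rownames(tr) <- NULL
      names(out_seq) <- sprintf("%s_r%06d", gt, seq_len(library_size))
      reads[[gt]] <- out_seq
      truth[[gt]] <- tr
    }
    structure(list(reads = reads, truth = do.call(rbind, truth),
                   proportions = do.call(rbind, props), genotypes = genotypes,
                   library_size = library_size, error_rate = error_rate),
              class = "sim_reads")
  })
}

#' Truth alignments of a simulated read set
#'
#' Converts the simulator's per-read truth table into the alignment-table
#' form the junction pipeline consumes: the error-free genomic placement of
#' every read, with the `N`-gap blocks for junction-spanning reads. This is
#' the simulation's stand-in for an external spliced aligner's SAM output.
#'
#' @param simr A `sim_reads` object from [simulate_reads] (or any list with
#'   a compatible `truth` element).
#' @return Alignment data.frame (see [alignment-table]).
#' @export
truth_alignments <- function(simr) {
  tr <- simr$truth
  alignment_table(
    read_id = tr$read_id, sample = tr$sample, chrom = tr$chrom,
    strand = tr$strand, b1_start = tr$b1_start, b1_end = tr$b1_end,
    b2_start = tr$b2_start, b2_end = tr$b2_end,
    mismatches = tr$n_errors, n_best = rep(1L, nrow(tr)),
    step = ifelse(is.na(tr$b2_start), "ungapped", "gapped"))
}

#' Closed-form expected junction-read counts per planted event
#'
#' For each planted alternative event, the expected number of
#' junction-spanning reads in one genotype's library, from the decay model:
#' `library_size * P(gene) * P(isoform | genotype) * P(read spans the
#' junction | isoform)`, the last factor by exact enumeration of valid
#' start positions.
#'
#' @param sim A `sim_world`.
#' @param genotype Genotype label (`"WT"` = NMD-competent).
#' @param library_size Reads in the library.
#' @param retention Optional retention-factor override.
#' @return data.frame with one row per event: `event_id`, `gene_id`,
#'   `nmd_target`, `expected_reads`.
#' @export
expected_event_reads <- function(sim, genotype,
                                 library_size = sim$config$library_size,
                                 retention = sim$config$nmd_retention) {
  L <- sim$config$read_len
  w <- sim$expression / sum(sim$expression)
  rows <- list()
  for (gid in names(sim$genes)) {
    p_post <- sim_gene_proportions(sim, gid, genotype, retention)
    for (iso in sim$isoforms[[gid]]) {
      if (iso$kind != "alt") next
      M <- nchar(iso$mrna)
      j <- iso$left_len
      n_span <- min(j, M - L + 1L) - max(1L, j - L + 2L) + 1L
      rows[[iso$isoform_id]] <- data.frame(
        event_id = iso$isoform_id, gene_id = gid,
        nmd_target = iso$nmd_target,
        expected_reads = library_size * w[[gid]] *
          p_post[[iso$isoform_id]] * n_span / (M - L + 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Choose the retention factor giving a target closed-form enrichment
#'
#' Solves for the retention factor r at which the closed-form expected
#' depth-adjusted aggregate enrichment of NMD-target events
#' (NMD-deficient over NMD-competent, summed read support) equals
#' `target_fold`.
#'
#' @param sim A `sim_world`.
#' @param target_fold Desired aggregate fold (e.g. 1.7).
#' @return The retention factor r.
#' @export
calibrate_retention <- function(sim, target_fold = 1.7) {
  fold_at <- function(r) {
    mut <- expected_event_reads(sim, "nmd_deficient", retention = r)
    wt <- expected_event_reads(sim, "WT", retention = r)
    sum(mut$expected_reads[mut$nmd_target]) /
      sum(wt$expected_reads[wt$nmd_target])
  }
  stats::uniroot(function(r) fold_at(r) - target_fold,
                 lower = 1e-3, upper = 1, tol = 1e-10)$root
}

#' Write a simulation to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `registry.tsv` and, when reads are
#' given, per-genotype `reads_<genotype>.fastq`, `truth_<genotype>.sam` and
#' a combined `truth.tsv`.
#'
#' @param sim A `sim_world`.
#' @param simr Optional `sim_reads` from [simulate_reads].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, simr = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(outdir, "genome.fa"))
  write_annotation(sim$genes, file.path(outdir, "genes.gff3"))
  if (!is.null(sim$registry)) {
    write.table(sim$registry, file.path(outdir, "registry.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(simr)) {
    for (gt in simr$genotypes) {
      write_fastq(simr$reads[[gt]],
                  file.path(outdir, sprintf("reads_%s.fastq", gt)))
      tr <- simr$truth[simr$truth$sample == gt, , drop = FALSE]
      aln <- truth_alignments(list(truth = tr))
      write_sam(aln, file.path(outdir, sprintf("truth_%s.sam", gt)),
                sim$genome)
    }
    write.table(simr$truth, file.path(outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' Write reads to FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  names(q) <- names(x)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
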