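test_that("extract_junctions collapses gaps into counted events", {
  aln <- cryptosplice:::alignment_table(
    read_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7"),
    sample = c("s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    chrom = rep("chr1", 7),
    strand = rep("+", 7),
    b1_start = c(101L, 96L, 90L, 105L, 99L, 102L, 401L),
    b1_end = c(130L, 130L, 130L, 130L, 130L, 130L, 475L),
    b2_start = c(331L, 331L, 331L, 331L, 331L, 501L, NA),
    b2_end = c(375L, 370L, 365L, 372L, 368L, 540L, NA),
    mismatches = rep(0L, 7), n_best = c(1L, 1L, 2L, 1L, 1L, 1L, 1L),
    step = c(rep("gapped", 6), "ungapped"))
  jx <- extract_junctions(aln)
  expect_equal(nrow(jx), 2L)  # the ungapped read contributes nothing
  j1 <- jx[jx$intron_end == 330L, ]
  expect_equal(c(j1$intron_start, j1$intron_end), c(131L, 330L))
  expect_equal(c(j1$count_s1, j1$count_s2), c(3L, 2L))
  expect_equal(c(j1$ambig_s1, j1$ambig_s2), c(1L, 0L))
  # min_support drops weakly supported events
  jx2 <- extract_junctions(aln, min_support = 2L)
  expect_equal(nrow(jx2), 1L)
})

test_that("classify_events separates annotated, alternative and outside", {
  genes <- list(
    icg = gene_model("icg", "chr1", "+", rbind(c(101, 200), c(301, 400)),
                     cds_start = 10, cds_stop = 150),
    flat = gene_model("flat", "chr1", "+", rbind(c(1001, 1400))),
    micg = gene_model("micg", "chr1", "-", rbind(c(2001, 2100),
                                                 c(2301, 2400)),
                      cds_start = 10, cds_stop = 150))
  jx <- data.frame(
    chrom = "chr1", strand = NA_character_,
    intron_start = c(201L, 201L, 1101L, 5001L, 2101L, 2101L),
    intron_end = c(300L, 317L, 1200L, 5100L, 2300L, 2283L),
    stringsAsFactors = FALSE)
  out <- classify_events(jx, genes)
  expect_equal(out$status[1L], "annotated")
  # acceptor 17 nt downstream of the annotated 3'SS: alternative
  expect_equal(out$status[2L], "alternative")
  expect_equal(out$gene_id[2L], "icg")
  expect_equal(out$strand[2L], "+")
  # inside an intronless gene's span, and outside all genes
  expect_equal(out$status[3L], "outside_icg")
  expect_equal(out$status[4L], "outside_icg")
  # minus-strand gene: exact annotated intron, and an alternative
  expect_equal(out$status[5L], "annotated")
  expect_equal(out$status[6L], "alternative")
  expect_equal(out$strand[6L], "-")
  # idempotent and order-independent
  out2 <- classify_events(out[, names(jx)], genes)
  expect_equal(out2$status, out$status)
  perm <- sample(nrow(jx))
  out3 <- classify_events(jx[perm, ], genes)
  expect_equal(out3$status[order(perm)], out$status)
})

test_that("site_sequences reads donors and acceptors in transcript orientation", {
  #            1        10        20        30        40        50
  left <- "CCCCCCCCCC"
  intron <- paste0("GTATGTAAAACCCTACTAACTTTTTTTTACAAG")  # ends ...ACAAG
  right <- "GGGGGGGGGG"
  gseq <- paste0(left, intron, right)
  genome <- Biostrings::DNAStringSet(gseq); names(genome) <- "chr1"
  is_ <- 11L; ie_ <- 10L + nchar(intron)
  jx <- data.frame(chrom = "chr1", strand = "+",
                   intron_start = is_, intron_end = ie_,
                   stringsAsFactors = FALSE)
  out <- site_sequences(jx, genome)
  expect_equal(out$donor_seq, "GTATGT")
  expect_equal(out$acceptor_window, "TTTACAAG")
  expect_equal(substr(out$acceptor_window, 6, 8), "AAG")
  expect_false(out$short_intron)

  # the same intron on the minus strand: genomic reverse complement
  genome_rc <- Biostrings::DNAStringSet(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq))))
  names(genome_rc) <- "chr1"
  n <- nchar(gseq)
  jx_rc <- data.frame(chrom = "chr1", strand = "-",
                      intron_start = n - ie_ + 1L,
                      intron_end = n - is_ + 1L,
                      stringsAsFactors = FALSE)
  out_rc <- site_sequences(jx_rc, genome_rc)
  expect_equal(out_rc$donor_seq, "GTATGT")
  expect_equal(out_rc$acceptor_window, "TTTACAAG")

  # a 10-nt intron gets truncated windows and a flag
  jx_short <- data.frame(chrom = "chr1", strand = "+",
                         intron_start = 11L, intron_end = 20L,
                         stringsAsFactors = FALSE)
  out_s <- site_sequences(jx_short, genome)
  expect_true(out_s$short_intron)
  expect_equal(nchar(out_s$donor_seq), 6L)
  expect_equal(nchar(out_s$acceptor_window), 8L)
})

test_that("strain_overlap tabulates every membership region", {
  sets <- list(A = c("e1", "e2"), B = c("e2", "e3"), C = c("e3"))
  ov <- strain_overlap(sets)
  get <- function(a, b, cc) {
    ov$n_events[ov$A == a & ov$B == b & ov$C == cc]
  }
  expect_equal(get(TRUE, FALSE, FALSE), 1L)   # e1
  expect_equal(get(TRUE, TRUE, FALSE), 1L)    # e2
  expect_equal(get(FALSE, TRUE, TRUE), 1L)    # e3
  expect_equal(get(TRUE, TRUE, TRUE), 0L)
  expect_equal(sum(ov$n_events), 3L)

  # identical sets: everything in the full intersection
  ov2 <- strain_overlap(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(ov2$n_events[ov2$x & ov2$y], 2L)
  expect_equal(sum(ov2$n_events), 2L)

  # 4 random sets against brute-force membership tabulation
  withr::with_seed(31, {
    events <- paste0("ev", 1:40)
    sets4 <- lapply(setNames(1:4, paste0("s", 1:4)),
                    function(i) sample(events, 20L))
  })
  ov4 <- strain_overlap(sets4)
  all_ev <- unique(unlist(sets4))
  for (r in seq_len(nrow(ov4))) {
    expected <- sum(vapply(all_ev, function(e) {
      all(vapply(names(sets4), function(s) {
        (e %in% sets4[[s]]) == ov4[r, s]
      }, logical(1)))
    }, logical(1)))
    expect_equal(ov4$n_events[r], expected)
  }
})

test_that("simulated truth junctions are recovered with exact counts", {
  cfg <- sim_config(n_genes = 5L, seed = 41L, error_rate = 0)
  sim <- build_toy_genome(cfg)
  simr <- simulate_reads(sim, genotypes = c("WT", "upf1d"),
                         library_size = 4000L, error_rate = 0)
  aln <- cryptosplice:::truth_alignments(simr)
  jx <- classify_events(extract_junctions(aln), sim$genes)
  # every discovered junction is a planted alternative event or an
  # annotated intron; counts match the truth tally exactly
  tr <- simr$truth[!is.na(simr$truth$b2_start), ]
  truth_key <- paste(tr$chrom, tr$b1_end + 1L, tr$b2_start - 1L)
  jx_key <- paste(jx$chrom, jx$intron_start, jx$intron_end)
  expect_setequal(jx_key, unique(truth_key))
  expect_true(all(jx$status %in% c("annotated", "alternative")))
  for (i in seq_len(nrow(jx))) {
    for (s in c("WT", "upf1d")) {
      expect_equal(jx[[paste0("count_", s)]][i],
                   sum(truth_key == jx_key[i] & tr$sample == s))
    }
  }
  # planted events all discovered (every event gets reads at this depth)
  reg_key <- paste(sim$registry$chrom, sim$registry$alt_intron_start,
                   sim$registry$alt_intron_end)
  expect_true(all(reg_key %in% jx_key))
})
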