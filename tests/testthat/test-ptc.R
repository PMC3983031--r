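# Hand-built gene: cds_start = 1 (ATG first), exon 1 ends on a codon
# boundary, canonical intron carries a TAG at its 3' end so that in-frame
# retention of the last 6 intronic nt terminates translation there.
ptc_fixture <- function(strand = "+") {
  exon1 <- paste0("ATG", "GCTGAAGTTCCAGACGCTGAAGTTCCAGAC",
                  "GCTGAAGTTCCAGACGCTGAAGTTCCAGAC")       # 63 nt, 21 codons
  intron <- paste0("GTATGT", strrep("CA", 10), "TACTAAC",
                   "TTTTCTTTCTT", "CATTAG")                # 50 nt, ends CATTAG
  # exon 2 opens CTAAATGAC: stop-free in frame 0, but both shifted frames
  # hit an early stop (TAA at 2-4, TGA at 6-8); the 3' UTR (TAAA repeats)
  # carries stops in every frame
  exon2 <- paste0("CTAAATGAC", "GGTCACGAAATCTTGGGTCACGAAATCTTGGGTCAC",
                  "TAA", "TAAATAAATAAATAAATA")               # 66 nt
  make_two_exon_gene(exon1, intron, exon2, strand = strand,
                     cds_start = 1L, cds_stop = 111L)
}

event_for <- function(fx, d5 = 0L, d3 = 0L) {
  g <- fx$gene
  if (g$strand == "+") {
    junction_row(g$chrom, g$strand, fx$intron_start + d5,
                 fx$intron_end + d3, g$gene_id)
  } else {
    junction_row(g$chrom, g$strand, fx$intron_start - d3,
                 fx$intron_end - d5, g$gene_id)
  }
}

classify_event <- function(fx, d5 = 0L, d3 = 0L, ...) {
  ev <- event_for(fx, d5, d3)
  p <- build_splice_product(fx$gene, ev, fx$genome)
  p <- call_ptc(p, fx$gene, ...)
  protein_consequence(p, fx$gene, fx$genome)
}

test_that("the identity event reproduces the canonical mRNA", {
  for (strand in c("+", "-")) {
    fx <- ptc_fixture(strand)
    p <- classify_event(fx)
    expect_equal(p$mrna_seq,
                 cryptosplice:::gene_mrna_seq(fx$gene, fx$genome))
    expect_false(p$is_ptc)
    expect_false(p$is_frameshift)
    expect_equal(p$protein_delta, "no change")
    # canonical stop, canonical 3' UTR
    expect_equal(p$first_stop_tx_pos, 109L)
    expect_equal(p$utr3_len, 18L)
  }
})

test_that("6-nt in-frame intronic retention ending in TAG is a PTC", {
  for (strand in c("+", "-")) {
    fx <- ptc_fixture(strand)
    # acceptor 6 nt upstream of the annotated 3'SS: retains ...CATTAG
    p <- classify_event(fx, d3 = -6L)
    expect_true(p$is_ptc)
    expect_false(p$is_frameshift)
    expect_true(p$nmd_candidate)
    # translation stops exactly at the retained TAG (after exon1's 63 nt
    # plus the retained CAT codon)
    expect_equal(p$first_stop_tx_pos, 67L)
  }
})

test_that("7-nt retention causes a frameshift-induced PTC", {
  fx <- ptc_fixture("+")
  p <- classify_event(fx, d3 = -7L)
  expect_true(p$is_frameshift)
  expect_true(p$is_ptc)
  expect_true(grepl("truncated", p$protein_delta))
})

test_that("in-frame exonic deletion changes protein without a PTC", {
  fx <- ptc_fixture("+")
  # donor 30 nt upstream of the annotated 5'SS: removes 10 codons from
  # the 3' end of exon 1, reading frame maintained
  p <- classify_event(fx, d5 = -30L)
  expect_false(p$is_ptc)
  expect_false(p$is_frameshift)
  expect_equal(p$delta, 30L)
  expect_match(p$protein_delta, "^Δ10 aa 12-21")
})

test_that("intronic retention of 3n nt without a stop extends the protein", {
  fx <- ptc_fixture("+")
  # donor 9 nt downstream keeps GTATGTCAC (GTA TGT CAC, no in-frame stop)
  p <- classify_event(fx, d5 = 9L)
  expect_false(p$is_frameshift)
  # retained GTATGTCAC contains no in-frame stop (GTA TGT CAC)
  expect_false(p$is_ptc)
  expect_match(p$protein_delta, "inserted")
})

test_that("start-lost and nonstop products are flagged, not misclassified", {
  fx <- ptc_fixture("+")
  g <- fx$gene
  # excision swallowing the start codon
  ev <- junction_row(g$chrom, g$strand, cryptosplice:::gene_span(g)[1L],
                     fx$intron_end, g$gene_id)
  p <- call_ptc(build_splice_product(g, ev, fx$genome), g)
  expect_true(p$start_lost)
  expect_false(p$is_ptc)

  # excision through the stop codon and most of the 3' end: no stop left
  ev2 <- junction_row(g$chrom, g$strand, fx$intron_start + 40L,
                      cryptosplice:::gene_span(g)[2L] - 3L, g$gene_id)
  p2 <- call_ptc(build_splice_product(g, ev2, fx$genome), g)
  expect_true(p2$nonstop)
  expect_false(p2$is_ptc)
})

test_that("events overlapping zero or two annotated introns are refused", {
  g2 <- gene_model("g2", "chr1", "+",
                   rbind(c(1, 100), c(201, 300), c(401, 500)),
                   cds_start = 1, cds_stop = 300)
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 200)))
  expect_error(build_splice_product(
    g2, junction_row("chr1", "+", 150, 450), genome), "2 annotated")
  expect_error(build_splice_product(
    g2, junction_row("chr1", "+", 20, 90), genome), "0 annotated")
})

test_that("protein consequences are reported by affected codon span", {
  pd <- cryptosplice:::cds_protein_delta
  # replacement spanning codons 2-4 (MVCTREST vs MQTSVDSTREST)
  expect_equal(pd("ATGGTCTGTACCCGTGAAAGCACC",
                  "ATGCAAACCTCTGTCGATTCTACGCGTGAAAGCACC"),
               "VCT -> QTSVDST at 2-4")
  expect_equal(pd("ATGCCTAAAGGGTCC", "ATGCCTAAAGGGTCC"), "no change")
  # MPKGS with codons 3-4 removed
  expect_equal(pd("ATGCCTAAAGGGTCC", "ATGCCTTCC"),
               "Δ2 aa 3-4 (KG deleted)")
  expect_equal(pd("ATGCCTTCC", "ATGCCTAAAGGGTCC"),
               "KG inserted after aa 2")
  # frameshifted tail is a truncation
  expect_match(pd("ATGCCTAAAGGGTCCGAA", "ATGCCTAAAGG", truncated = TRUE),
               "truncated \\(PTC\\)$")
})

test_that("PTC calls agree with the translation oracle on planted events", {
  # oracle route: the simulator registry computes is_ptc/is_frameshift by
  # splicing the pre-mRNA string and translating with Biostrings; the
  # module route reconstructs the product from genome coordinates and
  # scans codons itself
  cfg <- sim_config(n_genes = 40L, n_alt_per_gene = 2L, seed = 61L)
  sim <- build_toy_genome(cfg)
  reg <- sim$registry
  expect_gte(nrow(reg), 60L)
  for (i in seq_len(nrow(reg))) {
    g <- sim$genes[[reg$gene_id[i]]]
    ev <- junction_row(reg$chrom[i], reg$strand[i],
                       reg$alt_intron_start[i], reg$alt_intron_end[i],
                       reg$gene_id[i])
    p <- call_ptc(build_splice_product(g, ev, sim$genome), g)
    expect_equal(p$is_ptc, reg$is_ptc[i],
                 label = paste("is_ptc for", reg$event_id[i]))
    expect_equal(p$is_frameshift, reg$is_frameshift[i],
                 label = paste("is_frameshift for", reg$event_id[i]))
    # frame arithmetic: frameshift iff excision-length change mod 3 != 0
    expect_equal(p$is_frameshift, (reg$delta[i] %% 3L) != 0L)
    # the product mRNA matches direct string splicing of the pre-mRNA
    iso <- sim$isoforms[[reg$gene_id[i]]][[reg$event_id[i]]]
    expect_equal(p$mrna_seq, iso$mrna)
  }
})

test_that("first-stop scanning follows the geometric stop law on random sequence", {
  withr::with_seed(1234, seqs <- vapply(1:400, function(i) random_seq(300L),
                                        character(1)))
  fake_gene <- list(gene_id = "rand", ptc_excluded = FALSE)
  k <- 10L   # codons scanned
  p_hit <- 1 - (61 / 64)^k
  hits <- vapply(seqs, function(s) {
    prod <- structure(list(delta = 1L, start_lost = FALSE, mrna_seq = s,
                           cds_start_product = 1L,
                           canon_stop_product = 10000L),
                      class = "splice_product")
    p <- call_ptc(prod, fake_gene)
    !is.na(p$first_stop_tx_pos) && p$first_stop_tx_pos <= (k - 1L) * 3L + 1L
  }, logical(1), USE.NAMES = FALSE)
  expect_lt(abs(sum(hits) - 400 * p_hit),
            3 * sqrt(400 * p_hit * (1 - p_hit)))
})
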