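make_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chr1"
  g
}

test_that("ungapped scan finds exact, mutated and repeated placements", {
  withr::with_seed(11, g <- random_seq(8000))
  genome <- make_genome(g)
  r <- substr(g, 501, 575)
  a <- align_ungapped(r, genome)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$b1_start, a$b1_end, a$mismatches), c(501L, 575L, 0L))
  expect_equal(a$strand, "+")

  # reverse strand
  rc <- cryptosplice:::revcomp(r)
  arc <- align_ungapped(rc, genome)
  expect_equal(c(arc$b1_start, arc$strand), c("501", "-"))

  # a read planted identically at 3 loci returns all 3 best locations
  seg <- substr(g, 1001, 1075)
  g3 <- paste0(g, strrep("T", 20), seg, strrep("A", 20), seg)
  a3 <- align_ungapped(seg, make_genome(g3))
  expect_equal(nrow(a3), 3L)
  expect_true(all(a3$n_best == 3L))

  # five mutations exceed the ceiling
  withr::with_seed(12, r5 <- mutate_read(r, 5L))
  expect_equal(nrow(align_ungapped(r5, genome)), 0L)
  expect_equal(nrow(align_ungapped(r5, genome, max_mismatch = 5L)), 1L)

  expect_error(align_ungapped("ACGTX", genome), "non-ACGTN|shorter")
})

test_that("a junction-spanning read fails the ungapped step", {
  withr::with_seed(13, g <- random_seq(6000))
  genome <- make_genome(g)
  read <- paste0(substr(g, 2001, 2040), substr(g, 2241, 2275))
  # brute-force check that no contiguous placement reaches <= 4 mismatches
  best <- min(vapply(seq_len(nchar(g) - 74L), function(p) {
    sum(strsplit(substr(g, p, p + 74L), "")[[1L]] !=
          strsplit(read, "")[[1L]])
  }, numeric(1)))
  expect_gt(best, 4)
  expect_equal(nrow(align_ungapped(read, genome)), 0L)
})

test_that("gapped scan recovers junctions and honours the gap floor", {
  withr::with_seed(14, g <- random_seq(6000))
  genome <- make_genome(g)
  # 40 + 35 over a 200-nt gap; a repeated base at the junction boundary can
  # add one score-tied shifted placement, but the truth placement is found
  read <- paste0(substr(g, 1001, 1040), substr(g, 1241, 1275))
  a <- align_gapped(read, genome)
  expect_true(any(a$b1_start == 1001L & a$b1_end == 1040L &
                    a$b2_start == 1241L & a$b2_end == 1275L))
  expect_true(all(a$mismatches == 0L))
  expect_lte(nrow(a), 2L)

  # the same geometry with a 5-nt gap is never produced
  read5 <- paste0(substr(g, 3001, 3040), substr(g, 3046, 3080))
  expect_equal(nrow(align_gapped(read5, genome)), 0L)

  # minimum anchor: an 8-nt overhang cannot seed a gapped alignment
  read8 <- paste0(substr(g, 4001, 4067), substr(g, 4301, 4308))
  a8 <- align_gapped(read8, genome)
  expect_true(nrow(a8) == 0L ||
                all(a8$b2_end - a8$b2_start + 1L >= 12L))
})

test_that("gapped scan equals the enumeration oracle on random reads", {
  withr::with_seed(15, {
    g <- random_seq(5000)
    genome <- make_genome(g)
    for (i in 1:30) {
      kind <- sample(c("ungapped", "gapped", "random"), 1L,
                     prob = c(0.4, 0.4, 0.2))
      if (kind == "ungapped") {
        p <- sample.int(4900, 1L)
        read <- mutate_read(substr(g, p, p + 74L), sample(0:4, 1L))
      } else if (kind == "gapped") {
        p <- sample.int(3000, 1L)
        s <- sample(12:63, 1L)
        gap <- sample(c(3:20, 100, 500), 1L)
        read <- paste0(substr(g, p, p + s - 1L),
                       substr(g, p + s + gap, p + s + gap + (74L - s)))
        read <- mutate_read(read, sample(0:3, 1L))
      } else {
        read <- random_seq(75L)
      }
      imp <- align_gapped(read, genome)
      ora <- oracle_gapped(read, genome)
      if (is.null(ora)) {
        expect_equal(nrow(imp), 0L)
      } else {
        imp$step <- NULL
        expect_equal(
          sort_aln(cbind(imp[, names(ora)], step = "g")),
          sort_aln(cbind(ora, step = "g")),
          ignore_attr = TRUE)
      }
    }
  })
})

test_that("map_library applies step precedence and the location filter", {
  withr::with_seed(16, g <- random_seq(6000))
  seg <- substr(g, 101, 175)
  gdup <- paste0(g, strrep("C", 15), seg)            # 2 copies
  gtri <- paste0(gdup, strrep("T", 15), seg)          # 3 copies
  junc <- paste0(substr(g, 2001, 2040), substr(g, 2301, 2335))
  reads <- setNames(c(seg, junc), c("dup", "junc"))

  res2 <- map_library(reads, make_genome(gdup), sample = "s")
  expect_equal(sum(res2$alignments$read_id == "dup"), 2L)
  expect_true(all(res2$alignments$n_best[res2$alignments$read_id == "dup"] == 2L))
  junc_rows <- res2$alignments[res2$alignments$read_id == "junc", ]
  expect_gte(nrow(junc_rows), 1L)
  expect_true(all(junc_rows$step == "gapped"))
  expect_true(any(junc_rows$b1_start == 2001L & junc_rows$b2_start == 2301L))

  # 3 equal-best placements -> discarded, and never retried gapped
  res3 <- map_library(reads, make_genome(gtri), sample = "s")
  expect_equal(sum(res3$alignments$read_id == "dup"), 0L)
  expect_equal(unname(res3$report["step1_multi_rejected"]), 1L)

  # no read appears in both steps
  both <- tapply(res2$alignments$step, res2$alignments$read_id,
                 function(s) length(unique(s)))
  expect_true(all(both == 1L))

  # empty library: zero report, no error
  res0 <- map_library(character(0), make_genome(g))
  expect_equal(nrow(res0$alignments), 0L)
  expect_equal(unname(res0$report["n_reads"]), 0L)
})

test_that("raising the mismatch ceiling never loses accepted reads", {
  withr::with_seed(17, {
    g <- random_seq(4000)
    genome <- make_genome(g)
    reads <- vapply(1:25, function(i) {
      p <- sample.int(3900, 1L)
      mutate_read(substr(g, p, p + 74L), sample(0:6, 1L))
    }, character(1))
  })
  accepted <- vapply(0:5, function(mm) {
    res <- map_library(reads, genome, max_mismatch_ungapped = mm)
    sum(res$report[c("step1_accepted", "step2_accepted")])
  }, numeric(1))
  expect_true(all(diff(accepted) >= 0))
})

test_that("an error-free simulated library maps back to its truth positions", {
  cfg <- sim_config(n_genes = 4L, seed = 19L, error_rate = 0)
  sim <- build_toy_genome(cfg)
  simr <- simulate_reads(sim, genotypes = "WT", library_size = 150L,
                         error_rate = 0)
  tr <- simr$truth
  # reads the two-step policy can anchor: contiguous, or >= 12 nt per side
  ok <- is.na(tr$b2_start) |
    (tr$b1_end - tr$b1_start + 1L >= 12L &
       tr$b2_end - tr$b2_start + 1L >= 12L)
  res <- map_library(simr$reads$WT[tr$read_id[ok]], sim$genome,
                     sample = "WT")
  aln <- res$alignments
  expect_equal(unname(res$report["unaligned"]), 0L)
  expect_equal(aln$mismatches, rep(0L, nrow(aln)))
  # every placed read has its truth placement among its equal-best
  # locations (junction reads can carry a second, score-tied placement
  # when the boundary base repeats)
  for (rid in unique(aln$read_id)) {
    rows <- aln[aln$read_id == rid, ]
    t <- tr[tr$read_id == rid, ]
    hit <- any(rows$b1_start == t$b1_start & rows$b1_end == t$b1_end &
                 ((is.na(rows$b2_start) & is.na(t$b2_start)) |
                    (!is.na(rows$b2_start) & !is.na(t$b2_start) &
                       rows$b2_start == t$b2_start &
                       rows$b2_end == t$b2_end)))
    expect_true(hit, label = paste("truth placement recovered for", rid))
  }
  # accounting: placed + location-filtered = all anchorable reads
  placed <- length(unique(aln$read_id))
  expect_equal(placed + unname(res$report["step1_multi_rejected"]) +
                 unname(res$report["step2_multi_rejected"]),
               sum(ok))
})
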