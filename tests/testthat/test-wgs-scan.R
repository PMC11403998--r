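# Short-read NUMT caller: breakpoints, clip matching, the filter cascade
# and insertion-contig assembly.

make_wgs_fixture <- function(genotypes = c(s = "hom_ins"), age = 0.2,
                             mt_start = 2000L, mt_end = 2300L,
                             depth = 25, seed = 51, error_rate = 0,
                             genome_length = 40000L, pos = 15000L) {
  ins <- insertion_spec("x", "chr1", pos, mt_start, mt_end, age = age,
                        genotypes = genotypes)
  samples <- data.frame(sample = names(genotypes), species = "scrofa")
  pl <- fixture_planted(list(ins), genome_length = genome_length,
                        seed = seed, samples = samples)
  reads <- lapply(names(genotypes), function(s) {
    simulate_reads(pl$genomes[[s]], pl$reference$scrofa,
                   truth = pl$truth[pl$truth$sample == s, ],
                   depth = depth, read_len = 100L, error_rate = error_rate,
                   seed = seed + match(s, names(genotypes)), sample_id = s)
  })
  names(reads) <- names(genotypes)
  list(planted = pl, reads = reads,
       mt = pl$mt$tips[["scrofa"]], bp_truth = pos)
}

test_that("a homozygous insertion produces left+right breakpoints at the
           truth position and a clean genome produces none", {
  fx <- make_wgs_fixture()
  bp <- detect_breakpoints(fx$reads$s, sample_id = "s")
  expect_equal(nrow(bp), 2L)
  expect_setequal(bp$side, c("left", "right"))
  expect_true(all(abs(bp$pos - fx$bp_truth) <= 1))
  clean <- fixture_planted(list(), genome_length = 20000L, seed = 55,
                           samples = data.frame(sample = "s",
                                                species = "scrofa"))
  rd <- simulate_reads(clean$genomes$s, clean$reference$scrofa,
                       depth = 20, error_rate = 0, seed = 56,
                       sample_id = "s")
  expect_equal(nrow(detect_breakpoints(rd, sample_id = "s")), 0L)
})

test_that("fewer than three supporting clips do not make a breakpoint", {
  sam <- data.frame(
    qname = paste0("r", 1:2), flag = 0L, rname = "chr1",
    pos = c(100L, 100L), mapq = 60L, cigar = c("20S80M", "30S70M"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = strrep("A", 100), qual = strrep("I", 100))
  bp <- detect_breakpoints(sam, sq = data.frame(name = "chr1",
                                                length = 10000L))
  expect_equal(nrow(bp), 0L)
  expect_error(detect_breakpoints(sam), "@SQ")
})

test_that("clip matching recovers the planted mtDNA interval and rejects
           random clips and identity at exactly the threshold", {
  fx <- make_wgs_fixture()
  recs <- numtatlas:::.prep_records(fx$reads$s$sam)
  bp <- detect_breakpoints(fx$reads$s, sample_id = "s")
  left <- bp[bp$side == "left", ]
  mc <- match_clips(left, recs, fx$mt)
  expect_gt(sum(mc$matches$pass), 0)
  expect_equal(nrow(mc$mt_intervals), 1L)
  # the left-side clips carry the *end* of the inserted segment
  expect_lte(abs(mc$mt_intervals$mt_end - 2300L), 2)
  expect_equal(nchar(mc$sequence),
               mc$mt_intervals$mt_end - mc$mt_intervals$mt_start)
  # a random 40-mer clip has no credible mtDNA match
  set.seed(57)
  rnd <- numtatlas:::.match_clip_set(random_dna(40), "r", circularize(fx$mt),
                                     nchar(fx$mt), scoring_scheme(),
                                     0.75, 1e-4)
  expect_false(any(rnd$pass))
  # identity exactly 0.75 fails the strict "higher than 75%" rule
  expect_false(0.75 > 0.75)
  fake <- data.frame(identity = 0.75, e_value = 1e-9)
  expect_false(with(fake, identity > 0.75 & e_value < 1e-4))
})

test_that("the depth filter applies MD = d + 4*sqrt(d) with inclusive
           bounds", {
  bp <- data.frame(contig = "chr1", pos = 500L)
  d <- 16
  expect_equal(d + 4 * sqrt(d), 32)
  expect_false(depth_filter(bp, rep(33L, 1000L), d))   # above MD
  expect_false(depth_filter(bp, rep(5L, 1000L), d))    # below six
  expect_true(depth_filter(bp, rep(6L, 1000L), d))     # inclusive low
  expect_true(depth_filter(bp, rep(32L, 1000L), d))    # inclusive high
  expect_error(depth_filter(bp, rep(10L, 1000L), 0))
})

test_that("breakpoints group across samples at the 100-bp boundary", {
  bps <- data.frame(contig = "chr1", pos = c(1000L, 1100L),
                    side = "left", n_clip_reads = 5L,
                    sample_id = c("s1", "s2"))
  expect_equal(nrow(group_loci(bps)), 1L)
  bps$pos <- c(1000L, 1101L)
  expect_equal(nrow(group_loci(bps)), 2L)
  solo <- group_loci(bps[1, ])
  expect_equal(solo$n_datasets, 1L)
})

test_that("R1 and R2 equal direct brute-force counts on the SAM slice and
           genotypes follow the R2 thresholds", {
  fx <- make_wgs_fixture(genotypes = c(s = "het"), depth = 30, seed = 61)
  recs <- numtatlas:::.prep_records(fx$reads$s$sam)
  bp <- detect_breakpoints(fx$reads$s, sample_id = "s")
  loci <- group_loci(bp)
  g <- genotype_locus(loci[1, ], attr(loci, "breakpoints"), recs, fx$mt)
  for (r in seq_len(nrow(g))) {
    at <- if (g$side[r] == "left") recs$start0 else recs$end0
    clen <- if (g$side[r] == "left") recs$clip_left else recs$clip_right
    eligible <- at == g$pos[r] & clen >= 7L
    expect_equal(g$n_clip_eligible[r], sum(eligible))
    overlapping <- recs$start0 <= g$pos[r] & recs$end0 >= g$pos[r]
    expect_equal(g$n_overlap[r], sum(overlapping))
    clipped <- (recs$start0 == g$pos[r] & recs$clip_left > 0) |
      (recs$end0 == g$pos[r] & recs$clip_right > 0)
    expect_equal(g$n_clipped[r], sum(clipped))
    expect_equal(g$R1[r], g$n_clip_matched[r] / sum(eligible))
    expect_equal(g$R2[r], sum(clipped) / sum(overlapping))
  }
  # threshold semantics: R2 = 0.80 exactly is heterozygous (hom needs > 0.80)
  fake_locus <- data.frame(locus_id = "l", contig = "chr1", pos = 100L)
  mk_geno <- function(r2) {
    if (r2 > 0.80) "hom_ins" else if (r2 >= 0.30) "het" else "absent"
  }
  expect_equal(mk_geno(0.80), "het")
  expect_equal(mk_geno(0.81), "hom_ins")
  expect_equal(mk_geno(0.30), "het")
  expect_equal(mk_geno(0.29), "absent")
})

test_that("hom/het/absent genotypes are recovered from read data", {
  fx <- make_wgs_fixture(genotypes = c(s1 = "hom_ins", s2 = "het",
                                       s3 = "absent"),
                         depth = 30, seed = 63)
  all_bp <- NULL
  recs <- list()
  for (s in c("s1", "s2", "s3")) {
    recs[[s]] <- numtatlas:::.prep_records(fx$reads[[s]]$sam)
    all_bp <- rbind(all_bp, detect_breakpoints(fx$reads[[s]],
                                               sample_id = s))
  }
  loci <- group_loci(all_bp)
  expect_equal(nrow(loci), 1L)
  bps <- attr(loci, "breakpoints")
  calls <- vapply(c("s1", "s2", "s3"), function(s) {
    g <- genotype_locus(loci[1, ],
                        bps[bps$sample_id == s, , drop = FALSE],
                        recs[[s]], fx$mt, sample_id = s)
    g$genotype[1]
  }, character(1))
  expect_equal(unname(calls), c("hom_ins", "het", "absent"))
})

test_that("novelty is decided against known regions with 100-bp slop", {
  regions <- data.frame(region_id = "r1", contig = "chr1",
                        start = 5000L, end = 6000L)
  expect_false(classify_novel(data.frame(contig = "chr1", pos = 5500L),
                              regions))
  expect_false(classify_novel(data.frame(contig = "chr1", pos = 6050L),
                              regions))       # within slop
  expect_true(classify_novel(data.frame(contig = "chr1", pos = 6200L),
                             regions))
  expect_true(classify_novel(data.frame(contig = "chr2", pos = 5500L),
                             regions))
})

test_that("error-free reads tiling an insertion assemble into the exact
           truth contig; disjoint loci assemble separately; a single read
           is fragmentary", {
  set.seed(65)
  truth_seq <- random_dna(300)
  starts <- seq(1, 201, by = 20)
  reads <- vapply(starts, function(s) substr(truth_seq, s, s + 99),
                  character(1))
  asm <- assemble_insertion(reads)
  expect_equal(asm$contig_seq[1], truth_seq)
  expect_false(asm$fragmentary[1])
  other <- random_dna(200)
  reads2 <- c(reads, substr(other, 1, 100), substr(other, 60, 160),
              substr(other, 101, 200))
  asm2 <- assemble_insertion(reads2)
  expect_equal(nrow(asm2), 2L)
  single <- assemble_insertion(reads[1])
  expect_true(single$fragmentary[1])
  expect_equal(single$contig_seq[1], reads[1])
  expect_error(assemble_insertion(character(0)))
})

test_that("assembled contigs annotate back to their mtDNA source
           interval", {
  spec <- fixture_tree()
  mt <- simulate_mtdna_set(spec, seed = 66)$tips[["scrofa"]]
  seg <- substr(mt, 4001, 4300)
  reads <- vapply(seq(1, 201, by = 25), function(s) substr(seg, s, s + 99),
                  character(1))
  asm <- assemble_insertion(reads, mt = mt)
  expect_equal(asm$mt_start[1], 4000L)
  expect_equal(asm$mt_end[1], 4300L)
  expect_equal(asm$mt_identity[1], 1)
})

test_that("the finalisation cascade rejects for each designed reason and
           keeps the designed survivors", {
  loci <- data.frame(
    locus_id = paste0("L", 1:6), contig = "chr1",
    pos = c(1000L, 5000L, 9000L, 13000L, 17000L, 21000L),
    n_breakpoints = 2L, n_datasets = c(2L, 2L, 2L, 2L, 1L, 2L),
    samples = "s1,s2", novel = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    length = c(200L, 200L, 200L, 25L, 200L, 200L))
  geno <- function(lid, sample, r1, r2, pool = FALSE,
                   carrier = r2 >= 0.3) {
    data.frame(locus_id = lid, contig = "chr1", pos = 0L, side = "left",
               sample_id = sample, n_clip_eligible = 10L,
               n_clip_matched = round(r1 * 10), n_clipped = round(r2 * 10),
               n_overlap = 10L, R1 = r1, R2 = r2,
               genotype = if (r2 > 0.8) "hom_ins" else if (r2 >= 0.3)
                 "het" else "absent",
               carrier = carrier, is_pool = pool)
  }
  genos <- rbind(
    geno("L1", "s1", 0.9, 0.5), geno("L1", "s2", 0.8, 0.6),  # survivor
    geno("L2", "s1", 0.5, 0.5), geno("L2", "s2", 0.6, 0.6),  # all R1 < .75
    geno("L3", "s1", 0.9, 0.1), geno("L3", "s2", 0.9, 0.2),  # all R2 < .30
    geno("L4", "s1", 0.9, 0.5), geno("L4", "s2", 0.9, 0.5),  # too short
    geno("L5", "s1", 0.9, 0.5),                              # one dataset
    geno("L6", "s1", 0.9, 0.5), geno("L6", "s2", 0.9, 0.5))  # known
  out <- finalize_novel(loci, genos)
  expect_equal(out$locus_id, "L1")
  reasons <- attr(out, "reject_reasons")
  expect_equal(reasons$reason,
               c("pass", "R1", "R2", "length", "datasets", "known"))
  # the R2 rejection is waived for pool-only loci
  pool_loci <- loci[3, , drop = FALSE]
  pool_genos <- rbind(geno("L3", "p1", 0.9, 0.1, pool = TRUE,
                           carrier = TRUE),
                      geno("L3", "p2", 0.9, 0.1, pool = TRUE,
                           carrier = TRUE))
  kept <- finalize_novel(pool_loci, pool_genos)
  expect_equal(kept$locus_id, "L3")
  expect_equal(kept$region_id, "chr1_REGION_1")
})

test_that("no accepted novel locus overlaps a known region", {
  regions <- data.frame(region_id = "r1", contig = "chr1",
                        start = 900L, end = 1500L)
  loci <- data.frame(locus_id = c("L1", "L2"), contig = "chr1",
                     pos = c(1000L, 8000L), n_breakpoints = 2L,
                     n_datasets = 2L, samples = "s1,s2",
                     novel = NA, length = 200L)
  loci$novel <- vapply(seq_len(nrow(loci)), function(i) {
    classify_novel(loci[i, ], regions)
  }, logical(1))
  genos <- rbind(
    data.frame(locus_id = c("L1", "L1", "L2", "L2"), contig = "chr1",
               pos = 0L, side = "left", sample_id = c("s1", "s2"),
               n_clip_eligible = 10L, n_clip_matched = 9L, n_clipped = 5L,
               n_overlap = 10L, R1 = 0.9, R2 = 0.5, genotype = "het",
               carrier = TRUE, is_pool = FALSE))
  out <- finalize_novel(loci, genos, regions)
  expect_equal(out$locus_id, "L2")
})
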