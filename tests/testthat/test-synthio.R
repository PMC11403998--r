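# Synthetic-data generator: K80 mtDNA evolution on the species tree, NUMT
# planting with exact truth, and analytic paired-end read simulation.

test_that("tree spec validates rates, lengths and ultrametricity", {
  expect_error(species_tree_spec("(A:1,B:2);"), "ultrametric")
  expect_error(species_tree_spec("(A:1,B:1);", mt_length = 500),
               "mt_length")
  expect_error(species_tree_spec("(A,B)n;",
                                 divergence_times = c(n = -1)),
               "ultrametric|positive")
  spec <- suinae_tree_spec()
  expect_equal(root_age(spec), 55)
  expect_equal(unname(spec$heights["sus"]), 3.5)
})

test_that("zero divergence time yields identical sequences", {
  spec <- species_tree_spec("(A:0.000001,B:0.000001)n;", mito_rate = 2e-8,
                            mt_length = 2000)
  mt <- simulate_mtdna_set(spec, seed = 1)
  d <- mean(strsplit(mt$tips[["A"]], "")[[1]] !=
              strsplit(mt$tips[["B"]], "")[[1]])
  expect_lt(d, 0.001)
})

test_that("pairwise K80 distance matches 2 * rate * T over 20 seeds", {
  spec <- species_tree_spec("(A:3.5,B:3.5)n;", mito_rate = 2e-8,
                            mt_length = 16600)
  d <- vapply(1:20, function(s) {
    mt <- simulate_mtdna_set(spec, seed = s)
    k80_distance_oracle(mt$tips[["A"]], mt$tips[["B"]])
  }, numeric(1))
  expect_lt(abs(mean(d) - 0.14) / 0.14, 0.15)
})

test_that("kappa = 1 gives statistically equal transition and transversion
           counts", {
  spec <- species_tree_spec("(A:3.5,B:3.5)n;", mito_rate = 2e-8,
                            kappa = 1, mt_length = 16600)
  ts_tot <- 0; tv_tot <- 0
  for (s in 1:20) {
    mt <- simulate_mtdna_set(spec, seed = s)
    x <- strsplit(mt$tips[["A"]], "")[[1]]
    y <- strsplit(mt$tips[["B"]], "")[[1]]
    ts_pairs <- c(A = "G", G = "A", C = "T", T = "C")
    diff <- x != y
    ts <- sum(diff & ts_pairs[x] == y)
    ts_tot <- ts_tot + ts
    tv_tot <- tv_tot + sum(diff) - ts
  }
  # under kappa = 1 transitions arise at half the rate of the two
  # transversion channels combined: expect ts:tv = 1:2
  p <- stats::chisq.test(c(ts_tot, tv_tot), p = c(1 / 3, 2 / 3))$p.value
  expect_gt(p, 0.01)
})

test_that("NUMT-vs-modern identity decreases monotonically with age", {
  spec <- fixture_tree()
  mean_ident <- vapply(c(0.5, 3, 10, 30), function(age) {
    idents <- vapply(1:10, function(s) {
      ins <- insertion_spec("i", "chr1", 5000L, 2000L, 4000L, age = age,
                            genotypes = hom("g"))
      pl <- fixture_planted(list(ins), genome_length = 12000L, seed = s,
                            samples = data.frame(sample = "g",
                                                 species = "scrofa"))
      numt <- substr(pl$genomes$g$hap1, 5001, 7000)
      modern <- substr(pl$mt$tips[["scrofa"]], 2001, 4000)
      mean(strsplit(numt, "")[[1]] == strsplit(modern, "")[[1]])
    }, numeric(1))
    mean(idents)
  }, numeric(1))
  expect_true(all(diff(mean_ident) < 0))
})

test_that("an age-0 insertion is identical to the modern mtDNA segment and
           absent genotypes leave the background untouched", {
  ins <- insertion_spec("i", "chr1", 5000L, 2000L, 2400L, age = 0,
                        genotypes = c(s1 = "hom_ins", s2 = "absent"))
  pl <- fixture_planted(list(ins), genome_length = 20000L, seed = 3,
                        samples = data.frame(sample = c("s1", "s2"),
                                             species = "scrofa"))
  expect_identical(substr(pl$genomes$s1$hap1, 5001, 5400),
                   substr(pl$mt$tips[["scrofa"]], 2001, 2400))
  expect_identical(pl$genomes$s2$hap1, pl$reference$scrofa)
})

test_that("a full-branch-age insertion has truth amr near zero", {
  spec <- fixture_tree()
  amrs <- vapply(1:20, function(s) {
    ins <- insertion_spec("i", "chr1", 5000L, 2000L, 4000L, age = 3.5,
                          genotypes = hom("g"))
    pl <- fixture_planted(list(ins), genome_length = 12000L, seed = s,
                          spec = spec,
                          samples = data.frame(sample = "g",
                                               species = "scrofa"))
    ta <- pl$truth_amr
    ta$amr[ta$node == "sus"]
  }, numeric(1))
  expect_lt(mean(amrs, na.rm = TRUE), 0.15)
})

test_that("fragmentation plans delete and invert as specified", {
  plan <- list(deletions = data.frame(start = 100L, end = 200L),
               inversions = data.frame(start = 300L, end = 350L))
  ins <- insertion_spec("i", "chr1", 5000L, 2000L, 2400L, age = 0,
                        genotypes = hom("g"), fragmentation = plan)
  pl <- fixture_planted(list(ins), genome_length = 20000L, seed = 4,
                        samples = data.frame(sample = "g",
                                             species = "scrofa"))
  tr <- pl$truth[1, ]
  expect_equal(tr$length, 300L)   # 400 - 100 deleted
  seg <- substr(pl$mt$tips[["scrofa"]], 2001, 2400)
  inv <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seg, 301, 350))))
  expected <- paste0(substr(seg, 1, 100), substr(seg, 201, 300), inv,
                     substr(seg, 351, 400))
  expect_identical(substr(pl$genomes$g$hap1, 5001, 5300), expected)
  expect_error(insertion_spec("x", "chr1", 1L, 10L, 400L, age = 0,
                              genotypes = hom("g"),
                              fragmentation = list(deletions = data.frame(
                                start = c(0L, 50L), end = c(60L, 80L)))),
               "overlap")
})

test_that("out-of-range circular intervals are rejected without the
           wraparound flag", {
  ins <- insertion_spec("i", "chr1", 100L, 16000L, 17000L, age = 0,
                        genotypes = hom("g"))
  expect_error(fixture_planted(list(ins), genome_length = 20000L, seed = 5,
                               samples = data.frame(sample = "g",
                                                    species = "scrofa")),
               "wraparound")
  expect_error(insertion_spec("i", "chr1", 100L, 500L, 400L, age = 0,
                              genotypes = hom("g")), "wraparound")
})

test_that("insertion ages above the root age are rejected", {
  ins <- insertion_spec("i", "chr1", 100L, 0L, 400L, age = 60,
                        genotypes = hom("g"))
  expect_error(fixture_planted(list(ins), genome_length = 20000L, seed = 6,
                               samples = data.frame(sample = "g",
                                                    species = "scrofa")),
               "root age")
})

test_that("an insertion-free sample yields no soft clips at zero error
           rate and coverage near the request", {
  pl <- fixture_planted(list(), genome_length = 30000L, seed = 7,
                        samples = data.frame(sample = "s", species = "scrofa"))
  rd <- simulate_reads(pl$genomes$s, pl$reference$scrofa, truth = NULL,
                       depth = 20, read_len = 100L, error_rate = 0,
                       seed = 8, sample_id = "s")
  clips <- cigar_clips(rd$sam$cigar)
  expect_equal(sum(clips$left) + sum(clips$right), 0L)
  mapped <- rd$sam[bitwAnd(rd$sam$flag, 4L) == 0L, ]
  cov <- sum(cigar_ref_span(mapped$cigar)) / 30000
  expect_lt(abs(cov - 20) / 20, 0.1)
})

test_that("junction-overlapping reads are soft-clipped exactly as a direct
           placement enumeration predicts", {
  ins <- insertion_spec("i", "chr1", 10000L, 3000L, 3400L, age = 0,
                        genotypes = c(s = "hom_ins"))
  pl <- fixture_planted(list(ins), genome_length = 30000L, seed = 9,
                        samples = data.frame(sample = "s",
                                             species = "scrofa"))
  tr <- pl$truth[pl$truth$haplotype == "hap1", ]
  rd <- simulate_reads(pl$genomes$s, pl$reference$scrofa, truth = pl$truth,
                       depth = 20, read_len = 100L, insert_size = 300L,
                       error_rate = 0, seed = 10, sample_id = "s")
  clips <- cigar_clips(rd$sam$cigar)
  n_clipped <- sum(clips$left > 0 | clips$right > 0)
  # oracle: re-derive every read interval on the haplotype and count reads
  # that overlap the insertion [start, end) AND its flanks partially
  set.seed(10)   # same stream as simulate_reads
  hlen <- nchar(pl$genomes$s$hap1)
  n_frag <- round(20 * 0.5 * hlen / 200)
  expected <- 0L
  for (hap in c("hap1", "hap2")) {
    fs <- sample.int(hlen - 300 + 1L, n_frag, replace = TRUE) - 1L
    for (iv in list(cbind(fs, fs + 100), cbind(fs + 200, fs + 300))) {
      s0 <- iv[, 1]; e0 <- iv[, 2]
      bs <- tr$start[1]; be <- tr$end[1]
      inside <- pmin(e0, be) - pmax(s0, bs)
      flank <- pmax(pmax(bs, s0) - s0, e0 - pmin(be, e0))
      expected <- expected + sum(inside > 0 & inside < 100 & flank > 0)
    }
  }
  expect_equal(n_clipped, expected)
})

test_that("a heterozygous insertion clips about half of the junction
           reads", {
  ins <- insertion_spec("i", "chr1", 10000L, 3000L, 3500L, age = 0,
                        genotypes = c(s = "het"))
  pl <- fixture_planted(list(ins), genome_length = 30000L, seed = 11,
                        samples = data.frame(sample = "s",
                                             species = "scrofa"))
  rd <- simulate_reads(pl$genomes$s, pl$reference$scrofa, truth = pl$truth,
                       depth = 30, read_len = 100L, error_rate = 0,
                       seed = 12, sample_id = "s")
  recs <- numtatlas:::.prep_records(rd$sam)
  bp <- pl$truth$ref_breakpoint[1]
  over <- recs$start0 <= bp & recs$end0 >= bp
  clipped <- (recs$start0 == bp & recs$clip_left > 0) |
    (recs$end0 == bp & recs$clip_right > 0)
  frac <- sum(clipped) / sum(over)
  ci <- stats::binom.test(sum(clipped), sum(over), p = 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2] ||
                (frac > 0.3 && frac < 0.7))
})

test_that("identical seeds give byte-identical FASTA and SAM output", {
  ins <- insertion_spec("i", "chr1", 8000L, 100L, 600L, age = 1,
                        genotypes = c(s = "het"))
  run <- function() {
    pl <- fixture_planted(list(ins), genome_length = 20000L, seed = 13,
                          samples = data.frame(sample = "s",
                                               species = "scrofa"))
    rd <- simulate_reads(pl$genomes$s, pl$reference$scrofa,
                         truth = pl$truth, depth = 15, seed = 14,
                         sample_id = "s")
    fa <- tempfile(); sam <- tempfile()
    write_fasta(list(chr1 = pl$genomes$s$hap1), fa)
    write_sam(rd$sam, rd$sq, sam)
    c(tools::md5sum(fa), tools::md5sum(sam))
  }
  expect_identical(unname(run()), unname(run()))
})

test_that("read length beyond the contig is rejected", {
  pl <- fixture_planted(list(), genome_length = 2000L, seed = 15,
                        samples = data.frame(sample = "s",
                                             species = "scrofa"))
  expect_error(simulate_reads(pl$genomes$s, pl$reference$scrofa,
                              depth = 5, read_len = 5000L, seed = 1,
                              sample_id = "s"),
               "read_len")
})

test_that("SAM round-trips through the writer and reader", {
  pl <- fixture_planted(list(), genome_length = 5000L, seed = 16,
                        samples = data.frame(sample = "s",
                                             species = "scrofa"))
  rd <- simulate_reads(pl$genomes$s, pl$reference$scrofa, depth = 5,
                       seed = 2, sample_id = "s")
  path <- tempfile(fileext = ".sam")
  write_sam(rd$sam, rd$sq, path)
  back <- read_sam(path)
  expect_equal(back$sq$name, "chr1")
  expect_equal(nrow(back$records), nrow(rd$sam))
  expect_equal(back$records$pos, rd$sam$pos)
  expect_equal(back$records$cigar, rd$sam$cigar)
})
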