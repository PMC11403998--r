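# Carrier frequencies, polymorphism calling, UPGMA clustering, annotation
# and repeat enrichment.

test_that("carrier fractions are computed per group with undetermined
           calls excluded from denominators", {
  calls <- data.frame(
    region_id = "r1",
    sample_id = paste0("s", 1:5),
    genotype = c("hom_ins", "het", "absent", "absent", "undetermined"))
  groups <- stats::setNames(rep("b1", 5), paste0("s", 1:5))
  cf <- carrier_frequencies(calls, groups, min_datasets = 1L)
  expect_equal(unname(cf$table["r1", "b1"]), 2 / 4)
  expect_equal(unname(cf$n["r1", "b1"]), 4L)
  # 3 of 4 carriers -> 0.75
  calls2 <- data.frame(region_id = "r1", sample_id = paste0("s", 1:4),
                       carrier = c(TRUE, TRUE, TRUE, FALSE))
  cf2 <- carrier_frequencies(calls2, stats::setNames(rep("b", 4),
                                                     paste0("s", 1:4)),
                             min_datasets = 1L)
  expect_equal(unname(cf2$table["r1", "b"]), 0.75)
  # all-carrier pools -> 1.0
  pools <- data.frame(region_id = "r1", sample_id = c("p1", "p2"),
                      carrier = TRUE)
  cfp <- carrier_frequencies(pools, c(p1 = "pool", p2 = "pool"))
  expect_equal(unname(cfp$table["r1", "pool"]), 1)
  expect_false(cfp$group_sizes$eligible[1])   # 2 < 10 datasets
})

test_that("designed per-group frequencies are recovered within a binomial
           interval", {
  set.seed(91)
  n <- 40
  truth <- c(g1 = 0.2, g2 = 0.8)
  calls <- NULL
  for (g in names(truth)) {
    carriers <- stats::rbinom(n, 1, truth[g]) == 1
    calls <- rbind(calls, data.frame(
      region_id = "r1", sample_id = paste0(g, "_", seq_len(n)),
      carrier = carriers))
  }
  groups <- stats::setNames(sub("_.*", "", calls$sample_id),
                            calls$sample_id)
  cf <- carrier_frequencies(calls, groups, min_datasets = 10L)
  for (g in names(truth)) {
    ci <- stats::binom.test(round(truth[g] * n), n)$conf.int
    expect_gte(cf$table["r1", g], ci[1] - 0.1)
    expect_lte(cf$table["r1", g], ci[2] + 0.1)
  }
})

test_that("the ancient-region control yields the false-negative rate and
           the polymorphism threshold uses it strictly", {
  calls <- data.frame(region_id = rep(c("a1", "a2"), each = 100),
                      sample_id = paste0("s", 1:200),
                      carrier = rep(c(TRUE, FALSE), times = c(97, 3)))
  expect_equal(estimate_false_negative_rate(calls), 0.03,
               tolerance = 1e-9)
  perfect <- data.frame(region_id = "a1", sample_id = paste0("s", 1:10),
                        carrier = TRUE)
  expect_equal(estimate_false_negative_rate(perfect), 0)
  expect_true(is.na(estimate_false_negative_rate(perfect[0, ])))
  # threshold semantics at fn = 0.03: 0.969 polymorphic, 0.97 fixed
  poly <- call_polymorphic(c(r1 = 0.969, r2 = 0.97, r3 = 1), 0.03)
  expect_equal(unname(poly), c(TRUE, FALSE, FALSE))
  # fallback when no ancient control
  expect_true(call_polymorphic(c(r = 0.95), NA_real_)[["r"]])
})

test_that("dropout in the read data propagates into the estimated
           false-negative rate", {
  set.seed(92)
  carriers <- stats::rbinom(300, 1, 0.95) == 1
  calls <- data.frame(region_id = rep(c("a1", "a2", "a3"), each = 100),
                      sample_id = paste0("s", 1:300), carrier = carriers)
  rate <- estimate_false_negative_rate(calls)
  expect_equal(rate, 1 - mean(carriers), tolerance = 1e-12)
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("UPGMA reproduces a hand-computed agglomeration and duplicated
           groups merge at height zero", {
  # four groups in frequency space chosen so merges are unambiguous
  freq <- rbind(r1 = c(g1 = 0.0, g2 = 0.1, g3 = 0.9, g4 = 1.0),
                r2 = c(g1 = 0.0, g2 = 0.1, g3 = 0.8, g4 = 1.0))
  cl <- upgma_cluster(freq)
  d <- as.matrix(stats::dist(t(freq)))
  # hand agglomeration: (g1,g2) at d=0.1414.., (g3,g4) at 0.2236..,
  # then the two pairs at the average of the four cross distances
  h1 <- d["g1", "g2"]; h2 <- d["g3", "g4"]
  h3 <- mean(c(d["g1", "g3"], d["g1", "g4"], d["g2", "g3"], d["g2", "g4"]))
  expect_equal(sort(cl$hclust$height), sort(c(h1, h2, h3)),
               tolerance = 1e-12)
  expect_equal(sort(cl$hclust$height), upgma_heights_oracle(d),
               tolerance = 1e-12)
  # dendrogram is ultrametric and covers all groups
  expect_true(ape::is.ultrametric(cl$phylo))
  expect_setequal(cl$phylo$tip.label, colnames(freq))
  dup <- cbind(freq, g5 = freq[, "g4"])
  cl2 <- upgma_cluster(dup)
  expect_equal(min(cl2$hclust$height), 0)
  expect_error(upgma_cluster(freq[, 1:2]), "3 groups")
})

test_that("species-private insertion profiles cluster species together", {
  set.seed(93)
  freq <- rbind(
    shared = c(a1 = 1, a2 = 1, b1 = 1, b2 = 1),
    privA = c(a1 = 0.9, a2 = 0.8, b1 = 0, b2 = 0.05),
    privB = c(a1 = 0.02, a2 = 0, b1 = 0.85, b2 = 0.9))
  cl <- upgma_cluster(freq)
  nw <- cl$newick
  a_clade <- ape::getMRCA(cl$phylo, c("a1", "a2"))
  b_clade <- ape::getMRCA(cl$phylo, c("b1", "b2"))
  desc <- function(node) {
    tips <- ape::extract.clade(cl$phylo, node)$tip.label
    tips
  }
  expect_setequal(desc(a_clade), c("a1", "a2"))
  expect_setequal(desc(b_clade), c("b1", "b2"))
})

test_that("regions annotate with feature precedence, closest gene and
           flank GC", {
  genes <- data.frame(contig = "chr1",
                      start = c(1000L, 1000L, 8000L),
                      end = c(5000L, 1500L, 9000L),
                      type = c("gene", "exon", "gene"),
                      gene = c("GENE1", "GENE1", "GENE2"))
  regions <- data.frame(region_id = c("rA", "rB", "rC"),
                        contig = "chr1",
                        start = c(2000L, 1100L, 14000L),
                        end = c(2400L, 1200L, 14400L))
  genome <- c(chr1 = paste0(strrep("A", 10000),
                            strrep(paste0(strrep("G", 5), strrep("T", 5)),
                                   2000)))
  ann <- annotate_regions(regions, genes, genome = genome)
  expect_equal(ann$feature, c("intron", "exon", "intergenic"))
  expect_equal(ann$closest_gene, c("GENE1", "GENE1", "GENE2"))
  expect_equal(ann$gene_distance[1], 0L)
  expect_equal(ann$gene_distance[3], -(14000L - 9000L))
  # flanks of rC lie inside the 50% GC tail
  expect_equal(ann$flank_gc[3], 0.5, tolerance = 0.01)
  # intergenic region 5 kb from nearest gene
  expect_equal(abs(ann$gene_distance[3]), 5000L)
})

test_that("repeats within 1 kb are collected but repeats inside the
           region are not", {
  regions <- data.frame(region_id = "r", contig = "chr1",
                        start = 5000L, end = 6000L)
  genes <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      gene = character(0))
  repeats <- data.frame(contig = "chr1",
                        start = c(4500L, 5200L, 7500L),
                        end = c(4700L, 5400L, 7700L),
                        class = c("SINE", "LINE", "LTR"))
  ann <- annotate_regions(regions, genes, repeats = repeats)
  expect_equal(ann$repeat_classes, "SINE")
})

test_that("Fisher enrichment equals the hypergeometric oracle and
           degenerate tables return p = 1", {
  # exhaustive over small tables
  for (n in c(8L, 12L)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
      got <- repeat_enrichment(c(x = a), a + b, c(x = cc), cc + d)
      expect_equal(got$p_value, fisher_p_oracle(a, b, cc, d),
                   tolerance = 1e-9,
                   info = paste(a, b, cc, d))
    }
  }
  # random larger tables up to n = 200
  set.seed(94)
  for (i in 1:60) {
    n <- sample(20:200, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    cc <- sample(0:(n - a - b), 1); d <- n - a - b - cc
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    got <- repeat_enrichment(c(x = a), a + b, c(x = cc), cc + d)
    expect_equal(got$p_value, fisher_p_oracle(a, b, cc, d),
                 tolerance = 1e-9)
  }
  # identical proportions: p = 1, OR = 1
  same <- repeat_enrichment(c(x = 10L), 20L, c(x = 10L), 20L)
  expect_equal(same$p_value, 1)
  # zero-margin table
  zero <- repeat_enrichment(c(x = 0L), 20L, c(x = 0L), 50L)
  expect_equal(zero$p_value, 1)
  expect_equal(repeat_enrichment(c(x = 8L), 10L, c(x = 20L), 90L)$p_value,
               fisher_p_oracle(8, 2, 20, 70), tolerance = 1e-9)
})

test_that("flanks enriched for a planted repeat class reach significance
           at scale", {
  # 100 regions whose flanks are 3x enriched for SINE coverage
  genome_total <- 1e6
  genome_sine <- 1e5            # 10% of the genome
  flank_total <- 100 * 2000
  flank_sine <- round(0.3 * flank_total)   # 30% of flank bases
  res <- repeat_enrichment(c(SINE = flank_sine), flank_total,
                           c(SINE = genome_sine), genome_total)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$odds_ratio, 1)
})

test_that("the GFF3 export round-trips losslessly and agrees with the
           region table", {
  regions <- data.frame(region_id = c("chr1_REGION_1", "chr1_REGION_2"),
                        genome_id = "g", contig = "chr1",
                        start = c(1000L, 9000L), end = c(1500L, 9800L),
                        n_fragments = c(1L, 2L),
                        total_numt_bp = c(500L, 700L),
                        mean_identity = 1, complex = FALSE,
                        inversion_present = FALSE)
  hits <- data.frame(region_id = c("chr1_REGION_1", "chr1_REGION_2",
                                   "chr1_REGION_2"),
                     contig = "chr1",
                     tstart = c(1000L, 9000L, 9500L),
                     tend = c(1500L, 9300L, 9800L),
                     qstart = c(0L, 100L, 400L),
                     qend = c(500L, 400L, 700L),
                     strand = c("+", "+", "-"), score = c(400L, 250L, 250L))
  p1 <- tempfile(fileext = ".gff3")
  export_gff(regions, hits, p1)
  back <- read_numt_gff(p1)
  expect_equal(nrow(back$regions), 2L)
  expect_equal(nrow(back$hits), 3L)
  expect_equal(back$regions$start, regions$start)
  expect_equal(back$hits$qend, hits$qend)
  p2 <- tempfile(fileext = ".gff3")
  export_gff(back$regions, back$hits, p2)
  expect_identical(readLines(p1), readLines(p2))
  # GFF (1-based inclusive) vs BED-style (0-based half-open) agreement
  gff_lines <- readLines(p1)
  first <- strsplit(gff_lines[2], "\t")[[1]]
  expect_equal(as.integer(first[4]) - 1L, regions$start[1])
  expect_equal(as.integer(first[5]), regions$end[1])
})
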