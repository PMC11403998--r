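# Shared fixture builders (all generated in code; no stored data).

fixture_tree <- function(mito_rate = 2e-8, mt_length = 16600L, ...) {
  suinae_tree_spec(mito_rate = mito_rate, mt_length = mt_length, ...)
}

# One scrofa genome with planted insertions; returns the plant_numts result.
fixture_planted <- function(insertions, genome_length = 60000L,
                            seed = 1L, samples = NULL,
                            spec = fixture_tree()) {
  bg <- background_genome(genome_length, seed = seed)
  plant_numts(bg, insertions, spec, seed = seed + 1L, samples = samples)
}

hom <- function(...) {
  samples <- c(...)
  stats::setNames(rep("hom_ins", length(samples)), samples)
}

# Four-insertion two-genome orthology design: one shared insertion,
# one private to genome A, one present-but-uncalled in B, and one in a
# region omitted from the alignment.
make_orth_fixture <- function(seed = 71) {
  spec <- fixture_tree()
  bg <- background_genome(60000L, seed = seed)
  ins <- list(
    insertion_spec("shared", "chr1", 10000L, 1000L, 1400L, age = 5,
                   genotypes = c(gA = "hom_ins", gB = "hom_ins")),
    insertion_spec("privA", "chr1", 25000L, 4000L, 4350L, age = 0.5,
                   genotypes = c(gA = "hom_ins", gB = "absent")),
    insertion_spec("uncalledB", "chr1", 40000L, 7000L, 7300L, age = 1,
                   genotypes = c(gA = "hom_ins", gB = "hom_ins")),
    insertion_spec("unalB", "chr1", 52000L, 9000L, 9200L, age = 1,
                   genotypes = c(gA = "hom_ins", gB = "absent")))
  pl <- plant_numts(bg, ins, spec, seed = seed + 1,
                    samples = data.frame(sample = c("gA", "gB"),
                                         species = "scrofa"))
  blocks <- emit_pairwise_maf(pl, "gA", "gB",
                              unaligned = data.frame(start = 51500L,
                                                     end = 52500L))
  truthA <- pl$truth[pl$truth$sample == "gA" &
                       pl$truth$haplotype == "hap1", ]
  regsA <- data.frame(
    region_id = paste0("chr1_REGION_", seq_len(nrow(truthA))),
    genome_id = "gA", contig = "chr1",
    start = truthA$start, end = truthA$end,
    n_fragments = 1L, total_numt_bp = truthA$length,
    mean_identity = 1, complex = FALSE, inversion_present = FALSE)
  rownames(regsA) <- truthA$insertion
  shared_b <- pl$truth[pl$truth$insertion == "shared" &
                         pl$truth$sample == "gB" &
                         pl$truth$haplotype == "hap1", ]
  regsB <- data.frame(region_id = "chr1_REGION_1", genome_id = "gB",
                      contig = "chr1", start = shared_b$start,
                      end = shared_b$end, n_fragments = 1L,
                      total_numt_bp = shared_b$length, mean_identity = 1,
                      complex = FALSE, inversion_present = FALSE)
  list(planted = pl, blocks = blocks, regsA = regsA, regsB = regsB)
}

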