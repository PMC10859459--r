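test_that("marker map generation is seeded, sorted and size-checked", {
  m1 <- gen_marker_map(1, 5, 1e6, seed = 7)
  m2 <- gen_marker_map(1, 5, 1e6, seed = 7)
  expect_identical(m1, m2)

  m <- gen_marker_map(21, 100, 7e8, seed = 1)
  expect_equal(nrow(m), 2100)
  expect_false(anyDuplicated(m$marker_id) > 0)
  for (ch in unique(m$chromosome)) {
    expect_false(is.unsorted(m$position[m$chromosome == ch], strictly = TRUE))
  }
  # wheat-style names for multiples of 3
  expect_true(all(c("1A", "1B", "1D", "7D") %in% m$chromosome))

  expect_error(gen_marker_map(1, 10, 5, seed = 1), "cannot place")
  expect_error(gen_marker_map(0, 10, 100, seed = 1), "positive")
})

test_that("array experiment is degenerate without noise and reproducible", {
  map <- gen_marker_map(2, 50, 1e7, seed = 2)
  exp <- gen_array_experiment(map, NULL, noise_sd = 0,
                              otv_rate_background = 0, nocall_rate = 0,
                              seed = 9)
  expect_identical(exp$intensity$mutant, exp$intensity$reference)
  expect_false(any(exp$calls$mutant == "OTV"))
  expect_false(any(exp$calls$reference == "OTV"))
  expect_equal(nrow(exp$truth), 0)

  e1 <- gen_array_experiment(map, NULL, seed = 11)
  e2 <- gen_array_experiment(map, NULL, seed = 11)
  expect_identical(e1, e2)

  expect_error(gen_array_experiment(map, NULL, noise_sd = -0.1, seed = 1),
               "non-negative")
  expect_error(
    gen_array_experiment(map, deletion_spec("9Z", 1, 100), seed = 1),
    "not in map")
})

test_that("OTV rate inside an injected deletion matches its binomial bounds", {
  map <- gen_marker_map(1, 200, 1e8, seed = 5)
  del <- deletion_spec("chr1", map$position[50], map$position[99],
                       signal_shift = -3, otv_rate_inside = 0.6)
  exp <- gen_array_experiment(map, del, noise_sd = 0.2, nocall_rate = 0,
                              seed = 6)
  inside <- exp$calls$mutant[50:99]
  frac <- mean(inside == "OTV")
  bounds <- binom_bounds(50, 0.6)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  # intensity shift applied inside, not outside
  expect_lt(mean(exp$intensity$mutant[50:99]), -2)
  expect_gt(mean(exp$intensity$mutant[-(50:99)]), -1)
  expect_equal(exp$truth$first_marker, 50)
  expect_equal(exp$truth$last_marker, 99)
})

test_that("meiocyte generator conserves chromosomes and hits shape fractions", {
  profs <- genotype_profiles()

  # all shape probabilities zero -> all ring bivalents
  quiet <- genotype_profile("quiet", 0, 0, 0, mean_chiasmata = 42)
  cells <- gen_meiocytes(quiet, 50, seed = 1)
  expect_true(all(cells$n_ring_bivalent == 21))
  expect_true(all(cells$n_univalent == 0))

  # WT: univalent probability is zero
  wt <- gen_meiocytes(profs$WT, 2000, seed = 2)
  expect_equal(sum(wt$n_univalent > 0), 0)

  # conservation holds for every generated cell of every default genotype
  for (p in profs) {
    cells <- gen_meiocytes(p, 300, seed = 3)
    got <- cells$n_univalent + 2 * (cells$n_rod_bivalent + cells$n_ring_bivalent) +
      3 * cells$n_trivalent + 4 * (cells$n_ring_quadrivalent + cells$n_rod_quadrivalent)
    expect_true(all(got == 42))
  }

  # Htz-B-like univalent cell fraction within exact binomial bounds of 7.6%
  htzb <- gen_meiocytes(profs$`Htz-B`, 5000, seed = 4)
  frac <- mean(htzb$n_univalent > 0)
  bounds <- binom_bounds(5000, 0.076)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])

  expect_error(gen_meiocytes(profs$WT, 10, total_chromosomes = 41, seed = 1),
               "even")
  expect_error(genotype_profile("bad", p_cell_with_univalents = 1.2), "\\[0, 1\\]")
  # an unreachable chiasma mean with no rod-bearing cells is refused
  expect_error(gen_meiocytes(genotype_profile("inf", 0, 0, 0, 41), 10, seed = 1),
               "infeasible")
})

test_that("fertility counts are seeded Poisson draws around each mean", {
  p0 <- genotype_profile("zero", mean_seeds_per_spike = 0)
  expect_true(all(gen_fertility(p0, 100, seed = 1)$seeds == 0))

  p36 <- genotype_profile("full", mean_seeds_per_spike = 36)
  f <- gen_fertility(p36, 10000, seed = 2)
  expect_lt(abs(mean(f$seeds) - 36) / 36, 0.01)

  expect_identical(gen_fertility(p36, 50, seed = 3),
                   gen_fertility(p36, 50, seed = 3))
  expect_error(gen_fertility(p36, 0, seed = 1), ">= 1")
})

test_that("generated CDS variants round-trip through the annotator", {
  g <- gen_cds(1202, inject = list(codon_index = 539, ref_codon = "ACA",
                                   alt_base_offset = 1, alt_base = "G"),
               seed = 1)
  expect_equal(nchar(g$cds), 3606)
  expect_equal(g$truth$codon_index, 539)
  expect_equal(g$truth$cds_position, 1615)
  expect_equal(g$truth$ref_aa, "T")
  expect_equal(g$truth$alt_aa, "A")
  expect_equal(g$truth$consequence, "missense")

  # no injection: starts ATG, ends with a stop, no internal stop
  g0 <- gen_cds(50, seed = 2)
  expect_null(g0$truth)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(g0$cds)))
  expect_equal(substr(aa, 1, 1), "M")
  expect_equal(substr(aa, 50, 50), "*")
  expect_false(grepl("\\*", substr(aa, 1, 49)))

  # property: injected truth always equals annotate_cds_snp on the output
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    ci <- sample(2:29, 1)
    rc <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (rc %in% c("TAA", "TAG", "TGA")) next
    off <- sample(1:3, 1)
    alt <- sample(setdiff(bases, substr(rc, off, off)), 1)
    g <- gen_cds(30, inject = list(codon_index = ci, ref_codon = rc,
                                   alt_base_offset = off, alt_base = alt),
                 seed = i)
    redo <- annotate_cds_snp(g$cds, (ci - 1) * 3 + off, alt)
    expect_identical(unclass(g$truth), unclass(redo))
  }

  expect_error(gen_cds(30, inject = list(codon_index = 1, ref_codon = "ACA",
                                         alt_base_offset = 1, alt_base = "G")),
               "start codon")
  expect_error(gen_cds(30, inject = list(codon_index = 5, ref_codon = "TAA",
                                         alt_base_offset = 1, alt_base = "G")),
               "stop")
})

test_that("synthetic annotation and orthogroup tables are well formed", {
  genes <- gen_gene_annotation(c("2A", "2B", "2D"), 1e7, 25, seed = 1)
  expect_equal(nrow(genes), 75)
  expect_true(all(genes$start <= genes$end))
  expect_false(anyDuplicated(genes$gene_id) > 0)

  tab <- gen_orthogroup_table(40, p_present = 0.8, seed = 2)
  expect_true(all(tab$subgenome %in% c("A", "B", "D")))
  expect_false(anyDuplicated(tab$gene_id) > 0)
  expect_identical(tab, gen_orthogroup_table(40, p_present = 0.8, seed = 2))
})
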