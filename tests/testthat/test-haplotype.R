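snp_tab <- function(pos, baf, chrom = "chr1")
  data.frame(chrom = chrom, pos = pos, lrr = 0, baf = baf, genotype = ".",
             stringsAsFactors = FALSE)

test_that("phase-informative SNP selection follows the BAF rules", {
  parental <- snp_tab(c(100, 200, 300, 400), c(0.02, 0.50, 0.97, 0.03))
  baseline <- snp_tab(c(100, 200, 300, 400), c(0.34, 0.34, 0.96, 0.02))
  info <- find_phase_informative_snps(parental, baseline, "chr1")
  # pos 100: parental AA, baseline shifted to ~1/3 -> informative, B allele in
  expect_equal(info$pos, 100)
  expect_equal(info$transferred_allele, "B")
  expect_equal(info$expected_baf, 1 / 3)
  # pos 200 heterozygous parental, pos 300 no shift, pos 400 no shift: excluded

  # the 2/3 side
  parental <- snp_tab(100, 0.98)
  baseline <- snp_tab(100, 0.66)
  info <- find_phase_informative_snps(parental, baseline, "chr1")
  expect_equal(info$transferred_allele, "A")
  expect_equal(info$expected_baf, 2 / 3)

  expect_error(
    find_phase_informative_snps(snp_tab(1, 0.5), snp_tab(2, 0.5), "chr1"),
    "no positions")
})

test_that("CNA allele assignment reads loss BAF signatures correctly", {
  # 5 informative SNPs inside the CNA, parental side A (expected 1/3)
  info <- data.frame(chrom = "chr1", pos = seq(100, 500, by = 100),
                     parental_allele = "A", transferred_allele = "B",
                     expected_baf = 1 / 3, stringsAsFactors = FALSE)
  cna <- data.frame(chrom = "chr1", start = 0, end = 1000, state = "loss")
  # transferred deletion: back to homozygosity (0.02 / on the B side 0.97)
  clone <- snp_tab(info$pos, c(0.02, 0.01, 0.03, 0.02, 0.00))
  hc <- assign_cna_allele_baf(cna, info, clone)
  expect_equal(hc$verdict, "transferred")
  expect_equal(hc$n_total, 5)
  # endogenous deletion: AB genotype, BAF ~ 0.5
  clone <- snp_tab(info$pos, c(0.49, 0.52, 0.50, 0.48, 0.51))
  expect_equal(assign_cna_allele_baf(cna, info, clone)$verdict, "endogenous")
})

test_that("CNA allele assignment reads gain BAF signatures correctly", {
  info <- data.frame(chrom = "chr1", pos = seq(100, 400, by = 100),
                     parental_allele = c("A", "A", "B", "B"),
                     transferred_allele = c("B", "B", "A", "A"),
                     expected_baf = c(1 / 3, 1 / 3, 2 / 3, 2 / 3),
                     stringsAsFactors = FALSE)
  cna <- data.frame(chrom = "chr1", start = 0, end = 1000, state = "gain")
  # transferred duplication: 1/3 -> 1/2 and 2/3 -> 1/2 (AABB)
  clone <- snp_tab(info$pos, c(0.50, 0.49, 0.51, 0.50))
  expect_equal(assign_cna_allele_baf(cna, info, clone, min_snps = 3)$verdict,
               "transferred")
  # endogenous duplication: 1/3 -> 1/4, 2/3 -> 3/4 (AAAB / ABBB)
  clone <- snp_tab(info$pos, c(0.25, 0.26, 0.74, 0.75))
  expect_equal(assign_cna_allele_baf(cna, info, clone, min_snps = 3)$verdict,
               "endogenous")
})

test_that("assignment degrades to ambiguous rather than guessing", {
  info <- data.frame(chrom = "chr1", pos = c(100, 200),
                     parental_allele = "A", transferred_allele = "B",
                     expected_baf = 1 / 3, stringsAsFactors = FALSE)
  cna <- data.frame(chrom = "chr1", start = 0, end = 1000, state = "loss")
  clone <- snp_tab(info$pos, c(0.02, 0.03))
  # only 2 votes < min_snps = 3
  hc <- assign_cna_allele_baf(cna, info, clone)
  expect_equal(hc$verdict, "ambiguous")
  # CNA on a chromosome with zero informative SNPs
  cna2 <- data.frame(chrom = "chr2", start = 0, end = 1000, state = "loss")
  hc2 <- assign_cna_allele_baf(cna2, info, clone)
  expect_equal(hc2$verdict, "ambiguous")
  expect_equal(hc2$n_total, 0)
  # split votes below the majority margin
  info5 <- data.frame(chrom = "chr1", pos = seq(100, 600, by = 100),
                      parental_allele = "A", transferred_allele = "B",
                      expected_baf = 1 / 3, stringsAsFactors = FALSE)
  clone5 <- snp_tab(info5$pos, c(0.02, 0.03, 0.01, 0.49, 0.51, 0.50))
  expect_equal(assign_cna_allele_baf(cna, info5, clone5)$verdict, "ambiguous")
})

test_that("swapping A/B labels everywhere leaves verdicts unchanged", {
  g <- tiny_genome(seed = 41)
  ev <- data.frame(chrom = "chr1",
                   start = seq(1e5, 1.7e6, length.out = 8),
                   end = seq(1e5, 1.7e6, length.out = 8) + 1.5e5,
                   homolog = rep(c("transferred", "endogenous"), 4),
                   kind = rep(c("deletion", "duplication"), each = 4),
                   stringsAsFactors = FALSE)
  ev$start <- round(ev$start); ev$end <- round(ev$end)
  tr <- plant_cna_events(g, ev)
  prof <- render_snp_profile(tr, noise_sd = 0.02, seed = 5)
  base <- render_snp_profile(simulate_intact(g), noise_sd = 0.02, seed = 6)
  flip <- function(tab) { tab$baf <- 1 - tab$baf; tab }
  info <- find_phase_informative_snps(prof$parental, base$clone, "chr1")
  info_f <- find_phase_informative_snps(flip(prof$parental), flip(base$clone),
                                        "chr1")
  expect_equal(nrow(info), nrow(info_f))
  ev$state <- ifelse(ev$kind == "deletion", "loss", "gain")
  for (i in seq_len(nrow(ev))) {
    v <- assign_cna_allele_baf(ev[i, ], info, prof$clone)$verdict
    v_f <- assign_cna_allele_baf(ev[i, ], info_f, flip(prof$clone))$verdict
    expect_equal(v, v_f)
  }
})

test_that("junction read-pair verdicts use the exact binomial", {
  counts <- function(t, e) data.frame(transferred_count = t,
                                      endogenous_count = e)
  # 12 vs 0: one-sided p = 2^-12 < 0.05
  expect_equal(assign_junction_allele_reads(counts(12, 0))$verdict,
               "transferred")
  expect_equal(assign_junction_allele_reads(counts(0, 12))$verdict,
               "endogenous")
  # 3 vs 2: one-sided p = 0.5, not significant
  expect_equal(assign_junction_allele_reads(counts(3, 2))$verdict, "ambiguous")
  # zero evidence
  expect_equal(assign_junction_allele_reads(counts(0, 0))$verdict, "ambiguous")
  # below the minimum pair count even if unanimous
  expect_equal(assign_junction_allele_reads(counts(3, 0),
                                            min_pairs = 5)$verdict,
               "ambiguous")
  # counts split over SNP rows are pooled
  pooled <- data.frame(transferred_count = c(6, 6), endogenous_count = c(0, 0))
  expect_equal(assign_junction_allele_reads(pooled)$n_total, 12)
})

test_that("affected-fraction summary handles all cases", {
  hc <- function(v) structure(list(verdict = v, n_support = 1, n_total = 1),
                              class = "haplotype_call")
  s <- summarize_affected_fraction(c(replicate(9, hc("transferred"),
                                               simplify = FALSE),
                                     list(hc("endogenous"))))
  expect_equal(s$fraction, 0.9)
  expect_equal(s$n_transferred, 9)
  s2 <- summarize_affected_fraction(list(hc("ambiguous"), hc("ambiguous")))
  expect_true(is.na(s2$fraction))
  expect_equal(s2$n_ambiguous, 2)
  expect_true(is.na(summarize_affected_fraction(list())$fraction))
})
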