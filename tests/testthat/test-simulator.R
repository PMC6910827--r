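test_that("reference simulation is deterministic and honours the spec", {
  g1 <- tiny_genome(seed = 7)
  g2 <- tiny_genome(seed = 7)
  expect_identical(g1$snps, g2$snps)

  g_all <- simulate_reference(
    genome_spec(chromosomes = c(chr1 = 1e6), informative_fraction = 1,
                aneuploid_chrom = "chr1"), seed = 1, sequence = FALSE)
  expect_true(all(g_all$snps$informative))
  expect_true(all(g_all$snps$par_is_b != g_all$snps$trans_is_b))

  expect_error(genome_spec(informative_fraction = 0), "informative_fraction")
  expect_error(genome_spec(aneuploid_chrom = "chrX"), "aneuploid_chrom")
  expect_error(simulate_reference(
    genome_spec(chromosomes = c(chr1 = 100), snp_density = 1e-9,
                aneuploid_chrom = "chr1"), seed = 1, sequence = FALSE),
    "zero SNPs")
})

test_that("shattering conserves fragment lengths exactly", {
  g <- tiny_genome(seed = 3)
  for (seed in 1:5) {
    tr <- simulate_shattering(g, k_breakpoints = 20, deletion_fraction = 0.4,
                              seed = seed)
    expect_equal(sum(tr$events$end - tr$events$start), 2e6)
    retained <- sum(tr$derived_structure$end - tr$derived_structure$start)
    deleted <- sum((tr$events$end - tr$events$start)[tr$events$deleted])
    expect_equal(retained + deleted, 2e6)
  }
})

test_that("shattering limit cases behave", {
  g <- tiny_genome(seed = 3)
  # no deletion, no reordering, no inversion: identity reassembly
  tr <- simulate_shattering(g, k_breakpoints = 5, deletion_fraction = 0,
                            seed = 2, shuffle = FALSE, invert_prob = 0)
  expect_equal(nrow(true_cnas(tr)), 0)
  expect_equal(nrow(tr$junctions), 0)

  # k = 1 with one fragment deleted: exactly one terminal loss, no junction
  found <- FALSE
  for (seed in 1:20) {
    tr1 <- simulate_shattering(g, k_breakpoints = 1, deletion_fraction = 0.5,
                               seed = seed, shuffle = FALSE, invert_prob = 0)
    if (any(tr1$events$deleted)) {
      found <- TRUE
      tc <- true_cnas(tr1)
      expect_equal(nrow(tc), 1)
      expect_equal(tc$state, "loss")
      expect_equal(tc$homolog, "transferred")
      expect_equal(nrow(tr1$derived_structure), 1)
      expect_equal(nrow(tr1$junctions), 0)
      break
    }
  }
  expect_true(found)

  # determinism
  a <- simulate_shattering(g, 10, 0.3, seed = 9)
  b <- simulate_shattering(g, 10, 0.3, seed = 9)
  expect_identical(a$derived_structure, b$derived_structure)
  expect_identical(a$junctions, b$junctions)
})

test_that("chromoanasynthesis produces >2 copy states and bounded inserts", {
  g <- tiny_genome(seed = 5)
  ca <- simulate_chromoanasynthesis(g, n_switches = 5, seed = 11)
  an_states <- unique(ca$cn_profile$cn_total[ca$cn_profile$chrom == "chr1"])
  expect_gte(max(an_states), 4)        # duplications raise trisomic to >= 4
  expect_gt(length(an_states), 2)      # more than two copy-number states
  ins <- ca$junctions$ins_len[ca$junctions$ins_len > 0]
  if (length(ins)) expect_true(all(ins >= 50 & ins <= 200))
  ca2 <- simulate_chromoanasynthesis(g, n_switches = 5, seed = 11)
  expect_identical(ca$derived_structure, ca2$derived_structure)
})

test_that("junction orientations are consistent with the derived structure", {
  # recompute each stored orientation from adjacent derived fragments using
  # the strand-to-side table applied by hand
  side_up <- function(strand) if (strand == "+") "tail" else "head"
  side_dn <- function(strand) if (strand == "+") "head" else "tail"
  pos_up <- function(f) if (f$strand == "+") f$end else f$start
  pos_dn <- function(f) if (f$strand == "+") f$start else f$end
  g <- tiny_genome(seed = 13)
  tr <- simulate_shattering(g, k_breakpoints = 15, deletion_fraction = 0.3,
                            seed = 21)
  ds <- tr$derived_structure
  expected <- list()
  for (i in seq_len(nrow(ds) - 1)) {
    up <- ds[i, ]; dn <- ds[i + 1, ]
    orig_adj <- (up$strand == "+" && dn$strand == "+" && up$end == dn$start) ||
      (up$strand == "-" && dn$strand == "-" && up$start == dn$end)
    if (orig_adj) next
    p1 <- pos_up(up); s1 <- side_up(up$strand)
    p2 <- pos_dn(dn); s2 <- side_dn(dn$strand)
    lab <- if (p1 <= p2) paste0(s1, "_", s2) else paste0(s2, "_", s1)
    expected[[length(expected) + 1]] <- lab
  }
  expect_equal(tr$junctions$orientation, unlist(expected))
})

test_that("zero-noise rendering reproduces exact allele fractions", {
  g <- tiny_genome(seed = 17)
  tr <- simulate_shattering(g, k_breakpoints = 10, deletion_fraction = 0.5,
                            seed = 4)
  prof <- render_snp_profile(tr, noise_sd = 0, seed = 1)
  cl <- prof$clone
  info <- g$snps[g$snps$informative & g$snps$chrom == "chr1", ]
  # transferred-copy coverage at each informative SNP
  ds <- tr$derived_structure
  for (i in head(seq_len(nrow(info)), 200)) {
    pos <- info$pos[i]
    t_cov <- sum(ds$start <= pos & pos < ds$end)
    row <- cl[cl$chrom == "chr1" & cl$pos == pos, ]
    n_b <- 2 * info$par_is_b[i] + t_cov * info$trans_is_b[i]
    expect_equal(row$baf, n_b / (2 + t_cov))
    expect_equal(row$lrr, log2((2 + t_cov) / 2))
  }
  # an informative SNP in an intact trisomic region sits at exactly 1/3 or 2/3
  intact <- info[vapply(info$pos, function(p)
    sum(ds$start <= p & p < ds$end) == 1, logical(1)), ]
  expect_true(all(abs(cl$baf[match(paste("chr1", intact$pos),
                                   paste(cl$chrom, cl$pos))] - 0.5) >
                    0.16))  # 1/3 or 2/3, never 0.5
})

test_that("zero-noise quantal segments equal true copy numbers", {
  g <- tiny_genome(seed = 19)
  tr <- simulate_shattering(g, k_breakpoints = 8, deletion_fraction = 0.5,
                            seed = 6)
  segs <- render_quantal_segments(tr, bin_size = 1e4, noise_sd = 0, seed = 1)
  expect_true(all(segs$quantal == round(segs$quantal)))
  # disomic background chromosome renders exactly 2.0
  expect_equal(unique(segs$quantal[segs$chrom == "chr2"]), 2)
  # aneuploid chromosome oscillates between 3 (retained) and 2 (deleted)
  an <- segs[segs$chrom == "chr1", ]
  expect_setequal(unique(an$quantal), c(2, 3))
})

test_that("simple events give the textbook junction orientations", {
  g <- tiny_genome(seed = 23)
  del <- simulate_simple_event(g, "deletion", 5e5, 8e5)
  expect_equal(del$junctions$orientation, "tail_head")
  expect_equal(true_cnas(del)$state, "loss")

  dup <- simulate_simple_event(g, "tandem_duplication", 5e5, 8e5)
  expect_equal(dup$junctions$orientation, "head_tail")
  expect_equal(true_cnas(dup)$state, "gain")

  inv <- simulate_simple_event(g, "inversion", 5e5, 8e5)
  expect_setequal(inv$junctions$orientation, c("tail_tail", "head_head"))
  expect_equal(nrow(true_cnas(inv)), 0)  # copy-neutral
})

test_that("read-pair rendering respects error rate and coverage", {
  g <- tiny_genome(seed = 29)
  tr <- simulate_shattering(g, k_breakpoints = 10, deletion_fraction = 0.3,
                            seed = 8)
  rp <- render_readpair_counts(tr, coverage_mean = 6, error_rate = 0, seed = 1)
  expect_gt(nrow(rp), 0)
  expect_true(all(rp$endogenous_count == 0))  # every event is transferred

  rp0 <- render_readpair_counts(tr, coverage_mean = 0, error_rate = 0, seed = 1)
  expect_true(all(rp0$transferred_count + rp0$endogenous_count == 0))
  hc <- assign_junction_allele_reads(rp0)
  expect_equal(hc$verdict, "ambiguous")

  rp1 <- render_readpair_counts(tr, coverage_mean = 6, error_rate = 0.1, seed = 3)
  rp2 <- render_readpair_counts(tr, coverage_mean = 6, error_rate = 0.1, seed = 3)
  expect_identical(rp1, rp2)
})

test_that("planted CNA events yield the expected per-homolog profile", {
  g <- tiny_genome(seed = 31)
  ev <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(1e5, 5e5, 2e5), end = c(2e5, 7e5, 4e5),
                   homolog = c("transferred", "endogenous", "endogenous"),
                   kind = c("deletion", "duplication", "deletion"),
                   stringsAsFactors = FALSE)
  tr <- plant_cna_events(g, ev)
  tc <- true_cnas(tr)
  expect_equal(nrow(tc), 3)
  expect_equal(tc$state, c("loss", "gain", "loss"))
  expect_equal(tc$homolog, c("transferred", "endogenous", "endogenous"))
  prof <- tr$cn_profile
  expect_equal(prof$cn_total[prof$chrom == "chr1" & prof$start == 1e5], 2)
  expect_equal(prof$cn_total[prof$chrom == "chr1" & prof$start == 5e5], 4)
  expect_error(
    plant_cna_events(g, data.frame(chrom = "chr2", start = 0, end = 1e5,
                                   homolog = "transferred", kind = "deletion")),
    "aneuploid")
})
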