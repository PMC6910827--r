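test_that("orientation classification is order-invariant and flags translocations", {
  j <- make_junctions("chr1", 5000L, "head", "chr1", 100L, "tail")
  cls <- classify_orientation(j)
  expect_equal(cls$orientation, "tail_head")
  expect_false(cls$translocation)
  t <- make_junctions("chr8", 100L, "head", "chr5", 5000L, "tail")
  expect_true(classify_orientation(t)$translocation)
})

test_that("orientation spectrum applies the span filter strictly", {
  j <- make_junctions(rep("chr1", 5),
                      c(0L, 0L, 0L, 0L, 1000L),
                      c("tail", "head", "head", "tail", "tail"),
                      rep("chr1", 5),
                      c(1e6L, 2e6L, 3e6L, 4e6L, 10000L),
                      c("head", "tail", "head", "tail", "head"))
  sp <- orientation_spectrum(j, min_span = 1e4)
  expect_equal(sum(sp$counts), 4)  # the 9 kb-spanning junction is excluded
  expect_equal(unname(sp$counts), c(1, 1, 1, 1))
  expect_equal(orientation_spectrum(j[0, ])$total, 0)
  # a junction spanning exactly min_span is excluded (strict >)
  jeq <- make_junctions("chr1", 0L, "tail", "chr1", 10000L, "head")
  expect_equal(orientation_spectrum(jeq, min_span = 1e4)$total, 0)
  # translocations always count
  jt <- make_junctions("chr1", 0L, "tail", "chr2", 5L, "head")
  expect_equal(orientation_spectrum(jt)$total, 1)
})

test_that("multinomial uniformity test reproduces closed forms", {
  perfect <- multinomial_uniform_test(c(5, 5, 5, 5))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  skew <- multinomial_uniform_test(c(10, 0, 0, 0), method = "asymptotic")
  expect_equal(skew$statistic, 30)
  expect_equal(skew$p_value, pchisq(30, df = 3, lower.tail = FALSE))

  tiny <- multinomial_uniform_test(c(2, 0, 0, 0))
  expect_equal(tiny$method, "exact")
  expect_equal(tiny$p_value, 0.25)  # 4 * (1/4)^2 outcomes at statistic 6

  expect_error(multinomial_uniform_test(c(0, 0, 0, 0)), "at least one")
  # exact and asymptotic agree for large totals
  for (big in list(c(30, 26, 24, 20), c(35, 28, 22, 15), c(40, 30, 20, 10))) {
    pe <- multinomial_uniform_test(big, method = "exact")$p_value
    pa <- multinomial_uniform_test(big, method = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("junction homology resolves planted splits like the oracle", {
  set.seed(7)
  dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  F <- 80
  for (rep in 1:60) {
    mh <- sample(0:15, 1)
    ins <- if (mh == 0) sample(c(0, sample(1:30, 1)), 1) else 0
    left <- dna(F)
    right_tail <- dna(F - mh)
    right <- paste0(substr(left, F - mh + 1, F), right_tail)
    contig <- paste0(left, if (ins > 0) dna(ins) else "",
                     substr(right, mh + 1, F))
    got <- junction_homology(contig, left, right)
    want <- oracle_junction_split(contig, left, right)
    expect_equal(got$microhomology_len, want$microhomology_len)
    expect_equal(got$insertion_len, want$insertion_len)
    expect_equal(got$feature_class, want$feature_class)
    expect_equal(got$microhomology_len, mh)
    expect_equal(got$insertion_len, ins)
  }
  # blunt concatenation
  l <- dna(F); r <- dna(F)
  b <- junction_homology(paste0(l, r), l, r)
  expect_equal(b$feature_class, "blunt")
  # contig too short
  expect_error(junction_homology("ACGT", l, r), "anchor")
  # one flank entirely wrong -> unclassifiable
  u <- junction_homology(paste0(dna(F), r), l, r)
  expect_equal(u$feature_class, "unclassifiable")
})

test_that("templated insertions are found by exact search, with threshold", {
  set.seed(11)
  ref <- c(chrA = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                        collapse = ""))
  ins <- substr(ref[["chrA"]], 1001, 1080)  # 80 bp copied verbatim
  hit <- detect_templated_insertion(ins, ref)
  expect_true(hit$templated)
  expect_equal(hit$template_start, 1000)
  expect_equal(hit$template_end, 1080)
  expect_true(oracle_find_template(ins, ref))
  # reverse complement hits too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
  hit_rc <- detect_templated_insertion(rc, ref)
  expect_true(hit_rc$templated)
  expect_equal(hit_rc$template_strand, "-")
  # below min_len is non-templated by threshold
  expect_false(detect_templated_insertion(substr(ins, 1, 10), ref)$templated)
  # a random 60-mer absent from the reference
  absent <- paste(rep("ACGTT", 12), collapse = "")
  expect_equal(oracle_find_template(absent, ref),
               detect_templated_insertion(absent, ref)$templated)
})

test_that("copy-number oscillation statistics count transitions and states", {
  expect_equal(copy_number_oscillations(c(3, 2, 3, 2, 3)),
               list(n_transitions = 4L, n_distinct_states = 2L))
  expect_equal(copy_number_oscillations(c(3)),
               list(n_transitions = 0L, n_distinct_states = 1L))
  expect_equal(copy_number_oscillations(c(3, 4, 2)),
               list(n_transitions = 2L, n_distinct_states = 3L))
  expect_equal(copy_number_oscillations(numeric())$n_distinct_states, 0L)
})

test_that("breakpoint percentages per chromosome sum to 100", {
  j <- make_junctions(rep("chr5", 10), seq(1e5, 1e6, 1e5), "tail",
                      rep("chr5", 10), seq(2e6, 2.9e6, 1e5), "head")
  bp <- breakpoints_per_chromosome(j, c("chr5", "chr8"))
  expect_equal(bp$percent[bp$chrom == "chr5"], 100)
  tr <- make_junctions("chr5", 100L, "tail", "chr8", 200L, "head")
  bp2 <- breakpoints_per_chromosome(tr, c("chr5", "chr8"))
  expect_equal(bp2$percent, c(50, 50))
  expect_equal(sum(bp2$percent), 100)
  bp0 <- breakpoints_per_chromosome(j[0, ], c("chr5", "chr8"))
  expect_true(all(bp0$percent == 0))
})

test_that("hallmark panel reflects the simulated mechanism", {
  g <- tiny_genome(seed = 47, sequence = TRUE,
                   chroms = c(chr1 = 2e6, chr2 = 5e5))
  tr <- simulate_shattering(g, k_breakpoints = 20, deletion_fraction = 0.4,
                            seed = 19)
  rj <- render_junction_records(tr, flank_len = 200, seed = 2)
  feats <- junction_features(rj$junctions, rj$reference, flank_len = 200)
  rep_sh <- chromothripsis_report(tr$cn_profile, rj$junctions, feats, "chr1")
  expect_equal(rep_sh$n_orientation_classes, 4)    # all four classes arise
  expect_equal(rep_sh$oscillation_states, 2)       # trisomic <-> disomic
  expect_gt(rep_sh$oscillation_transitions, 2)

  ca <- simulate_chromoanasynthesis(g, n_switches = 6, seed = 23)
  rj2 <- render_junction_records(ca, flank_len = 200, seed = 3)
  f2 <- junction_features(rj2$junctions, rj2$reference, flank_len = 200)
  rep_ca <- chromothripsis_report(ca$cn_profile, rj2$junctions, f2, "chr1")
  expect_gte(rep_ca$oscillation_states, 3)         # >2 copy states
  expect_gt(sum(f2$feature_class == "microhomology"), 0)

  empty <- chromothripsis_report(tr$cn_profile, rj$junctions[0, ],
                                 feats[0, ], "chr1")
  expect_equal(empty$n_junctions_aneuploid, 0)
  expect_true(is.na(empty$orientation_uniformity_p))
})
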