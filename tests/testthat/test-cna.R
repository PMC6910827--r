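seg <- function(chrom, start, end, quantal, clone = "c1")
  data.frame(chrom = chrom, start = start, end = end, quantal = quantal,
             clone_id = clone, stringsAsFactors = FALSE)

test_that("quantal thresholds and aneuploid correction are strict", {
  s <- rbind(seg("chr2", 0, 2e5, 1.2),       # loss on a disomic chromosome
             seg("chr1", 0, 2e5, 3.8),       # corrected 2.8 -> gain
             seg("chr2", 2e5, 4e5, 1.5),     # exactly 1.5 -> no call
             seg("chr2", 4e5, 6e5, 2.5),     # exactly 2.5 -> no call
             seg("chr1", 2e5, 4e5, 3.0))     # corrected 2.0 -> neutral
  calls <- call_quantal_states(s, aneuploid_chrom = "chr1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$state[calls$chrom == "chr2"], "loss")
  expect_equal(calls$state[calls$chrom == "chr1"], "gain")
  expect_equal(calls$corrected_quantal[calls$chrom == "chr1"], 2.8)

  overlapping <- rbind(seg("chr1", 0, 2e5, 1.0), seg("chr1", 1e5, 3e5, 1.0))
  expect_error(call_quantal_states(overlapping, "chr1"), "overlapping")
})

test_that("per-clone aneuploid maps are honoured", {
  s <- rbind(seg("chr1", 0, 2e5, 3.8, "a"), seg("chr1", 0, 2e5, 3.8, "b"))
  calls <- call_quantal_states(s, aneuploid_chrom = c(a = "chr1", b = "chr2"))
  expect_equal(calls$state[calls$clone_id == "a"], "gain")   # 2.8 > 2.5
  expect_equal(calls$corrected_quantal[calls$clone_id == "b"], 3.8)
})

test_that("consecutive merging follows the 90% span-coverage rule", {
  base <- call_quantal_states(
    rbind(seg("chr2", 0, 5e4, 1.0), seg("chr2", 5.5e4, 1e5, 1.0)), "chr1")
  merged <- merge_consecutive(base)
  expect_equal(nrow(merged), 1)                 # 95/100 covered > 0.90
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 1e5)
  expect_equal(merged$corrected_quantal, 1.0)

  sparse <- call_quantal_states(
    rbind(seg("chr2", 0, 1e4, 1.0), seg("chr2", 9e4, 1e5, 1.0)), "chr1")
  expect_equal(nrow(merge_consecutive(sparse)), 2)  # 0.20 coverage

  mixed <- call_quantal_states(
    rbind(seg("chr2", 0, 5e4, 1.0), seg("chr2", 5.5e4, 1e5, 3.5)), "chr1")
  expect_equal(nrow(merge_consecutive(mixed)), 2)   # loss next to gain

  # weighted-mean quantal: 60kb at 1.0 and 30kb at 1.2 over a 90kb+gap span
  w <- call_quantal_states(
    rbind(seg("chr2", 0, 6e4, 1.0), seg("chr2", 6.5e4, 9.5e4, 1.2)), "chr1")
  m <- merge_consecutive(w)
  expect_equal(m$corrected_quantal, (6e4 * 1 + 3e4 * 1.2) / 9e4)

  # idempotence
  expect_identical(merge_consecutive(merge_consecutive(base)),
                   merge_consecutive(base))
  # never merges across chromosomes
  two <- call_quantal_states(
    rbind(seg("chr2", 0, 5e4, 1.0), seg("chr3", 5e4, 1e5, 1.0)), "chr1")
  expect_equal(nrow(merge_consecutive(two)), 2)
})

test_that("size floor is a strict inequality at 100 kb", {
  calls <- data.frame(chrom = "chr1", start = 0,
                      end = c(100001, 100000, 50000))
  expect_equal(filter_min_size(calls)$end, 100001)
  expect_equal(nrow(filter_min_size(calls[0, ])), 0)
})

test_that("reciprocal overlap matches hand-computed fractions", {
  expect_equal(reciprocal_overlap("c", 0, 100, "c", 30, 130), 0.70)
  expect_equal(reciprocal_overlap("c", 0, 100, "c", 0, 100), 1.0)
  expect_equal(reciprocal_overlap("c1", 0, 100, "c2", 0, 100), 0.0)
  expect_equal(reciprocal_overlap("c", 0, 100, "c", 200, 300), 0.0)
  # symmetric and bounded
  set.seed(1)
  for (i in 1:50) {
    a <- sort(sample(1000, 2)); b <- sort(sample(1000, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    x <- reciprocal_overlap("c", a[1], a[2], "c", b[1], b[2])
    y <- reciprocal_overlap("c", b[1], b[2], "c", a[1], a[2])
    expect_equal(x, y)
    expect_gte(x, 0); expect_lte(x, 1)
  }
})

test_that("uniqueness filter matches the spec examples", {
  calls <- rbind(seg("chr1", 0, 1e5, 1, "clone1"),
                 seg("chr1", 0, 1e5, 1, "clone2"))
  u <- unique_cnas(calls)
  expect_false(any(u$unique))      # identical intervals overlap 1.0

  calls <- rbind(seg("chr1", 0, 1e5, 1, "clone1"),
                 seg("chr1", 5e4, 1.5e5, 1, "clone2"))
  u <- unique_cnas(calls)
  expect_true(all(u$unique))       # reciprocal 0.5 < 0.7

  # matching a parental CNA at 0.9 reciprocal overlap makes a call shared
  calls <- seg("chr1", 0, 1e5, 1, "clone1")
  parental <- seg("chr1", 0, 9e4, 1, "parental")
  u <- unique_cnas(calls, parental)
  expect_false(u$unique)
  # a call never competes with its own clone
  same <- rbind(seg("chr1", 0, 1e5, 1, "clone1"),
                seg("chr1", 1e4, 1.1e5, 1, "clone1"))
  expect_true(all(unique_cnas(same)$unique))
})

test_that("uniqueness filter equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (rep in 1:150) {
    n_clones <- sample(2:4, 1)
    rows <- do.call(rbind, lapply(seq_len(n_clones), function(cl) {
      n <- sample(1:6, 1)
      st <- sample(seq(0, 9e5, by = 1e4), n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                 start = st, end = st + sample(seq(5e4, 3e5, by = 1e4), n,
                                               replace = TRUE),
                 quantal = 1, clone_id = paste0("c", cl),
                 stringsAsFactors = FALSE)
    }))
    par_n <- sample(0:3, 1)
    parental <- if (par_n > 0) {
      st <- sample(seq(0, 9e5, by = 1e4), par_n)
      data.frame(chrom = sample(c("chr1", "chr2"), par_n, replace = TRUE),
                 start = st, end = st + 1e5, stringsAsFactors = FALSE)
    } else NULL
    got <- unique_cnas(rows, parental)$unique
    want <- oracle_unique_cnas(rows, parental)
    expect_identical(got, want)
  }
})

test_that("per-chromosome CNA partition counts and forwards sizes", {
  calls <- rbind(seg("chr1", 0, 3e5, 1, "a"), seg("chr1", 5e5, 6e5, 1, "a"),
                 seg("chr2", 0, 2e5, 1, "a"), seg("chr1", 0, 4e5, 1, "b"))
  calls$unique <- c(TRUE, TRUE, TRUE, FALSE)
  res <- count_cnas_per_chromosome(calls, "chr1")
  expect_equal(res$n_aneuploid, 2)
  expect_equal(res$n_other, 1)
  expect_setequal(res$sizes_aneuploid, c(3e5, 1e5))
  expect_equal(res$sizes_other, 2e5)
  empty <- count_cnas_per_chromosome(calls[0, ], "chr1")
  expect_equal(empty$n_aneuploid, 0)
  expect_equal(empty$n_other, 0)
})
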