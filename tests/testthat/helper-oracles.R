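# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) all-pairs uniqueness filter: a call is unique iff it has reciprocal
# overlap < threshold with every call of every other clone and every
# parental call. Pure loops, no interval machinery.
oracle_unique_cnas <- function(calls, parental_calls = NULL, threshold = 0.70) {
  ro <- function(c1, s1, e1, c2, s2, e2) {
    if (c1 != c2) return(0)
    ov <- max(0, min(e1, e2) - max(s1, s2))
    min(ov / (e1 - s1), ov / (e2 - s2))
  }
  unique_flag <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (calls$clone_id[i] == calls$clone_id[j]) next
      if (ro(calls$chrom[i], calls$start[i], calls$end[i],
             calls$chrom[j], calls$start[j], calls$end[j]) >= threshold) {
        unique_flag[i] <- FALSE
        break
      }
    }
    if (unique_flag[i] && !is.null(parental_calls)) {
      for (j in seq_len(nrow(parental_calls))) {
        if (ro(calls$chrom[i], calls$start[i], calls$end[i],
               parental_calls$chrom[j], parental_calls$start[j],
               parental_calls$end[j]) >= threshold) {
          unique_flag[i] <- FALSE
          break
        }
      }
    }
  }
  unique_flag
}

# try-every-split junction classifier: for every (l, r) with l + r <= n,
# test validity by direct substring comparison against the flanks (outer
# ends aligned); maximize l + r, count zero-insertion splits.
oracle_junction_split <- function(contig, left_flank, right_flank,
                                  min_anchor = 20) {
  n <- nchar(contig)
  fl <- nchar(left_flank)
  fr <- nchar(right_flank)
  valid_l <- logical(min(n, fl) + 1)
  for (l in 0:min(n, fl))
    valid_l[l + 1] <- substr(contig, 1, l) == substr(left_flank, 1, l)
  valid_r <- logical(min(n, fr) + 1)
  for (r in 0:min(n, fr))
    valid_r[r + 1] <- substr(contig, n - r + 1, n) ==
      substr(right_flank, fr - r + 1, fr)
  best <- -1; best_l <- 0; best_r <- 0; n_zero_splits <- 0
  # max valid r at or below each bound, so every (l, r) pair is considered
  # without the quadratic inner loop
  rs <- which(valid_r) - 1
  rs <- rs[rs <= n]
  max_r_upto <- rep(-1, n + 1)
  max_r_upto[rs + 1] <- rs
  max_r_upto <- cummax(max_r_upto)
  for (l in 0:(length(valid_l) - 1)) {
    if (!valid_l[l + 1] || l > n) next
    r_zero <- n - l
    if (r_zero < length(valid_r) && valid_r[r_zero + 1])
      n_zero_splits <- n_zero_splits + 1
    r <- max_r_upto[n - l + 1]
    if (r >= 0 && l + r > best) { best <- l + r; best_l <- l; best_r <- r }
  }
  if (best_l < min_anchor || best_r < min_anchor)
    return(list(microhomology_len = NA_integer_, insertion_len = NA_integer_,
                feature_class = "unclassifiable"))
  if (n_zero_splits > 0) {
    mh <- n_zero_splits - 1; ins <- 0
  } else {
    mh <- 0; ins <- n - best
  }
  cls <- if (mh == 0 && ins == 0) "blunt"
         else if (mh > 0) "microhomology" else "insertion"
  list(microhomology_len = mh, insertion_len = ins, feature_class = cls)
}

# plain-character exact substring scan for a templated insert (forward and
# reverse complement), independent of Biostrings
oracle_find_template <- function(insert_seq, reference) {
  rc <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  for (chrom in names(reference)) {
    for (pat in c(insert_seq, rc(insert_seq))) {
      hit <- regexpr(pat, reference[[chrom]], fixed = TRUE)
      if (hit > 0) return(TRUE)
    }
  }
  FALSE
}

# small shared genome fixtures
tiny_genome <- function(seed = 1, sequence = FALSE,
                        chroms = c(chr1 = 2e6, chr2 = 1e6)) {
  simulate_reference(
    genome_spec(chromosomes = chroms, aneuploid_chrom = "chr1"),
    seed = seed, sequence = sequence)
}
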