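# Breakpoint junction forensics: orientation classes, microhomology /
# insertion calling from junction contigs, templated-insertion detection,
# copy-number oscillation statistics and the chromothripsis hallmark panel.

#' Classify junction orientation
#'
#' Breakends are ordered by (chrom, pos); the label is
#' `side(lower)_side(higher)`. Under the strand-to-side convention a simple
#' deletion is `tail_head`, a tandem duplication `head_tail`, and an
#' inversion contributes one `head_head` and one `tail_tail` junction.
#' Inter-chromosomal junctions are labeled by the same rule and flagged.
#'
#' @param junctions a `junction_table` (see [make_junctions()]).
#' @return data.frame with `orientation` and logical `translocation`.
#' @export
classify_orientation <- function(junctions) {
  canon <- make_junctions(junctions$chrom_a, junctions$pos_a, junctions$side_a,
                          junctions$chrom_b, junctions$pos_b, junctions$side_b,
                          name = junctions$name)
  data.frame(name = canon$name, orientation = canon$orientation,
             translocation = canon$chrom_a != canon$chrom_b,
             stringsAsFactors = FALSE)
}

.orientation_classes <- c("tail_head", "head_tail", "head_head", "tail_tail")

#' Orientation spectrum of a junction set
#'
#' Counts junctions per orientation class, excluding intra-chromosomal
#' junctions spanning `min_span` or less (strict >); translocations are
#' always counted.
#'
#' @param junctions `junction_table`.
#' @param min_span minimum intra-chromosomal span in bp (default 10 kb).
#' @return list with `counts` (named vector over the four classes) and
#'   `total`.
#' @export
orientation_spectrum <- function(junctions, min_span = 1e4) {
  keep <- is.na(junctions$span) | junctions$span > min_span
  j <- junctions[keep, , drop = FALSE]
  counts <- vapply(.orientation_classes,
                   function(cl) sum(j$orientation == cl), integer(1))
  list(counts = counts, total = sum(counts))
}

#' Multinomial goodness-of-fit test against uniform orientations
#'
#' Chi-square statistic against expected counts `total/4` in each of the
#' four orientation classes (df = 3). For small totals (below
#' `exact_threshold`) the p-value is computed by full enumeration of
#' multinomial outcomes with statistic at least as extreme; otherwise the
#' asymptotic chi-square tail is used. Pooling across clones is a test on
#' the summed counts.
#'
#' @param counts numeric vector of 4 orientation counts (or an
#'   [orientation_spectrum()] result).
#' @param exact_threshold totals below this use exact enumeration
#'   (default 20).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
multinomial_uniform_test <- function(counts, exact_threshold = 20,
                                     method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (is.list(counts)) counts <- counts$counts
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("orientation test needs at least one junction", call. = FALSE)
  E <- n / 4
  stat <- sum((counts - E)^2 / E)
  use_exact <- method == "exact" || (method == "auto" && n < exact_threshold)
  if (use_exact) {
    grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    grid <- grid[grid$a + grid$b + grid$c <= n, ]
    grid$d <- n - grid$a - grid$b - grid$c
    m <- as.matrix(grid)
    stats <- rowSums((m - E)^2) / E
    probs <- apply(m, 1, function(x) stats::dmultinom(x, prob = rep(0.25, 4)))
    p <- sum(probs[stats >= stat - 1e-9])
    meth <- "exact"
  } else {
    p <- pchisq(stat, df = 3, lower.tail = FALSE)
    meth <- "asymptotic"
  }
  list(statistic = stat, df = 3, p_value = min(1, p), method = meth)
}

#' Resolve microhomology / insertion at a junction from its contig
#'
#' Splits the contig into `L + I + R` maximizing `|L| + |R|`, where `L` must
#' match the left flank (aligned at their common outer end) and `R` the
#' right flank (aligned at their common outer end), exact matching only.
#' Microhomology is junction-shift ambiguity: the number of distinct valid
#' zero-insertion splits minus one. Ties between splits are resolved toward
#' the smaller insertion automatically by the maximality rule. Flanks must
#' be extracted at the flank length used to assemble the contig (see
#' [junction_flanks()]), so the outer ends align.
#'
#' @param contig junction-spanning sequence.
#' @param left_flank,right_flank oriented reference flanks.
#' @param min_anchor minimum matched bases required on each side
#'   (default 20); weaker matches are reported unclassifiable.
#' @return list with `microhomology_len`, `insertion_len`, `feature_class`
#'   (`blunt`/`microhomology`/`insertion`/`unclassifiable`) and the split
#'   anchors `left_match`, `right_match`.
#' @export
junction_homology <- function(contig, left_flank, right_flank,
                              min_anchor = 20) {
  n <- nchar(contig)
  if (n < 2 * min_anchor)
    stop("contig shorter than twice the minimum anchor", call. = FALSE)
  cc <- strsplit(contig, "")[[1]]
  lc <- strsplit(left_flank, "")[[1]]
  rc <- strsplit(right_flank, "")[[1]]
  # longest prefix of contig matching the left flank (outer ends aligned)
  k <- min(n, length(lc))
  eq <- cc[seq_len(k)] == lc[seq_len(k)]
  l_max <- if (all(eq)) k else which(!eq)[1] - 1L
  # longest suffix of contig matching the right flank (outer ends aligned)
  k <- min(n, length(rc))
  eq <- rev(cc)[seq_len(k)] == rev(rc)[seq_len(k)]
  r_max <- if (all(eq)) k else which(!eq)[1] - 1L
  if (l_max < min_anchor || r_max < min_anchor)
    return(list(microhomology_len = NA_integer_, insertion_len = NA_integer_,
                feature_class = "unclassifiable",
                left_match = l_max, right_match = r_max))
  if (l_max + r_max >= n) {
    # zero-insertion splits exist; count the distinct split positions
    n_splits <- min(l_max, n) - max(0, n - r_max) + 1L
    mh <- n_splits - 1L
    ins <- 0L
  } else {
    mh <- 0L
    ins <- n - l_max - r_max
  }
  cls <- if (mh == 0L && ins == 0L) "blunt"
         else if (mh > 0L) "microhomology" else "insertion"
  list(microhomology_len = as.integer(mh), insertion_len = as.integer(ins),
       feature_class = cls, left_match = l_max, right_match = r_max)
}

#' Detect a templated insertion by exact reference search
#'
#' Searches the insert sequence and its reverse complement against the
#' reference. Templated iff a full-length exact hit exists and the insert is
#' at least `min_len` bp; the first hit by coordinate is reported, with a
#' flag when several exist.
#'
#' @param insert_seq inserted sequence at a junction.
#' @param reference named character vector of chromosome sequences.
#' @param min_len minimum insert length to call templated (default 20).
#' @return list with `templated`, `template_chrom`, `template_start`,
#'   `template_end` (0-based half-open), `template_strand`,
#'   `multiple_hits`.
#' @export
detect_templated_insertion <- function(insert_seq, reference, min_len = 20) {
  none <- list(templated = FALSE, template_chrom = NA_character_,
               template_start = NA_integer_, template_end = NA_integer_,
               template_strand = NA_character_, multiple_hits = FALSE)
  if (nchar(insert_seq) < min_len) return(none)
  subject <- Biostrings::DNAStringSet(reference)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- Biostrings::DNAString(insert_seq)
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    m <- Biostrings::vmatchPattern(pat, subject)
    for (ci in seq_along(m)) {
      ir <- m[[ci]]
      if (length(ir))
        hits[[length(hits) + 1]] <- data.frame(
          chrom = names(reference)[ci],
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(none)
  h <- do.call(rbind, hits)
  h <- h[order(h$chrom, h$start), , drop = FALSE]
  list(templated = TRUE, template_chrom = h$chrom[1],
       template_start = h$start[1], template_end = h$end[1],
       template_strand = h$strand[1], multiple_hits = nrow(h) > 1)
}

#' Junction-sequence features for a junction set
#'
#' Runs [junction_homology()] (and, for insertions,
#' [detect_templated_insertion()]) for every junction carrying a contig.
#' Junctions without a contig are skipped, not errors.
#'
#' @param junctions `junction_table` with contigs.
#' @param reference named character vector of chromosome sequences.
#' @param flank_len flank length used when the contigs were assembled.
#' @param min_anchor see [junction_homology()].
#' @param templated_min_len see [detect_templated_insertion()].
#' @return data.frame, one row per classified junction.
#' @export
junction_features <- function(junctions, reference, flank_len = 300,
                              min_anchor = 20, templated_min_len = 20) {
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    if (is.na(junctions$contig[i])) next
    fl <- junction_flanks(junctions$chrom_a[i], junctions$pos_a[i],
                          junctions$side_a[i], junctions$chrom_b[i],
                          junctions$pos_b[i], junctions$side_b[i],
                          reference, flank_len)
    jh <- junction_homology(junctions$contig[i], fl$left, fl$right, min_anchor)
    templ <- list(templated = FALSE, template_chrom = NA_character_,
                  template_start = NA_integer_, template_end = NA_integer_,
                  template_strand = NA_character_, multiple_hits = FALSE)
    if (!is.na(jh$insertion_len) && jh$insertion_len > 0) {
      ins <- substr(junctions$contig[i], jh$left_match + 1,
                    nchar(junctions$contig[i]) - jh$right_match)
      templ <- detect_templated_insertion(ins, reference, templated_min_len)
    }
    rows[[length(rows) + 1]] <- data.frame(
      name = junctions$name[i],
      microhomology_len = jh$microhomology_len,
      insertion_len = jh$insertion_len,
      feature_class = jh$feature_class,
      templated = templ$templated,
      template_chrom = templ$template_chrom,
      template_start = templ$template_start,
      template_end = templ$template_end,
      template_strand = templ$template_strand,
      multiple_hits = templ$multiple_hits,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(name = character(), microhomology_len = integer(),
                      insertion_len = integer(), feature_class = character(),
                      templated = logical(), template_chrom = character(),
                      template_start = integer(), template_end = integer(),
                      template_strand = character(), multiple_hits = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-number oscillation statistics along one chromosome
#'
#' @param cn ordered vector of constant-copy segment values (or a profile
#'   data.frame with a `cn_total` column).
#' @return list with `n_transitions` (adjacent state changes) and
#'   `n_distinct_states`.
#' @export
copy_number_oscillations <- function(cn) {
  if (is.data.frame(cn)) cn <- cn$cn_total
  if (!length(cn)) return(list(n_transitions = 0L, n_distinct_states = 0L))
  list(n_transitions = sum(diff(cn) != 0),
       n_distinct_states = length(unique(cn)))
}

#' Breakpoint counts and percentages per chromosome
#'
#' Each junction contributes both breakends to their chromosomes.
#'
#' @param junctions `junction_table`.
#' @param chromosomes character vector of chromosome names to report
#'   (zero-count chromosomes included).
#' @return data.frame `chrom n percent`; percentages sum to 100 when any
#'   breakpoints exist.
#' @export
breakpoints_per_chromosome <- function(junctions, chromosomes) {
  be <- c(junctions$chrom_a, junctions$chrom_b)
  n <- vapply(chromosomes, function(ch) sum(be == ch), integer(1))
  pct <- if (sum(n) > 0) 100 * n / sum(n) else rep(0, length(n))
  data.frame(chrom = chromosomes, n = as.integer(n), percent = pct,
             stringsAsFactors = FALSE)
}

#' Chromothripsis hallmark panel for one clone
#'
#' Summarizes the hallmarks without asserting a binary verdict: junction
#' counts on the aneuploid versus other chromosomes, orientation classes
#' present and their uniformity-test p-value, copy-number oscillation
#' statistics on the aneuploid chromosome, and the junction feature-class
#' spectrum.
#'
#' @param profile copy-number profile (`chrom`, ordered segments,
#'   `cn_total`).
#' @param junctions `junction_table` for the clone.
#' @param features output of [junction_features()] (may be empty).
#' @param aneuploid_chrom aneuploid chromosome name.
#' @param min_span span filter for the orientation spectrum (default 10 kb).
#' @return list summarizing the hallmark panel.
#' @export
chromothripsis_report <- function(profile, junctions, features,
                                  aneuploid_chrom, min_span = 1e4) {
  on_an <- junctions$chrom_a == aneuploid_chrom |
           junctions$chrom_b == aneuploid_chrom
  spect <- orientation_spectrum(junctions, min_span)
  osc <- copy_number_oscillations(
    profile[profile$chrom == aneuploid_chrom, , drop = FALSE])
  p_orient <- if (spect$total > 0)
    multinomial_uniform_test(spect$counts)$p_value else NA_real_
  feat_counts <- if (nrow(features))
    table(factor(features$feature_class,
                 levels = c("blunt", "microhomology", "insertion",
                            "unclassifiable")))
  else table(factor(character(),
                    levels = c("blunt", "microhomology", "insertion",
                               "unclassifiable")))
  list(n_junctions_aneuploid = sum(on_an),
       n_junctions_other = sum(!on_an),
       orientation_counts = spect$counts,
       n_orientation_classes = sum(spect$counts > 0),
       orientation_uniformity_p = p_orient,
       oscillation_transitions = osc$n_transitions,
       oscillation_states = osc$n_distinct_states,
       feature_class_counts = as.vector(feat_counts),
       feature_class_names = names(feat_counts),
       microhomology_lengths = features$microhomology_len[
         nrow(features) > 0 & features$feature_class == "microhomology"],
       insertion_lengths = features$insertion_len[
         nrow(features) > 0 & features$feature_class == "insertion"])
}
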