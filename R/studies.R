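# End-to-end study workflows: each runs one of the package's headline
# analyses on simulated data at desk scale and returns the quantities the
# study measures. The analysis/ drivers, the test suite and the acceptance
# script all call these.

#' End-to-end copy-number recovery study
#'
#' Simulates shattering of the transferred homolog on the default toy genome
#' (three 10 Mb chromosomes), renders noise-free binned quantal segments,
#' runs calling plus merging, and matches the calls against the true CNA
#' intervals at bin resolution.
#'
#' @param seed RNG seed.
#' @param k_breakpoints,deletion_fraction shattering parameters
#'   (defaults 20 and 0.4).
#' @param bin_size quantal bin width (default 50 kb).
#' @param noise_sd quantal noise (default 0: identifiability conditions).
#' @return list with `n_true`, `n_called`, `n_recovered`, `n_false`,
#'   `recovery_rate`, plus the call and truth tables.
#' @export
study_cna_recovery <- function(seed, k_breakpoints = 20,
                               deletion_fraction = 0.4, bin_size = 5e4,
                               noise_sd = 0) {
  genome <- simulate_reference(genome_spec(), seed = seed, sequence = FALSE)
  truth <- simulate_shattering(genome, k_breakpoints, deletion_fraction,
                               seed = seed + 1)
  segs <- render_quantal_segments(truth, bin_size = bin_size,
                                  noise_sd = noise_sd, seed = seed + 2)
  calls <- merge_consecutive(call_quantal_states(segs, "chr1"))
  # truth at bin resolution: snap the whole copy-number profile to the bin
  # grid exactly as the renderer does (sub-bin features are unrepresentable
  # in the rendered input), then take the deviant runs
  tc <- do.call(rbind, lapply(unique(truth$cn_profile$chrom), function(ch) {
    rows <- truth$cn_profile[truth$cn_profile$chrom == ch, , drop = FALSE]
    snapped <- .snap_profile(rows, bin_size,
                             truth$genome$spec$chromosomes[[ch]])
    base <- if (ch == "chr1") 3L else 2L
    dev <- snapped[snapped$cn != base, , drop = FALSE]
    if (!nrow(dev)) return(NULL)
    data.frame(chrom = ch, start = dev$start, end = dev$end,
               state = ifelse(dev$cn < base, "loss", "gain"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tc)) tc <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), state = character())
  # the method's own >90% span-coverage merging applies to the truth too:
  # two true CNAs separated by a gap under 10% of their joint span are, by
  # design, reported as one call
  if (nrow(tc)) {
    tc$quantal <- ifelse(tc$state == "loss", 2, 4)
    tc$corrected_quantal <- tc$quantal - 1
    tc$clone_id <- "truth"
    tc <- merge_consecutive(tc, coverage_threshold = 0.90)
  }
  recovered <- vapply(seq_len(nrow(tc)), function(i) {
    any(calls$chrom == tc$chrom[i] & calls$state == tc$state[i] &
        abs(calls$start - tc$start[i]) <= bin_size &
        abs(calls$end - tc$end[i]) <= bin_size)
  }, logical(1))
  false_pos <- vapply(seq_len(nrow(calls)), function(i) {
    !any(tc$chrom == calls$chrom[i] & tc$state == calls$state[i] &
         abs(tc$start - calls$start[i]) <= bin_size &
         abs(tc$end - calls$end[i]) <= bin_size)
  }, logical(1))
  list(n_true = nrow(tc), n_called = nrow(calls),
       n_recovered = sum(recovered), n_false = sum(false_pos),
       recovery_rate = if (nrow(tc)) mean(recovered) else NA_real_,
       calls = calls, truth = tc)
}

#' Haplotype-assignment parameter-recovery study
#'
#' Plants CNAs (transferred and endogenous, deletions and duplications) on a
#' 30 Mb aneuploid chromosome, keeping CNA windows that contain at least
#' `min_informative` phase-informative SNPs, renders parental, intact
#' trisomic baseline and clone BAF profiles at the given noise, and scores
#' the transferred/endogenous verdicts against the planted truth.
#'
#' @param seed RNG seed.
#' @param noise_sd BAF/LRR noise (study condition 0.03).
#' @param n_cnas number of planted CNAs (default 100).
#' @param min_informative minimum informative SNPs per CNA window
#'   (default 5).
#' @param p_transferred fraction of CNAs planted on the transferred homolog.
#' @return list with `accuracy` (verdict equals planted homolog),
#'   `n_ambiguous`, `n_correct`, `n` and the per-CNA verdict table.
#' @export
study_haplotype_recovery <- function(seed, noise_sd = 0.03, n_cnas = 100,
                                     min_informative = 5,
                                     p_transferred = 0.7) {
  spec <- genome_spec(chromosomes = c(chr1 = 3e7, chr2 = 1e7, chr3 = 1e7),
                      aneuploid_chrom = "chr1")
  genome <- simulate_reference(spec, seed = seed, sequence = FALSE)
  set.seed(seed + 1)
  # candidate 200 kb windows on a 250 kb grid; keep those with enough
  # informative SNPs (the study condition)
  cand_start <- seq(5e4, 3e7 - 2.5e5, by = 2.5e5)
  info_pos <- genome$snps$pos[genome$snps$chrom == "chr1" &
                              genome$snps$informative]
  n_info <- vapply(cand_start, function(s)
    sum(info_pos >= s & info_pos < s + 2e5), integer(1))
  ok <- which(n_info >= min_informative)
  if (length(ok) < n_cnas)
    stop("genome too small for ", n_cnas, " qualifying CNA windows",
         call. = FALSE)
  starts <- cand_start[sort(sample(ok, n_cnas))]
  ev <- data.frame(chrom = "chr1", start = starts, end = starts + 2e5,
                   homolog = sample(c("transferred", "endogenous"), n_cnas,
                                    TRUE, prob = c(p_transferred,
                                                   1 - p_transferred)),
                   kind = sample(c("deletion", "duplication"), n_cnas, TRUE),
                   stringsAsFactors = FALSE)
  truth <- plant_cna_events(genome, ev)
  prof <- render_snp_profile(truth, noise_sd = noise_sd, seed = seed + 2)
  base <- render_snp_profile(simulate_intact(genome), noise_sd = noise_sd,
                             seed = seed + 3)
  info <- find_phase_informative_snps(prof$parental, base$clone, "chr1")
  ev$state <- ifelse(ev$kind == "deletion", "loss", "gain")
  ev$verdict <- vapply(seq_len(n_cnas), function(i)
    assign_cna_allele_baf(ev[i, ], info, prof$clone)$verdict, character(1))
  correct <- ev$verdict == ev$homolog
  list(accuracy = mean(correct), n_correct = sum(correct),
       n_ambiguous = sum(ev$verdict == "ambiguous"), n = n_cnas,
       n_informative_snps = nrow(info), events = ev)
}

#' Junction forensics recovery study
#'
#' Simulates a heavily shattered transferred homolog with planted junction
#' features (microhomology 1-15 bp, non-templated insertions 1-30 bp,
#' templated insertions 50-200 bp), renders contigs, classifies them
#' against the (edited) reference, and scores agreement with the planted
#' truth. Also scores orientation labels of canonical deletion, tandem
#' duplication and inversion events against their textbook classes.
#'
#' @param seed RNG seed.
#' @param k_breakpoints shattering cuts (default 560, yielding roughly 500
#'   junctions).
#' @param flank_len contig flank length (default 300 bp).
#' @return list with `n_junctions`, `feature_agreement` (fraction with
#'   exactly recovered homology and insertion lengths),
#'   `templated_detection_rate`, `orientation_match_rate`, and the merged
#'   per-junction table.
#' @export
study_junction_forensics <- function(seed, k_breakpoints = 560,
                                     flank_len = 300) {
  spec <- genome_spec(chromosomes = c(chr1 = 1e7, chr2 = 1e6),
                      aneuploid_chrom = "chr1")
  genome <- simulate_reference(spec, seed = seed, sequence = TRUE)
  truth <- simulate_shattering(
    genome, k_breakpoints, deletion_fraction = 0.1, seed = seed + 1,
    features = junction_feature_config(p_blunt = 0.2, p_microhomology = 0.5,
                                       p_insertion = 0.3, p_templated = 0.5))
  rj <- render_junction_records(truth, flank_len = flank_len, seed = seed + 2)
  feats <- junction_features(rj$junctions, rj$reference,
                             flank_len = flank_len)
  m <- merge(rj$features, feats, by = "name",
             suffixes = c("_truth", "_called"))
  agree <- m$mh_len == m$microhomology_len & m$ins_len == m$insertion_len
  tmpl <- m[m$ins_len >= 50 & m$templated_truth, , drop = FALSE]
  # canonical event types
  set.seed(seed + 3)
  n_ev <- 30
  labels <- character(0); expected <- character(0)
  for (i in seq_len(n_ev)) {
    s <- sample(seq(5e5, 8e6, by = 1e4), 1); e <- s + sample(seq(1e5, 1e6, by = 1e4), 1)
    type <- c("deletion", "tandem_duplication", "inversion")[1 + i %% 3]
    ev <- simulate_simple_event(genome, type, s, e, seed = seed + 10 + i)
    labels <- c(labels, sort(ev$junctions$orientation))
    expected <- c(expected, switch(type, deletion = "tail_head",
                                   tandem_duplication = "head_tail",
                                   inversion = c("head_head", "tail_tail")))
  }
  list(n_junctions = nrow(m),
       feature_agreement = mean(agree),
       templated_detection_rate =
         if (nrow(tmpl)) mean(tmpl$templated_called) else NA_real_,
       orientation_match_rate = mean(labels == expected),
       junctions = m, rendered = rj)
}

#' Enrichment-test calibration study
#'
#' Generates datasets under the null (CNAs placed by the same weighted
#' scheme the test assumes) and collects the permutation p-values, plus the
#' two-chromosome closed-form toy case. Each null dataset draws its own
#' genome (chromosome lengths), clone ploidies and CNA counts so the
#' attained p-values — discrete within any single scenario — mix over a
#' family of null scenarios, which is what a uniformity check can sensibly
#' be applied to.
#'
#' @param seed RNG seed.
#' @param n_datasets number of null datasets (default 200).
#' @param n_perm permutations per dataset (default 1e4).
#' @return list with `p_values`, `type1_at_05`, `ks_p` (uniformity),
#'   `toy_p` (closed-form 0.6 case at 1e5 permutations) and `toy_exact`.
#' @export
study_enrichment_calibration <- function(seed, n_datasets = 200,
                                         n_perm = 1e4) {
  set.seed(seed)
  seeds <- sample.int(2^30, n_datasets + 1)
  pvals <- vapply(seq_len(n_datasets), function(i) {
    set.seed(seeds[i])
    n_chr <- sample(3:8, 1)
    genome <- data.frame(chrom = paste0("chr", seq_len(n_chr)),
                         length = round(runif(n_chr, 2e6, 5e7)))
    n_cl <- sample(2:5, 1)
    clones <- paste0("cl", seq_len(n_cl))
    amap <- stats::setNames(sample(genome$chrom, n_cl, replace = TRUE),
                            clones)
    ploidy <- stats::setNames(sample(c(3, 4), n_cl, replace = TRUE), clones)
    cnas <- simulate_null_cnas(sample(3:20, n_cl, replace = TRUE), clones,
                               genome, amap, ploidy_map = ploidy)
    permutation_enrichment(cnas, genome, amap, n_permutations = n_perm,
                           seed = seeds[i] + 1,
                           ploidy_map = ploidy)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  toy_genome <- data.frame(chrom = c("A", "B"), length = c(1e7, 1e7))
  toy <- data.frame(chrom = "A", clone_id = "c1")
  toy_p <- permutation_enrichment(toy, toy_genome, c(c1 = "A"),
                                  n_permutations = 1e5,
                                  seed = seeds[n_datasets + 1])$p_value
  list(p_values = pvals, type1_at_05 = mean(pvals <= 0.05),
       ks_p = ks$p.value, toy_p = toy_p,
       toy_exact = enrichment_exact_tail(toy, toy_genome,
                                         c(c1 = "A"))$p_value)
}
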