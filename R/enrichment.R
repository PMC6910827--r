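# Chromosome-size- and ploidy-aware permutation test for enrichment of de
# novo CNAs on the aneuploid chromosome, an exact Poisson-binomial
# cross-check, and the CNA size comparison.

# per-CNA probability of landing on its clone's aneuploid chromosome under
# weighted random reassignment
.landing_probs <- function(cnas, genome, aneuploid_map, ploidy_map = NULL,
                           weighting = "length_times_copy") {
  if (!all(cnas$clone_id %in% names(aneuploid_map)))
    stop("clone(s) without an aneuploid-chromosome mapping: ",
         paste(setdiff(unique(cnas$clone_id), names(aneuploid_map)),
               collapse = ", "), call. = FALSE)
  lens <- stats::setNames(as.numeric(genome$length), genome$chrom)
  vapply(seq_len(nrow(cnas)), function(i) {
    cl <- cnas$clone_id[i]
    an <- aneuploid_map[[cl]]
    copies <- stats::setNames(rep(2, length(lens)), names(lens))
    copies[an] <- if (!is.null(ploidy_map) && cl %in% names(ploidy_map))
      ploidy_map[[cl]] else 3
    w <- if (weighting == "length_times_copy") lens * copies else lens
    unname(w[an] / sum(w))
  }, numeric(1))
}

#' Permutation test for CNA enrichment on the aneuploid chromosome
#'
#' Each observed CNA is independently reassigned to a chromosome with
#' probability proportional to chromosome weight (length times copy number
#' under the default weighting, with the clone's aneuploid chromosome at
#' copy 3 or 4 and all others at 2). The statistic is the number of CNAs
#' landing on their own clone's aneuploid chromosome; the empirical p-value
#' uses the add-one correction `(1 + #{null >= observed}) / (1 + n_perm)` so
#' it is never exactly zero.
#'
#' @param cnas data.frame with `chrom` and `clone_id` (one row per unique
#'   CNA).
#' @param genome data.frame `chrom length`.
#' @param aneuploid_map named vector/list `clone_id -> aneuploid chromosome`.
#' @param n_permutations number of permutations (default 1e6).
#' @param seed RNG seed.
#' @param ploidy_map optional named vector `clone_id -> aneuploid copy
#'   number` (3 trisomic, 4 tetrasomic; default 3).
#' @param weighting `"length_times_copy"` (default) or `"length_only"`.
#' @return list with `p_value`, `observed`, `n`, `null_mean`, `null_sd`,
#'   `n_permutations`.
#' @export
permutation_enrichment <- function(cnas, genome, aneuploid_map,
                                   n_permutations = 1e6, seed = 1,
                                   ploidy_map = NULL,
                                   weighting = c("length_times_copy",
                                                 "length_only")) {
  weighting <- match.arg(weighting)
  stopifnot(n_permutations >= 1)
  probs <- .landing_probs(cnas, genome, aneuploid_map, ploidy_map, weighting)
  an_of <- unlist(aneuploid_map)[cnas$clone_id]
  observed <- sum(cnas$chrom == an_of)
  set.seed(seed)
  # CNAs sharing a landing probability are exchangeable: draw their joint
  # contribution binomially instead of per-CNA Bernoulli draws
  null_stat <- integer(n_permutations)
  for (p in unique(probs)) {
    k <- sum(probs == p)
    null_stat <- null_stat + rbinom(n_permutations, k, p)
  }
  p_emp <- (1 + sum(null_stat >= observed)) / (1 + n_permutations)
  list(p_value = p_emp, observed = observed, n = nrow(cnas),
       null_mean = mean(null_stat), null_sd = stats::sd(null_stat),
       n_permutations = n_permutations)
}

#' Exact enrichment tail probability (Poisson-binomial)
#'
#' Exact `P(statistic >= observed)` where the statistic is the sum of
#' independent but not identically distributed Bernoulli landings, computed
#' by dynamic-programming convolution over the per-CNA landing
#' probabilities. Intended for small cases as an independent cross-check of
#' the permutation engine.
#'
#' @param cnas,genome,aneuploid_map,ploidy_map,weighting as in
#'   [permutation_enrichment()].
#' @param observed observed count; defaults to the count in `cnas`.
#' @return list with `p_value` (exact tail), `observed`, `probs`.
#' @export
enrichment_exact_tail <- function(cnas, genome, aneuploid_map,
                                  ploidy_map = NULL,
                                  weighting = "length_times_copy",
                                  observed = NULL) {
  probs <- .landing_probs(cnas, genome, aneuploid_map, ploidy_map, weighting)
  if (is.null(observed)) {
    an_of <- unlist(aneuploid_map)[cnas$clone_id]
    observed <- sum(cnas$chrom == an_of)
  }
  pmf <- poisson_binomial_pmf(probs)
  p <- sum(pmf[(observed + 1):length(pmf)])
  list(p_value = min(1, p), observed = observed, probs = probs)
}

#' Poisson-binomial probability mass function
#'
#' @param probs vector of Bernoulli success probabilities.
#' @return numeric vector of length `length(probs) + 1`; element `k + 1` is
#'   `P(sum = k)`.
#' @export
poisson_binomial_pmf <- function(probs) {
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Simulate a null CNA placement
#'
#' Places `n_cnas` CNAs on chromosomes by the same weighted scheme the
#' permutation test uses — the null hypothesis of no aneuploid-chromosome
#' enrichment. Used for calibration studies.
#'
#' @param n_cnas number of CNAs per clone (recycled over clones).
#' @param clones clone identifiers.
#' @param genome data.frame `chrom length`.
#' @param aneuploid_map named vector `clone_id -> aneuploid chromosome`.
#' @param ploidy_map optional named vector of aneuploid copy numbers.
#' @param weighting as in [permutation_enrichment()].
#' @return data.frame `chrom clone_id`.
#' @export
simulate_null_cnas <- function(n_cnas, clones, genome, aneuploid_map,
                               ploidy_map = NULL,
                               weighting = "length_times_copy") {
  lens <- stats::setNames(as.numeric(genome$length), genome$chrom)
  rows <- lapply(seq_along(clones), function(i) {
    cl <- clones[i]
    n <- n_cnas[((i - 1) %% length(n_cnas)) + 1]
    copies <- stats::setNames(rep(2, length(lens)), names(lens))
    copies[aneuploid_map[[cl]]] <-
      if (!is.null(ploidy_map) && cl %in% names(ploidy_map))
        ploidy_map[[cl]] else 3
    w <- if (weighting == "length_times_copy") lens * copies else lens
    data.frame(chrom = sample(names(lens), n, replace = TRUE,
                              prob = w / sum(w)),
               clone_id = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare CNA sizes on the transferred versus other chromosomes
#'
#' Reports group medians and a two-sided rank-sum (Wilcoxon) test: exact
#' null enumeration when both groups have at most 10 observations and no
#' ties, normal approximation with tie correction otherwise.
#'
#' @param sizes_transferred,sizes_other CNA sizes in bp (both non-empty).
#' @return list with `median_transferred`, `median_other`, `p_value`,
#'   `method`.
#' @export
cna_size_comparison <- function(sizes_transferred, sizes_other) {
  if (!length(sizes_transferred) || !length(sizes_other))
    stop("both size groups must be non-empty", call. = FALSE)
  all_vals <- c(sizes_transferred, sizes_other)
  if (length(unique(all_vals)) == 1L) {
    # fully tie-degenerate: no evidence of a location shift
    return(list(median_transferred = median(sizes_transferred),
                median_other = median(sizes_other), p_value = 1,
                method = "degenerate"))
  }
  exact <- length(sizes_transferred) <= 10 && length(sizes_other) <= 10 &&
    !anyDuplicated(all_vals)
  wt <- suppressWarnings(
    wilcox.test(sizes_transferred, sizes_other, exact = exact,
                correct = !exact))
  list(median_transferred = median(sizes_transferred),
       median_other = median(sizes_other),
       p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
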