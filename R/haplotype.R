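# Deciding, for each CNA (from BAF shifts) and each junction (from read-pair
# allele counts), whether the transferred or an endogenous homolog is
# affected. The transferred homolog has a distinct haplotype, so at SNPs
# where the parental line is homozygous and the transferred copy carries the
# other allele, the trisomic baseline BAF sits at 1/3 or 2/3 and every local
# copy-number change moves it in a homolog-specific direction.

#' Find phase-informative SNPs
#'
#' A SNP is phase-informative when the parental line is homozygous (BAF
#' below `hom_lo` or above `hom_hi`) and an unrearranged aneuploid baseline
#' shows the heterozygous shift expected from a differing transferred allele
#' (BAF within `window` of the expected fraction, 1/3 or 2/3 for a trisomy).
#' The baseline table must come from unrearranged trisomic signal: a sibling
#' intact clone, or the clone itself restricted to regions outside called
#' CNAs — inside a rearranged interval the diagnostic 1/3 / 2/3 signature is
#' destroyed, which is precisely what the downstream assignment exploits.
#'
#' @param parental parental SNP table (see [read_snp_table()]).
#' @param baseline unrearranged aneuploid-clone SNP table on the same
#'   positions.
#' @param aneuploid_chrom chromosome carrying the transferred homolog.
#' @param hom_lo,hom_hi parental homozygosity bounds (defaults 0.05/0.95).
#' @param window half-width of the acceptance window around the expected
#'   heterozygous BAF (default 0.12).
#' @param n_transferred transferred copies (1 trisomic, 2 tetrasomic).
#' @return data.frame `chrom pos parental_allele transferred_allele
#'   expected_baf` (expected BAF on the intact aneuploid baseline).
#' @export
find_phase_informative_snps <- function(parental, baseline, aneuploid_chrom,
                                        hom_lo = 0.05, hom_hi = 0.95,
                                        window = 0.12, n_transferred = 1L) {
  key_p <- paste(parental$chrom, parental$pos)
  key_b <- paste(baseline$chrom, baseline$pos)
  common <- intersect(key_p, key_b)
  if (!length(common))
    stop("parental and baseline tables share no positions", call. = FALSE)
  p <- parental[match(common, key_p), ]
  b <- baseline[match(common, key_b), ]
  on_an <- p$chrom == aneuploid_chrom
  par_hom_a <- p$baf < hom_lo
  par_hom_b <- p$baf > hom_hi
  total <- 2L + n_transferred
  # expected baseline BAF if the transferred allele differs from the parental
  exp_if_par_a <- n_transferred / total   # parental AA..., transferred B
  exp_if_par_b <- 2 / total               # parental BB..., transferred A
  shifted <- (par_hom_a & abs(b$baf - exp_if_par_a) <= window) |
             (par_hom_b & abs(b$baf - exp_if_par_b) <= window)
  sel <- on_an & (par_hom_a | par_hom_b) & shifted
  data.frame(chrom = p$chrom[sel], pos = p$pos[sel],
             parental_allele = ifelse(par_hom_a[sel], "A", "B"),
             transferred_allele = ifelse(par_hom_a[sel], "B", "A"),
             expected_baf = ifelse(par_hom_a[sel], exp_if_par_a, exp_if_par_b),
             stringsAsFactors = FALSE)
}

# expected BAF for a copy configuration given the B-allele identity of the
# parental homozygous allele: n_par parental copies, n_tr transferred copies
.target_baf <- function(n_par, n_tr, par_is_b) {
  n_b <- ifelse(par_is_b, n_par, n_tr)
  expected_baf(n_par + n_tr - n_b, n_b)
}

#' Assign the affected homolog of a CNA from BAF
#'
#' Each phase-informative SNP inside the CNA votes. For a loss, a BAF
#' returned to parental homozygosity (outside (`shift_lo`, `shift_hi`) on
#' the parental side) indicates loss of the transferred copy; a BAF near the
#' expected endogenous-loss fraction (AB, i.e. 0.5 in a trisomy) indicates
#' an endogenous loss. For a gain, movement to the transferred-duplication
#' fraction (AABB, 0.5) versus the endogenous-duplication fraction
#' (AAAB/ABBB, 0.25/0.75) separates the homologs. The verdict is the
#' majority of votes, ambiguous when fewer than `min_snps` votes are cast or
#' the majority falls short of `margin`.
#'
#' @param cna one call row (needs `chrom`, `start`, `end`, `state`).
#' @param informative output of [find_phase_informative_snps()].
#' @param clone clone SNP table.
#' @param shift_lo,shift_hi homozygous-return thresholds (defaults
#'   0.15/0.85).
#' @param target_window half-width around heterozygous target fractions
#'   (default 0.08).
#' @param min_snps minimum informative votes for a verdict (default 3).
#' @param margin minimum majority fraction among votes (default 2/3).
#' @param n_transferred transferred copies on the intact baseline.
#' @return list (class `haplotype_call`) with `verdict`
#'   (`transferred`/`endogenous`/`ambiguous`), `n_support`, `n_total`.
#' @export
assign_cna_allele_baf <- function(cna, informative, clone,
                                  shift_lo = 0.15, shift_hi = 0.85,
                                  target_window = 0.08, min_snps = 3,
                                  margin = 2 / 3, n_transferred = 1L) {
  stopifnot(cna$state %in% c("loss", "gain"))
  inside <- informative[informative$chrom == cna$chrom &
                        informative$pos >= cna$start &
                        informative$pos < cna$end, , drop = FALSE]
  key_c <- paste(clone$chrom, clone$pos)
  baf <- clone$baf[match(paste(inside$chrom, inside$pos), key_c)]
  ok <- !is.na(baf)
  inside <- inside[ok, , drop = FALSE]
  baf <- baf[ok]
  if (!nrow(inside))
    return(structure(list(verdict = "ambiguous", n_support = 0L,
                          n_total = 0L), class = "haplotype_call"))
  par_is_b <- inside$parental_allele == "B"
  if (cna$state == "loss") {
    if (n_transferred == 1L) {
      # trisomy: transferred copy lost -> back to parental homozygosity
      vote_tr <- ifelse(par_is_b, baf > shift_hi, baf < shift_lo)
    } else {
      tgt_tr <- .target_baf(2L, n_transferred - 1L, par_is_b)
      vote_tr <- abs(baf - tgt_tr) <= target_window
    }
    tgt_en <- .target_baf(1L, n_transferred, par_is_b) # one parental copy left
    vote_en <- abs(baf - tgt_en) <= target_window
  } else {
    tgt_tr <- .target_baf(2L, n_transferred + 1L, par_is_b) # extra transferred
    tgt_en <- .target_baf(3L, n_transferred, par_is_b)      # extra parental
    vote_tr <- abs(baf - tgt_tr) <= target_window
    vote_en <- abs(baf - tgt_en) <= target_window & !vote_tr
  }
  n_tr <- sum(vote_tr & !vote_en)
  n_en <- sum(vote_en & !vote_tr)
  n_votes <- n_tr + n_en
  verdict <- "ambiguous"
  n_support <- max(n_tr, n_en)
  if (n_votes >= min_snps) {
    if (n_tr / n_votes >= margin) verdict <- "transferred"
    else if (n_en / n_votes >= margin) verdict <- "endogenous"
  }
  structure(list(verdict = verdict, n_support = n_support,
                 n_total = n_votes), class = "haplotype_call")
}

#' Assign the affected homolog of a junction from read-pair allele counts
#'
#' Discordant read pairs supporting a junction carry the allele of the
#' homolog the junction lies on. Summed over phase-informative SNPs, the
#' transferred-allele count is tested against a fair coin by a one-sided
#' exact binomial test; a significant majority in either direction gives the
#' verdict, anything else is ambiguous.
#'
#' @param counts data.frame with `transferred_count` and `endogenous_count`
#'   (one row per SNP for one junction).
#' @param min_pairs minimum total discordant pairs (default 5).
#' @param alpha significance level (default 0.05).
#' @return `haplotype_call` list.
#' @export
assign_junction_allele_reads <- function(counts, min_pairs = 5, alpha = 0.05) {
  n_tr <- sum(counts$transferred_count)
  n_en <- sum(counts$endogenous_count)
  n <- n_tr + n_en
  verdict <- "ambiguous"
  if (n >= min_pairs && n > 0) {
    p_tr <- pbinom(n_tr - 1, n, 0.5, lower.tail = FALSE) # P(X >= n_tr)
    p_en <- pbinom(n_en - 1, n, 0.5, lower.tail = FALSE)
    if (p_tr < alpha) verdict <- "transferred"
    else if (p_en < alpha) verdict <- "endogenous"
  }
  structure(list(verdict = verdict, n_support = max(n_tr, n_en),
                 n_total = n), class = "haplotype_call")
}

#' Fraction of calls affecting the transferred homolog
#'
#' @param calls list of `haplotype_call` objects.
#' @return list with `fraction` (NA when no non-ambiguous evidence),
#'   `n_transferred`, `n_endogenous`, `n_ambiguous`.
#' @export
summarize_affected_fraction <- function(calls) {
  verdicts <- vapply(calls, function(x) x$verdict, character(1))
  n_tr <- sum(verdicts == "transferred")
  n_en <- sum(verdicts == "endogenous")
  frac <- if (n_tr + n_en > 0) n_tr / (n_tr + n_en) else NA_real_
  list(fraction = frac, n_transferred = n_tr, n_endogenous = n_en,
       n_ambiguous = sum(verdicts == "ambiguous"))
}
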