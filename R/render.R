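# Render downstream pipeline inputs (SNP tables, quantal segments, junction
# contigs, read-pair allele counts) from a simulation truth.

# local per-homolog copy numbers at positions (profile rows are sorted,
# contiguous per chromosome)
.cn_at <- function(profile, chrom, pos) {
  cn_e <- integer(length(pos)); cn_t <- integer(length(pos))
  for (ch in unique(chrom)) {
    rows <- profile[profile$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    idx <- findInterval(pos[sel], rows$start)
    idx[idx < 1] <- 1L
    cn_e[sel] <- rows$cn_endogenous[idx]
    cn_t[sel] <- rows$cn_transferred[idx]
  }
  list(endogenous = cn_e, transferred = cn_t)
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Render SNP-array style BAF/LRR profiles
#'
#' For each SNP the clone BAF is the exact B-allele fraction over all local
#' copies under the true copy configuration plus truncated Gaussian noise
#' (clipped to [0, 1]); LRR is `log2(total_cn / 2)` plus Gaussian noise. The
#' parental table is rendered at copy number 2.
#'
#' @param truth a `sim_truth`.
#' @param noise_sd Gaussian noise standard deviation (0 for exact signals).
#' @param seed RNG seed.
#' @return list with `parental` and `clone` SNP tables (see
#'   [read_snp_table()] for columns).
#' @export
render_snp_profile <- function(truth, noise_sd = 0.03, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), noise_sd >= 0)
  set.seed(seed)
  snps <- truth$genome$snps
  n <- nrow(snps)
  cn <- .cn_at(truth$cn_profile, snps$chrom, snps$pos)
  # endogenous copies all carry the parental allele
  n_b <- cn$endogenous * as.integer(snps$par_is_b) +
         cn$transferred * as.integer(snps$trans_is_b)
  total <- cn$endogenous + cn$transferred
  baf_true <- ifelse(total > 0, n_b / total, NA_real_)
  clone <- data.frame(
    chrom = snps$chrom, pos = snps$pos,
    lrr = log2(pmax(total, 0.25) / 2) + rnorm(n, 0, noise_sd),
    baf = .clip01(baf_true + rnorm(n, 0, noise_sd)),
    genotype = format_genotype(total - n_b, n_b),
    stringsAsFactors = FALSE)
  par_b <- 2L * as.integer(snps$par_is_b)
  parental <- data.frame(
    chrom = snps$chrom, pos = snps$pos,
    lrr = rnorm(n, 0, noise_sd),
    baf = .clip01(par_b / 2 + rnorm(n, 0, noise_sd)),
    genotype = format_genotype(2L - par_b, par_b),
    stringsAsFactors = FALSE)
  gt <- parse_genotype(clone$genotype)
  clone$n_a <- gt$n_a; clone$n_b <- gt$n_b
  gtp <- parse_genotype(parental$genotype)
  parental$n_a <- gtp$n_a; parental$n_b <- gtp$n_b
  list(parental = parental, clone = clone)
}

.snap_profile <- function(rows, bin_size, len) {
  # snap true copy-number boundaries to the bin grid, re-evaluate each snapped
  # segment at its midpoint, merge equal neighbours
  bounds <- sort(unique(c(0, len, round(rows$start / bin_size) * bin_size,
                          round(rows$end / bin_size) * bin_size)))
  bounds <- bounds[bounds >= 0 & bounds <= len]
  st <- head(bounds, -1); en <- tail(bounds, -1)
  keep <- en > st
  st <- st[keep]; en <- en[keep]
  mid <- (st + en) / 2
  idx <- findInterval(mid, rows$start)
  cn <- rows$cn_total[pmax(idx, 1L)]
  out <- data.frame(start = st, end = en, cn = cn)
  if (nrow(out) > 1) {
    same <- c(FALSE, out$cn[-1] == out$cn[-nrow(out)])
    grp <- cumsum(!same)
    out <- data.frame(start = tapply(out$start, grp, min),
                      end = tapply(out$end, grp, max),
                      cn = tapply(out$cn, grp, function(x) x[1]))
  }
  out
}

#' Render binned quantal copy-number segments
#'
#' Partitions each chromosome into constant-copy-number segments at the truth
#' boundaries snapped to bin boundaries; the quantal value is the true total
#' copy number plus Gaussian noise.
#'
#' @param truth a `sim_truth`.
#' @param bin_size bin width in bp (default 50 kb).
#' @param noise_sd Gaussian noise on the quantal value.
#' @param seed RNG seed.
#' @param clone_id sample identifier (defaults to the truth's).
#' @return segment data.frame `chrom start end quantal clone_id`.
#' @export
render_quantal_segments <- function(truth, bin_size = 5e4, noise_sd = 0,
                                    seed = 1, clone_id = truth$clone_id) {
  stopifnot(inherits(truth, "sim_truth"), bin_size > 0)
  set.seed(seed)
  spec <- truth$genome$spec
  segs <- do.call(rbind, lapply(names(spec$chromosomes), function(ch) {
    rows <- truth$cn_profile[truth$cn_profile$chrom == ch, , drop = FALSE]
    snapped <- .snap_profile(rows, bin_size, spec$chromosomes[[ch]])
    data.frame(chrom = ch, start = snapped$start, end = snapped$end,
               quantal = snapped$cn + rnorm(nrow(snapped), 0, noise_sd),
               clone_id = clone_id, stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  segs
}

#' Render parental (diploid) quantal segments
#' @param genome an `mn_genome`.
#' @param noise_sd Gaussian noise on the quantal value.
#' @param seed RNG seed.
#' @param clone_id sample identifier.
#' @return one segment per chromosome at quantal ~ 2.
#' @export
render_parental_segments <- function(genome, noise_sd = 0, seed = 1,
                                     clone_id = "parental") {
  set.seed(seed)
  chroms <- genome$spec$chromosomes
  data.frame(chrom = names(chroms), start = 0, end = as.numeric(chroms),
             quantal = 2 + rnorm(length(chroms), 0, noise_sd),
             clone_id = clone_id, stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract oriented reference flanks for a junction
#'
#' The left flank reads toward the junction along the retained side of the
#' first (canonically lower) breakend; the right flank reads away from the
#' junction along the retained side of the second breakend. A `tail` side
#' retains sequence toward lower coordinates, `head` toward higher; flanks on
#' the `head`-left or `tail`-right are reverse-complemented so both are given
#' in junction reading order.
#'
#' @param chrom_a,pos_a,side_a,chrom_b,pos_b,side_b the two breakends.
#' @param reference named character vector of chromosome sequences.
#' @param flank_len flank length in bp.
#' @return list with `left` and `right` flank strings.
#' @export
junction_flanks <- function(chrom_a, pos_a, side_a, chrom_b, pos_b, side_b,
                            reference, flank_len) {
  get_flank <- function(chrom, pos, side, role) {
    seq <- reference[[chrom]]
    L <- nchar(seq)
    toward_lower <- (side == "tail")
    if (toward_lower) {
      if (pos < flank_len)
        stop("reference too short for flank at ", chrom, ":", pos, call. = FALSE)
      s <- substr(seq, pos - flank_len + 1, pos)
      if (role == "right") s <- .revcomp(s)
    } else {
      if (pos + flank_len > L)
        stop("reference too short for flank at ", chrom, ":", pos, call. = FALSE)
      s <- substr(seq, pos + 1, pos + flank_len)
      if (role == "left") s <- .revcomp(s)
    }
    s
  }
  list(left = get_flank(chrom_a, pos_a, side_a, "left"),
       right = get_flank(chrom_b, pos_b, side_b, "right"))
}

#' Render junction contigs with planted features
#'
#' Builds one junction-spanning contig per true junction: left reference
#' flank, then any planted insertion, then the right reference flank.
#' Microhomology is realized by editing the reference so the right context's
#' junction-proximal bases equal the left context's final bases; the homology
#' tract then appears once in the contig (length `2*flank_len - homology`),
#' making the junction placement ambiguous across `homology + 1` positions.
#' Planted edits whose region would collide with another junction's flank are
#' demoted to blunt and recorded as such in the returned features.
#'
#' @param truth a `sim_truth` whose genome carries a reference sequence.
#' @param flank_len flank length in bp; must exceed the largest planted
#'   homology plus insertion.
#' @param seed RNG seed (insertion sequence and template locus draws).
#' @return list with `junctions` (junction_table including contigs),
#'   `features` (ground-truth homology/insertion lengths and template loci)
#'   and `reference` (the edited reference to analyse against).
#' @export
render_junction_records <- function(truth, flank_len = 300, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$genome$reference))
    stop("genome was simulated without sequence; rerun simulate_reference ",
         "with sequence = TRUE", call. = FALSE)
  jt <- truth$junctions
  if (max(c(0, jt$mh_len + jt$ins_len)) >= flank_len)
    stop("flank_len must exceed planted homology + insertion", call. = FALSE)
  set.seed(seed)
  reference <- truth$genome$reference
  an <- truth$genome$spec$aneuploid_chrom
  n <- nrow(jt)
  if (n == 0)
    return(list(junctions = make_junctions(character(), integer(), character(),
                                           character(), integer(), character()),
                features = data.frame(), reference = reference))

  # flank regions on the reference, for collision detection
  region_of <- function(chrom, pos, side) {
    if (side == "tail") c(pos - flank_len, pos) else c(pos, pos + flank_len)
  }
  regions <- vector("list", n)
  for (i in seq_len(n))
    regions[[i]] <- list(
      a = list(chrom = jt$chrom_a[i], r = region_of(jt$chrom_a[i], jt$pos_a[i], jt$side_a[i])),
      b = list(chrom = jt$chrom_b[i], r = region_of(jt$chrom_b[i], jt$pos_b[i], jt$side_b[i])))

  overlaps <- function(chrom1, r1, chrom2, r2)
    chrom1 == chrom2 && r1[1] < r2[2] && r2[1] < r1[2]

  mh <- jt$mh_len
  for (i in seq_len(n)) {
    if (mh[i] == 0) next
    edit <- if (jt$side_b[i] == "head") c(jt$pos_b[i], jt$pos_b[i] + mh[i])
            else c(jt$pos_b[i] - mh[i], jt$pos_b[i])
    clash <- FALSE
    for (j in seq_len(n)) {
      for (end_nm in c("a", "b")) {
        if (j == i && end_nm == "b") next # the edit lives inside its own right flank
        reg <- regions[[j]][[end_nm]]
        if (overlaps(jt$chrom_b[i], edit, reg$chrom, reg$r)) { clash <- TRUE; break }
      }
      if (clash) break
    }
    if (clash) mh[i] <- 0L
  }

  # apply surviving homology edits
  for (i in seq_len(n)) {
    if (mh[i] == 0) next
    fl <- junction_flanks(jt$chrom_a[i], jt$pos_a[i], jt$side_a[i],
                          jt$chrom_b[i], jt$pos_b[i], jt$side_b[i],
                          reference, flank_len)
    hom <- substr(fl$left, flank_len - mh[i] + 1, flank_len)
    ch <- jt$chrom_b[i]
    if (jt$side_b[i] == "head") {
      substr(reference[[ch]], jt$pos_b[i] + 1, jt$pos_b[i] + mh[i]) <- hom
    } else {
      substr(reference[[ch]], jt$pos_b[i] - mh[i] + 1, jt$pos_b[i]) <-
        .revcomp(hom)
    }
  }

  # build contigs from the edited reference
  contigs <- character(n)
  tmpl <- data.frame(template_chrom = rep(NA_character_, n),
                     template_start = NA_integer_, template_end = NA_integer_,
                     template_strand = NA_character_, stringsAsFactors = FALSE)
  ins_seq <- character(n)
  for (i in seq_len(n)) {
    fl <- junction_flanks(jt$chrom_a[i], jt$pos_a[i], jt$side_a[i],
                          jt$chrom_b[i], jt$pos_b[i], jt$side_b[i],
                          reference, flank_len)
    ins <- ""
    if (jt$ins_len[i] > 0) {
      if (jt$templated[i]) {
        L <- nchar(reference[[an]])
        s <- sample.int(L - jt$ins_len[i], 1) - 1L
        ins <- substr(reference[[an]], s + 1, s + jt$ins_len[i])
        strand <- if (runif(1) < 0.5) "-" else "+"
        if (strand == "-") ins <- .revcomp(ins)
        tmpl$template_chrom[i] <- an
        tmpl$template_start[i] <- s
        tmpl$template_end[i] <- s + jt$ins_len[i]
        tmpl$template_strand[i] <- strand
      } else {
        ins <- .random_dna(jt$ins_len[i])
      }
    }
    ins_seq[i] <- ins
    contigs[i] <- paste0(fl$left, ins,
                         substr(fl$right, mh[i] + 1, flank_len))
  }

  out <- make_junctions(jt$chrom_a, jt$pos_a, jt$side_a,
                        jt$chrom_b, jt$pos_b, jt$side_b,
                        name = jt$name, clone_id = truth$clone_id,
                        contig = contigs)
  features <- cbind(
    data.frame(name = jt$name, mh_len = mh, ins_len = jt$ins_len,
               templated = jt$templated & jt$ins_len > 0,
               ins_seq = ins_seq, stringsAsFactors = FALSE),
    tmpl)
  list(junctions = out, features = features, reference = reference)
}

#' Render per-junction read-pair allele counts at informative SNPs
#'
#' For each junction, phase-informative SNPs within `window` bp of either
#' breakend receive Poisson-distributed discordant read pairs. Every
#' discordant pair derives from the transferred homolog (all simulated
#' events lie on it) but is mislabeled with probability `error_rate`;
#' concordant pairs are drawn from the endogenous copies plus, where intact,
#' the transferred copy.
#'
#' @param truth a `sim_truth`.
#' @param coverage_mean mean discordant pairs per informative SNP (> 0
#'   normally; 0 renders zero evidence, forcing downstream ambiguity).
#' @param error_rate allele mislabeling probability in [0, 0.5).
#' @param seed RNG seed.
#' @param window bp window around each breakend.
#' @return data.frame `junction_id snp_pos transferred_count
#'   endogenous_count concordant_transferred concordant_endogenous`.
#' @export
render_readpair_counts <- function(truth, coverage_mean = 8, error_rate = 0.01,
                                   seed = 1, window = 5e4) {
  stopifnot(inherits(truth, "sim_truth"), coverage_mean >= 0,
            error_rate >= 0, error_rate < 0.5)
  set.seed(seed)
  snps <- truth$genome$snps
  an <- truth$genome$spec$aneuploid_chrom
  info <- snps[snps$chrom == an & snps$informative, , drop = FALSE]
  jt <- truth$junctions
  rows <- list()
  for (i in seq_len(nrow(jt))) {
    near <- info[abs(info$pos - jt$pos_a[i]) <= window |
                 abs(info$pos - jt$pos_b[i]) <= window, , drop = FALSE]
    if (!nrow(near)) next
    cn <- .cn_at(truth$cn_profile, near$chrom, near$pos)
    n_disc <- rpois(nrow(near), coverage_mean)
    t_cnt <- rbinom(nrow(near), n_disc, 1 - error_rate)
    conc_t <- rpois(nrow(near), coverage_mean * cn$transferred)
    conc_e <- rpois(nrow(near), coverage_mean * cn$endogenous)
    rows[[length(rows) + 1]] <- data.frame(
      junction_id = jt$name[i], snp_pos = near$pos,
      transferred_count = t_cnt, endogenous_count = n_disc - t_cnt,
      concordant_transferred = conc_t, concordant_endogenous = conc_e,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(junction_id = character(), snp_pos = integer(),
                      transferred_count = integer(),
                      endogenous_count = integer(),
                      concordant_transferred = integer(),
                      concordant_endogenous = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
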