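# Synthetic trisomic genomes in which the transferred homolog is rearranged
# by shattering (chromothripsis-like) or replicative template switching
# (chromoanasynthesis-like). Ground truth is retained throughout so every
# downstream step has an oracle.

#' Specify a toy genome for simulation
#'
#' The default emulates the signal structure of a chromosome-transfer clone
#' at desk scale: three 10 Mb chromosomes, one SNP per 5 kb, and 30% of SNPs
#' phase-informative (parental genotype homozygous, transferred homolog
#' carrying the other allele) — dense enough for well over ten informative
#' SNPs per 100 kb aberration.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param snp_density SNPs per bp.
#' @param informative_fraction fraction of SNPs where the transferred
#'   haplotype differs from the homozygous parental genotype; must be > 0.
#' @param aneuploid_chrom name of the chromosome present in extra copies.
#' @param n_transferred number of transferred copies (1 = trisomic,
#'   2 = tetrasomic).
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                        snp_density = 1 / 5000,
                        informative_fraction = 0.3,
                        aneuploid_chrom = "chr1",
                        n_transferred = 1L) {
  stopifnot(length(chromosomes) >= 1, all(chromosomes > 0))
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be named", call. = FALSE)
  if (!aneuploid_chrom %in% names(chromosomes))
    stop("aneuploid_chrom '", aneuploid_chrom, "' is not a chromosome",
         call. = FALSE)
  if (informative_fraction <= 0 || informative_fraction > 1)
    stop("informative_fraction must be in (0, 1]; with no informative SNPs ",
         "haplotype assignment is untestable", call. = FALSE)
  if (!n_transferred %in% c(1L, 2L))
    stop("n_transferred must be 1 (trisomic) or 2 (tetrasomic)", call. = FALSE)
  structure(list(chromosomes = chromosomes, snp_density = snp_density,
                 informative_fraction = informative_fraction,
                 aneuploid_chrom = aneuploid_chrom,
                 n_transferred = as.integer(n_transferred)),
            class = "genome_spec")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the reference genome and haplotypes
#'
#' Draws SNP positions, decides which SNPs are phase-informative, assigns the
#' parental homozygous allele and the transferred allele, and (optionally)
#' generates a random reference sequence. At informative SNPs the parental
#' genotype is homozygous and the transferred homolog carries the other
#' allele; at non-informative SNPs all copies agree.
#'
#' @param spec a [genome_spec()].
#' @param seed integer RNG seed; identical seeds give identical genomes.
#' @param sequence generate the nucleotide reference (needed only for
#'   junction contig rendering; skip for copy-number-only studies).
#' @return object of class `mn_genome` with elements `spec`, `snps`
#'   (data.frame `chrom pos informative par_is_b trans_is_b`) and `reference`
#'   (named character vector or NULL).
#' @export
simulate_reference <- function(spec, seed, sequence = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed)
  snps <- do.call(rbind, lapply(names(spec$chromosomes), function(chrom) {
    len <- spec$chromosomes[[chrom]]
    n <- round(len * spec$snp_density)
    if (n < 1)
      stop("snp_density yields zero SNPs on ", chrom, call. = FALSE)
    pos <- sort(sample.int(len, n)) - 1L
    informative <- runif(n) < spec$informative_fraction
    par_is_b <- runif(n) < 0.5
    trans_is_b <- ifelse(informative, !par_is_b, par_is_b)
    data.frame(chrom = chrom, pos = pos, informative = informative,
               par_is_b = par_is_b, trans_is_b = trans_is_b,
               stringsAsFactors = FALSE)
  }))
  rownames(snps) <- NULL
  reference <- NULL
  if (sequence) {
    reference <- vapply(spec$chromosomes, .random_dna, character(1))
    names(reference) <- names(spec$chromosomes)
  }
  structure(list(spec = spec, snps = snps, reference = reference),
            class = "mn_genome")
}

#' Junction feature planting configuration
#'
#' Controls what is planted at simulated breakpoint junctions. Classes are
#' mutually exclusive per junction (a junction with both homology and an
#' insertion would have ambiguous ground truth).
#'
#' @param p_blunt,p_microhomology,p_insertion class probabilities (sum to 1).
#' @param microhomology_range inclusive bp range for planted homology.
#' @param insertion_range inclusive bp range for non-templated insertions.
#' @param p_templated probability that an insertion is templated (copied from
#'   the transferred homolog) rather than random sequence.
#' @param templated_range inclusive bp range for templated insertions.
#' @return list of class `junction_feature_config`.
#' @export
junction_feature_config <- function(p_blunt = 0.2, p_microhomology = 0.6,
                                    p_insertion = 0.2,
                                    microhomology_range = c(1L, 15L),
                                    insertion_range = c(1L, 30L),
                                    p_templated = 0,
                                    templated_range = c(50L, 200L)) {
  p <- c(p_blunt, p_microhomology, p_insertion)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9,
            p_templated >= 0, p_templated <= 1)
  structure(list(p = p, microhomology_range = microhomology_range,
                 insertion_range = insertion_range, p_templated = p_templated,
                 templated_range = templated_range),
            class = "junction_feature_config")
}

# derive junction breakends from two adjacent derived fragments.
# For the upstream fragment the breakend sits at its derived-right end:
# "+" strand -> original end, retained toward lower coords (tail);
# "-" strand -> original start, retained toward higher coords (head).
.adjacent_breakends <- function(up, dn) {
  a <- if (up$strand == "+") list(pos = up$end, side = "tail")
       else                  list(pos = up$start, side = "head")
  b <- if (dn$strand == "+") list(pos = dn$start, side = "head")
       else                  list(pos = dn$end, side = "tail")
  list(a = a, b = b)
}

.is_original_adjacency <- function(up, dn) {
  (up$strand == "+" && dn$strand == "+" && up$end == dn$start) ||
  (up$strand == "-" && dn$strand == "-" && up$start == dn$end)
}

# junctions (with planted features) from an ordered derived structure
.derive_junctions <- function(derived, chrom, features, clone_id) {
  n <- nrow(derived)
  rows <- list()
  for (i in seq_len(max(0, n - 1))) {
    up <- derived[i, ]; dn <- derived[i + 1, ]
    if (.is_original_adjacency(up, dn)) next
    be <- .adjacent_breakends(up, dn)
    cls <- sample(c("blunt", "microhomology", "insertion"), 1, prob = features$p)
    mh <- 0L; ins <- 0L; templated <- FALSE
    if (cls == "microhomology")
      mh <- sample(seq(features$microhomology_range[1],
                       features$microhomology_range[2]), 1)
    if (cls == "insertion") {
      templated <- runif(1) < features$p_templated
      rng <- if (templated) features$templated_range else features$insertion_range
      ins <- sample(seq(rng[1], rng[2]), 1)
    }
    rows[[length(rows) + 1]] <- data.frame(
      chrom_a = chrom, pos_a = be$a$pos, side_a = be$a$side,
      chrom_b = chrom, pos_b = be$b$pos, side_b = be$b$side,
      mh_len = mh, ins_len = ins, templated = templated,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(name = character(), chrom_a = character(),
                      pos_a = integer(), side_a = character(),
                      chrom_b = character(), pos_b = integer(),
                      side_b = character(), orientation = character(),
                      mh_len = integer(), ins_len = integer(),
                      templated = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  jt <- make_junctions(df$chrom_a, df$pos_a, df$side_a,
                       df$chrom_b, df$pos_b, df$side_b, clone_id = clone_id)
  cbind(jt[, c("name", "chrom_a", "pos_a", "side_a", "chrom_b", "pos_b",
               "side_b", "orientation")],
        df[, c("mh_len", "ins_len", "templated")])
}

# total/per-homolog copy-number profile from the derived fragment coverage
# of the transferred homolog; other chromosomes stay at the diploid baseline.
.profile_from_fragments <- function(genome, fragments) {
  spec <- genome$spec
  an <- spec$aneuploid_chrom
  rows <- lapply(names(spec$chromosomes), function(chrom) {
    len <- spec$chromosomes[[chrom]]
    if (chrom != an)
      return(data.frame(chrom = chrom, start = 0, end = len,
                        cn_endogenous = 2L, cn_transferred = 0L,
                        stringsAsFactors = FALSE))
    if (nrow(fragments)) {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = fragments$start + 1L, end = fragments$end),
        width = len)
      ends <- cumsum(S4Vectors::runLength(cov))
      starts <- c(0, head(ends, -1))
      vals <- S4Vectors::runValue(cov)
    } else {
      starts <- 0; ends <- len; vals <- 0L
    }
    extra <- if (spec$n_transferred == 2L) 1L else 0L
    data.frame(chrom = chrom, start = starts, end = ends,
               cn_endogenous = 2L,
               cn_transferred = as.integer(vals) + extra,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof$cn_total <- prof$cn_endogenous + prof$cn_transferred
  rownames(prof) <- NULL
  prof
}

.new_truth <- function(genome, kind, clone_id, derived, profile, junctions,
                       events = NULL) {
  structure(list(genome = genome, kind = kind, clone_id = clone_id,
                 derived_structure = derived, cn_profile = profile,
                 junctions = junctions, events = events),
            class = "sim_truth")
}

#' Simulate an intact (unrearranged) aneuploid clone
#'
#' The baseline condition: the transferred homolog is present but untouched.
#' Useful as the unrearranged trisomic reference for phase-informative SNP
#' discovery and as a negative control.
#'
#' @param genome an `mn_genome`.
#' @param clone_id sample identifier.
#' @return `sim_truth` with no events or junctions.
#' @export
simulate_intact <- function(genome, clone_id = "intact") {
  an <- genome$spec$aneuploid_chrom
  len <- genome$spec$chromosomes[[an]]
  derived <- data.frame(chrom = an, start = 0, end = len, strand = "+",
                        stringsAsFactors = FALSE)
  profile <- .profile_from_fragments(genome, derived)
  junctions <- .derive_junctions(derived[0, ], an,
                                 junction_feature_config(), clone_id)
  .new_truth(genome, "intact", clone_id, derived, profile, junctions)
}

#' Simulate chromosome shattering of the transferred homolog
#'
#' Cuts the transferred homolog at `k_breakpoints` random positions, deletes
#' each fragment independently with probability `deletion_fraction`, and
#' stitches the survivors back in random order and orientation. Copy number
#' on the aneuploid chromosome then oscillates between the trisomic
#' (retained) and disomic (deleted) state, and junctions of all four
#' orientation classes can arise.
#'
#' @param genome an `mn_genome`.
#' @param k_breakpoints number of cut positions (>= 1).
#' @param deletion_fraction per-fragment deletion probability in [0, 1).
#' @param seed RNG seed.
#' @param shuffle permute surviving fragments (TRUE, default). With
#'   `shuffle = FALSE`, `invert_prob = 0` and `deletion_fraction = 0` the
#'   chromosome is reassembled unchanged: zero true CNAs, zero junctions.
#' @param invert_prob per-fragment inversion probability (applied whether or
#'   not fragments are shuffled, so copy-neutral pure inversions are
#'   expressible).
#' @param features a [junction_feature_config()] for planted junction
#'   features.
#' @param clone_id sample identifier.
#' @param max_retry resampling limit when every fragment is deleted.
#' @return `sim_truth`; `events` records per-fragment retention.
#' @export
simulate_shattering <- function(genome, k_breakpoints, deletion_fraction,
                                seed, shuffle = TRUE, invert_prob = 0.5,
                                features = junction_feature_config(),
                                clone_id = "shatter", max_retry = 100) {
  stopifnot(inherits(genome, "mn_genome"), k_breakpoints >= 1,
            deletion_fraction >= 0, deletion_fraction < 1)
  set.seed(seed)
  spec <- genome$spec
  an <- spec$aneuploid_chrom
  len <- spec$chromosomes[[an]]
  cuts <- sort(sample(seq_len(len - 1), k_breakpoints))
  starts <- c(0L, cuts)
  ends <- c(cuts, len)
  for (try in seq_len(max_retry)) {
    deleted <- runif(length(starts)) < deletion_fraction
    if (!all(deleted)) break
    if (try == max_retry)
      stop("all fragments deleted after ", max_retry, " retries", call. = FALSE)
  }
  keep <- which(!deleted)
  ord <- if (shuffle) sample(keep) else keep
  strand <- ifelse(runif(length(ord)) < invert_prob, "-", "+")
  derived <- data.frame(chrom = an, start = starts[ord], end = ends[ord],
                        strand = strand, stringsAsFactors = FALSE)
  profile <- .profile_from_fragments(genome, derived)
  junctions <- .derive_junctions(derived, an, features, clone_id)
  events <- data.frame(chrom = an, start = starts, end = ends,
                       deleted = deleted, stringsAsFactors = FALSE)
  .new_truth(genome, "shattering", clone_id, derived, profile, junctions,
             events)
}

#' Simulate replicative rearrangement (template switching)
#'
#' Emulates chromoanasynthesis: `n_switches` serial template switches each
#' insert an extra copy of a segment of the transferred homolog at a random
#' position of the derived chromosome, producing duplications/triplications
#' (more than two copy-number states) and junctions that carry planted
#' microhomology and/or templated insertions.
#'
#' @param genome an `mn_genome`.
#' @param n_switches number of template switches (>= 1).
#' @param seed RNG seed.
#' @param segment_range bp range of duplicated segment lengths.
#' @param invert_prob probability an inserted copy is inverted.
#' @param features a [junction_feature_config()]; the default plants
#'   microhomology (1-15 bp) or templated insertions (50-200 bp).
#' @param clone_id sample identifier.
#' @return `sim_truth`; `events` records the duplicated source intervals.
#' @export
simulate_chromoanasynthesis <- function(genome, n_switches, seed,
                                        segment_range = c(2e5, 1e6),
                                        invert_prob = 0.2,
                                        features = junction_feature_config(
                                          p_blunt = 0, p_microhomology = 0.6,
                                          p_insertion = 0.4, p_templated = 1),
                                        clone_id = "chromoana") {
  stopifnot(inherits(genome, "mn_genome"), n_switches >= 1)
  set.seed(seed)
  spec <- genome$spec
  an <- spec$aneuploid_chrom
  len <- spec$chromosomes[[an]]
  frags <- list(list(start = 0L, end = len, strand = "+"))
  events <- list()
  for (s in seq_len(n_switches)) {
    seg_len <- round(runif(1, segment_range[1], min(segment_range[2], len / 2)))
    src_start <- sample.int(len - seg_len, 1) - 1L
    copy <- list(start = src_start, end = src_start + seg_len,
                 strand = if (runif(1) < invert_prob) "-" else "+")
    # split a random host fragment at a random interior offset
    host <- sample(length(frags), 1)
    h <- frags[[host]]
    w <- h$end - h$start
    if (w < 2) next
    off <- sample.int(w - 1, 1)
    split_at <- h$start + off
    left <- list(start = h$start, end = split_at, strand = h$strand)
    right <- list(start = split_at, end = h$end, strand = h$strand)
    if (h$strand == "-") { # derived order of an inverted fragment is reversed
      left <- list(start = split_at, end = h$end, strand = "-")
      right <- list(start = h$start, end = split_at, strand = "-")
    }
    frags <- append(frags[-host], list(left, copy, right), after = host - 1)
    events[[s]] <- data.frame(chrom = an, start = copy$start, end = copy$end,
                              strand = copy$strand, stringsAsFactors = FALSE)
  }
  derived <- do.call(rbind, lapply(frags, as.data.frame))
  derived$chrom <- an
  derived <- derived[, c("chrom", "start", "end", "strand")]
  profile <- .profile_from_fragments(genome, derived)
  junctions <- .derive_junctions(derived, an, features, clone_id)
  .new_truth(genome, "chromoanasynthesis", clone_id, derived, profile,
             junctions, do.call(rbind, events))
}

#' Simulate one canonical rearrangement event
#'
#' Builds the derived chromosome for a single textbook event on the
#' transferred homolog and derives its junction(s): a simple deletion yields
#' one tail-head junction, a tandem duplication one head-tail junction, and
#' an inversion one tail-tail plus one head-head junction.
#'
#' @param genome an `mn_genome`.
#' @param type `"deletion"`, `"tandem_duplication"` or `"inversion"`.
#' @param start,end affected interval on the aneuploid chromosome
#'   (0-based half-open).
#' @param features a [junction_feature_config()] (default: all blunt).
#' @param seed RNG seed for feature planting.
#' @param clone_id sample identifier.
#' @return `sim_truth`.
#' @export
simulate_simple_event <- function(genome, type = c("deletion",
                                                   "tandem_duplication",
                                                   "inversion"),
                                  start, end,
                                  features = junction_feature_config(1, 0, 0),
                                  seed = 1, clone_id = type) {
  type <- match.arg(type)
  stopifnot(inherits(genome, "mn_genome"))
  set.seed(seed)
  an <- genome$spec$aneuploid_chrom
  len <- genome$spec$chromosomes[[an]]
  stopifnot(start > 0, end > start, end < len)
  derived <- switch(type,
    deletion = data.frame(start = c(0, end), end = c(start, len),
                          strand = "+"),
    tandem_duplication = data.frame(start = c(0, start), end = c(end, len),
                                    strand = "+"),
    inversion = data.frame(start = c(0, start, end),
                           end = c(start, end, len),
                           strand = c("+", "-", "+")))
  derived$chrom <- an
  derived <- derived[, c("chrom", "start", "end", "strand")]
  profile <- .profile_from_fragments(genome, derived)
  junctions <- .derive_junctions(derived, an, features, clone_id)
  .new_truth(genome, type, clone_id, derived, profile, junctions)
}

#' Plant copy-number events directly (no junction structure)
#'
#' Constructs a truth object from an explicit event list, supporting events
#' on the transferred or an endogenous homolog. Used for haplotype-assignment
#' parameter-recovery studies where the CNA locations are the design.
#'
#' @param genome an `mn_genome`.
#' @param events data.frame with columns `chrom start end homolog kind`;
#'   `homolog` in `transferred`/`endogenous`, `kind` in
#'   `deletion`/`duplication`. Transferred events must lie on the aneuploid
#'   chromosome.
#' @param clone_id sample identifier.
#' @return `sim_truth` with the per-homolog copy profile implied by the
#'   events.
#' @export
plant_cna_events <- function(genome, events, clone_id = "planted") {
  stopifnot(inherits(genome, "mn_genome"))
  need <- c("chrom", "start", "end", "homolog", "kind")
  if (!all(need %in% names(events)))
    stop("events needs columns: ", paste(need, collapse = " "), call. = FALSE)
  stopifnot(all(events$homolog %in% c("transferred", "endogenous")),
            all(events$kind %in% c("deletion", "duplication")))
  validate_intervals(events$chrom, events$start, events$end, "event")
  spec <- genome$spec
  an <- spec$aneuploid_chrom
  if (any(events$homolog == "transferred" & events$chrom != an))
    stop("transferred-homolog events must lie on the aneuploid chromosome",
         call. = FALSE)
  rows <- lapply(names(spec$chromosomes), function(chrom) {
    len <- spec$chromosomes[[chrom]]
    ev <- events[events$chrom == chrom, , drop = FALSE]
    bounds <- sort(unique(c(0, len, ev$start, ev$end)))
    bounds <- bounds[bounds >= 0 & bounds <= len]
    st <- head(bounds, -1); en <- tail(bounds, -1)
    base_t <- if (chrom == an) spec$n_transferred else 0L
    cn_e <- rep(2L, length(st)); cn_t <- rep(base_t, length(st))
    for (i in seq_len(nrow(ev))) {
      hit <- st >= ev$start[i] & en <= ev$end[i]
      d <- if (ev$kind[i] == "deletion") -1L else 1L
      if (ev$homolog[i] == "transferred") cn_t[hit] <- pmax(0L, cn_t[hit] + d)
      else cn_e[hit] <- pmax(0L, cn_e[hit] + d)
    }
    data.frame(chrom = chrom, start = st, end = en, cn_endogenous = cn_e,
               cn_transferred = cn_t, stringsAsFactors = FALSE)
  })
  profile <- do.call(rbind, rows)
  profile$cn_total <- profile$cn_endogenous + profile$cn_transferred
  rownames(profile) <- NULL
  len <- spec$chromosomes[[an]]
  derived <- data.frame(chrom = an, start = 0, end = len, strand = "+",
                        stringsAsFactors = FALSE)
  .new_truth(genome, "planted", clone_id, derived, profile,
             .derive_junctions(derived[0, ], an, junction_feature_config(),
                               clone_id),
             events)
}

#' True copy-number aberrations implied by a simulation truth
#'
#' Intervals whose total copy number differs from the clone's baseline
#' (diploid, or trisomic/tetrasomic on the aneuploid chromosome), merged over
#' adjacent equal states, with the affected homolog annotated.
#'
#' @param truth a `sim_truth`.
#' @return data.frame `chrom start end cn_total state homolog`.
#' @export
true_cnas <- function(truth) {
  spec <- truth$genome$spec
  an <- spec$aneuploid_chrom
  prof <- truth$cn_profile
  baseline <- ifelse(prof$chrom == an, 2L + spec$n_transferred, 2L)
  base_t <- ifelse(prof$chrom == an, spec$n_transferred, 0L)
  dev <- prof[prof$cn_total != baseline, , drop = FALSE]
  if (!nrow(dev))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cn_total = integer(), state = character(),
                      homolog = character(), stringsAsFactors = FALSE))
  dev$state <- ifelse(dev$cn_total <
                        ifelse(dev$chrom == an, 2L + spec$n_transferred, 2L),
                      "loss", "gain")
  dev$homolog <- ifelse(dev$cn_endogenous != 2L, "endogenous", "transferred")
  # merge adjacent intervals with identical copy state
  out <- dev[1, , drop = FALSE]
  if (nrow(dev) > 1) {
    for (i in 2:nrow(dev)) {
      last <- nrow(out)
      if (dev$chrom[i] == out$chrom[last] && dev$start[i] == out$end[last] &&
          dev$cn_total[i] == out$cn_total[last] &&
          dev$homolog[i] == out$homolog[last]) {
        out$end[last] <- dev$end[i]
      } else out <- rbind(out, dev[i, ])
    }
  }
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "cn_total", "state", "homolog")]
}
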