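#' @importFrom stats rbinom rnorm rpois runif median pchisq pbinom dbinom
#'   wilcox.test setNames ks.test punif
#' @importFrom utils read.delim write.table head tail
NULL

# Coordinate convention: 0-based half-open [start, end) internally and on disk
# (BED/BEDPE); human-readable reports print 1-based inclusive.

#' Validate a set of genomic intervals
#'
#' Checks the package-wide interval invariants: non-empty chromosome name,
#' `start >= 0` and `end > start` (0-based half-open coordinates in bp).
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end integer-like vectors of interval bounds.
#' @param what label used in error messages.
#' @return invisibly `TRUE`; stops with a located error on violation.
#' @export
validate_intervals <- function(chrom, start, end, what = "interval") {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop(what, ": chrom/start/end lengths differ", call. = FALSE)
  bad <- which(is.na(chrom) | !nzchar(as.character(chrom)))
  if (length(bad))
    stop(what, " row ", bad[1], ": empty chromosome name", call. = FALSE)
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad))
    stop(what, " row ", bad[1], ": negative or missing start", call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop(what, " row ", bad[1], ": end <= start", call. = FALSE)
  invisible(TRUE)
}

#' Parse genotype allele-count strings
#'
#' Genotypes are allele-count pairs `"nA:nB"` (`"2:1"` is AAB) so that
#' trisomic and tetrasomic configurations share one representation; `"."`
#' denotes a missing genotype.
#'
#' @param x character vector of `"A:B"` strings or `"."`.
#' @return data.frame with integer columns `n_a`, `n_b` (NA when missing).
#' @export
parse_genotype <- function(x) {
  x <- as.character(x)
  n_a <- rep(NA_integer_, length(x))
  n_b <- rep(NA_integer_, length(x))
  present <- !is.na(x) & x != "." & nzchar(x)
  if (any(present)) {
    parts <- strsplit(x[present], ":", fixed = TRUE)
    ok <- vapply(parts, length, 1L) == 2L
    if (!all(ok))
      stop("malformed genotype at entry ", which(present)[!ok][1], call. = FALSE)
    m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
    if (anyNA(m))
      stop("non-integer genotype allele count", call. = FALSE)
    if (any(rowSums(m) < 1))
      stop("genotype with zero total alleles", call. = FALSE)
    n_a[present] <- m[, 1]
    n_b[present] <- m[, 2]
  }
  data.frame(n_a = n_a, n_b = n_b)
}

#' Format allele-count genotypes
#' @param n_a,n_b integer allele counts; NA yields `"."`.
#' @return character vector of `"A:B"` strings.
#' @export
format_genotype <- function(n_a, n_b) {
  out <- paste0(n_a, ":", n_b)
  out[is.na(n_a) | is.na(n_b)] <- "."
  out
}

#' Expected B allele frequency for an allele-count configuration
#'
#' For a genotype with `n_a` copies of the A allele and `n_b` of the B allele
#' the noise-free array BAF is `n_b / (n_a + n_b)`; AAB gives 1/3, ABB 2/3,
#' AABB 1/2, AAAB 1/4.
#'
#' @param n_a,n_b non-negative allele counts (vectors recycle).
#' @return numeric BAF in `[0, 1]`; NA where total is 0.
#' @export
expected_baf <- function(n_a, n_b) {
  tot <- n_a + n_b
  ifelse(tot > 0, n_b / tot, NA_real_)
}

# canonical order of the two breakends of a junction: (chrom, pos) ascending
.junction_canonical <- function(df) {
  swap <- (as.character(df$chrom_a) > as.character(df$chrom_b)) |
    (as.character(df$chrom_a) == as.character(df$chrom_b) & df$pos_a > df$pos_b)
  if (any(swap)) {
    tmp <- df[swap, c("chrom_a", "pos_a", "side_a")]
    df[swap, c("chrom_a", "pos_a", "side_a")] <-
      df[swap, c("chrom_b", "pos_b", "side_b")]
    df[swap, c("chrom_b", "pos_b", "side_b")] <- tmp
  }
  df
}

.valid_sides <- c("head", "tail")

#' Assemble a junction table
#'
#' Builds the canonical junction data.frame used throughout the pipeline.
#' Breakends are canonically ordered (lower chromosome/position first) and the
#' orientation class is derived as `side(lower)_side(higher)`. A breakend
#' `side` records the direction the retained sequence extends: `head` toward
#' higher coordinates, `tail` toward lower coordinates.
#'
#' @param chrom_a,pos_a,side_a first breakend (0-based position).
#' @param chrom_b,pos_b,side_b second breakend.
#' @param name junction identifiers (defaults `jct1..n`).
#' @param clone_id sample identifier.
#' @param contig optional junction-spanning contig sequences (ACGTN), NA to skip.
#' @return data.frame of class `junction_table` with derived `orientation` and
#'   intra-chromosomal `span` (NA for translocations).
#' @export
make_junctions <- function(chrom_a, pos_a, side_a, chrom_b, pos_b, side_b,
                           name = NULL, clone_id = "clone", contig = NA_character_) {
  n <- length(pos_a)
  if (n == 0) {
    out <- data.frame(name = character(), chrom_a = character(), pos_a = integer(),
                      side_a = character(), chrom_b = character(), pos_b = integer(),
                      side_b = character(), orientation = character(),
                      span = numeric(), clone_id = character(), contig = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("junction_table", "data.frame")
    return(out)
  }
  if (is.null(name)) name <- paste0("jct", seq_len(n))
  stopifnot(all(side_a %in% .valid_sides), all(side_b %in% .valid_sides))
  if (!all(is.na(contig))) {
    bad <- grepl("[^ACGTNacgtn]", contig[!is.na(contig)])
    if (any(bad)) stop("contig contains non-ACGTN characters", call. = FALSE)
  }
  df <- data.frame(name = as.character(name),
                   chrom_a = as.character(chrom_a), pos_a = as.integer(pos_a),
                   side_a = as.character(side_a),
                   chrom_b = as.character(chrom_b), pos_b = as.integer(pos_b),
                   side_b = as.character(side_b),
                   clone_id = rep_len(as.character(clone_id), n),
                   contig = rep_len(as.character(contig), n),
                   stringsAsFactors = FALSE)
  df <- .junction_canonical(df)
  df$orientation <- paste0(df$side_a, "_", df$side_b)
  df$span <- ifelse(df$chrom_a == df$chrom_b, abs(df$pos_b - df$pos_a), NA_real_)
  df <- df[, c("name", "chrom_a", "pos_a", "side_a", "chrom_b", "pos_b",
               "side_b", "orientation", "span", "clone_id", "contig")]
  rownames(df) <- NULL
  class(df) <- c("junction_table", "data.frame")
  df
}
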