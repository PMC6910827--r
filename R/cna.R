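# Copy-number calling from quantal segment tables: loss/gain thresholds with
# aneuploid correction, consecutive-segment merging, size floor, and
# reciprocal-overlap uniqueness filtering against sibling clones and the
# parental line.

#' Call loss/gain states from quantal segments
#'
#' On the aneuploid chromosome the quantal value is first corrected by
#' subtracting 1 (one copy of the chromosome is expected in excess).
#' Segments with corrected quantal < 1.5 are losses and > 2.5 gains (strict
#' inequalities); neutral segments are dropped.
#'
#' @param segments data.frame `chrom start end quantal clone_id`, sorted and
#'   non-overlapping within each clone.
#' @param aneuploid_chrom aneuploid chromosome name, or a named character
#'   vector mapping `clone_id` to its aneuploid chromosome.
#' @param loss_below,gain_above state thresholds on the corrected quantal.
#' @return data.frame of calls with `corrected_quantal` and
#'   `state` in `loss`/`gain`.
#' @export
call_quantal_states <- function(segments, aneuploid_chrom,
                                loss_below = 1.5, gain_above = 2.5) {
  if (!nrow(segments)) {
    segments$corrected_quantal <- numeric()
    segments$state <- character()
    return(segments)
  }
  validate_intervals(segments$chrom, segments$start, segments$end, "segment")
  segments <- segments[order(segments$clone_id, segments$chrom,
                             segments$start), , drop = FALSE]
  for (cl in unique(segments$clone_id)) {
    s <- segments[segments$clone_id == cl, ]
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, ]
      if (nrow(sc) > 1 && any(sc$start[-1] < sc$end[-nrow(sc)]))
        stop("overlapping segments in clone ", cl, " on ", ch, call. = FALSE)
    }
  }
  an_of <- if (is.null(names(aneuploid_chrom)))
    rep(aneuploid_chrom[1], nrow(segments))
  else aneuploid_chrom[segments$clone_id]
  segments$corrected_quantal <-
    ifelse(segments$chrom == an_of, segments$quantal - 1, segments$quantal)
  segments$state <- ifelse(segments$corrected_quantal < loss_below, "loss",
                    ifelse(segments$corrected_quantal > gain_above, "gain",
                           "neutral"))
  out <- segments[segments$state != "neutral", , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one greedy left-to-right merge pass over a same-clone, same-chromosome run
.merge_pass <- function(calls, coverage_threshold) {
  n <- nrow(calls)
  if (n < 2) return(calls)
  i <- 1
  out <- list()
  while (i <= n) {
    j <- i
    # extend the candidate run while state matches and coverage stays > threshold
    while (j < n && calls$state[j + 1] == calls$state[i]) {
      span <- calls$end[j + 1] - calls$start[i]
      covered <- sum(calls$end[i:(j + 1)] - calls$start[i:(j + 1)])
      if (covered / span > coverage_threshold) j <- j + 1 else break
    }
    if (j > i) {
      lens <- calls$end[i:j] - calls$start[i:j]
      merged <- calls[i, , drop = FALSE]
      merged$end <- calls$end[j]
      merged$corrected_quantal <-
        sum(calls$corrected_quantal[i:j] * lens) / sum(lens)
      merged$quantal <- sum(calls$quantal[i:j] * lens) / sum(lens)
      out[[length(out) + 1]] <- merged
    } else {
      out[[length(out) + 1]] <- calls[i, , drop = FALSE]
    }
    i <- j + 1
  }
  do.call(rbind, out)
}

#' Merge consecutive same-state calls
#'
#' Two or more consecutive calls of the same state on the same chromosome are
#' merged into one call spanning first start to last end when their summed
#' segment lengths cover more than `coverage_threshold` of that span (gaps
#' count against coverage). Merging is greedy left-to-right and repeated to a
#' fixpoint; the merged corrected quantal is the length-weighted mean.
#'
#' @param calls output of [call_quantal_states()].
#' @param coverage_threshold strict lower bound on covered fraction
#'   (default 0.90).
#' @return merged call data.frame.
#' @export
merge_consecutive <- function(calls, coverage_threshold = 0.90) {
  if (!nrow(calls)) return(calls)
  pieces <- split(calls, list(calls$clone_id, calls$chrom), drop = TRUE)
  merged <- lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    repeat {
      m <- .merge_pass(p, coverage_threshold)
      if (nrow(m) == nrow(p)) break
      p <- m
    }
    p
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$clone_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the minimum CNA size floor
#' @param calls call data.frame.
#' @param min_size strict lower bound on `end - start` in bp (default 100 kb).
#' @return calls longer than `min_size`.
#' @export
filter_min_size <- function(calls, min_size = 1e5) {
  out <- calls[(calls$end - calls$start) > min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal overlap of two genomic intervals
#'
#' `min(ov / len(a), ov / len(b))` where `ov` is the intersection length;
#' 0 for different chromosomes or disjoint intervals. Two CNAs are "the
#' same" when both coverage fractions reach the threshold, i.e. when the
#' reciprocal overlap does.
#'
#' @param chrom_a,start_a,end_a interval a.
#' @param chrom_b,start_b,end_b interval b.
#' @return fraction in [0, 1] (vectorized).
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ro <- pmin(ov / (end_a - start_a), ov / (end_b - start_b))
  ifelse(as.character(chrom_a) == as.character(chrom_b), ro, 0)
}

#' Flag unique (de novo) CNAs by reciprocal overlap
#'
#' A call is unique iff its reciprocal overlap is below `threshold` against
#' every call of every *other* clone from the same parental line and every
#' parental call; calls of the call's own clone are never compared. Shared
#' calls are retained with `unique = FALSE`.
#'
#' @param calls call data.frame for all clones (column `clone_id`).
#' @param parental_calls calls of the parental line (may be empty/NULL).
#' @param threshold strict reciprocal-overlap bound (default 0.70).
#' @return `calls` with a logical `unique` column.
#' @export
unique_cnas <- function(calls, parental_calls = NULL, threshold = 0.70) {
  if (!nrow(calls)) {
    calls$unique <- logical()
    return(calls)
  }
  others <- calls
  if (!is.null(parental_calls) && nrow(parental_calls)) {
    pc <- parental_calls[, c("chrom", "start", "end")]
    pc$clone_id <- "__parental__"
    others <- rbind(calls[, c("chrom", "start", "end", "clone_id")], pc)
  } else {
    others <- calls[, c("chrom", "start", "end", "clone_id")]
  }
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1, calls$end))
  gr_other <- GenomicRanges::GRanges(
    others$chrom, IRanges::IRanges(others$start + 1, others$end))
  hits <- GenomicRanges::findOverlaps(gr_calls, gr_other)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- calls$clone_id[q] != others$clone_id[s]
  q <- q[keep]; s <- s[keep]
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_calls[q], gr_other[s]))
  ro <- pmin(ov / GenomicRanges::width(gr_calls[q]),
             ov / GenomicRanges::width(gr_other[s]))
  shared_idx <- unique(q[ro >= threshold])
  calls$unique <- TRUE
  calls$unique[shared_idx] <- FALSE
  calls
}

#' Partition unique CNAs by chromosome class
#'
#' Counts unique CNAs on each clone's aneuploid chromosome versus all other
#' chromosomes and forwards the size lists for downstream statistics.
#'
#' @param calls unique-flagged calls (only rows with `unique = TRUE` are
#'   counted).
#' @param aneuploid_chrom single name or named map `clone_id -> chromosome`.
#' @return list with `n_aneuploid`, `n_other`, `sizes_aneuploid`,
#'   `sizes_other`.
#' @export
count_cnas_per_chromosome <- function(calls, aneuploid_chrom) {
  u <- if (nrow(calls)) calls[calls$unique, , drop = FALSE] else calls
  if (!nrow(u))
    return(list(n_aneuploid = 0L, n_other = 0L,
                sizes_aneuploid = numeric(), sizes_other = numeric()))
  an_of <- if (is.null(names(aneuploid_chrom)))
    rep(aneuploid_chrom[1], nrow(u))
  else aneuploid_chrom[u$clone_id]
  on_an <- u$chrom == an_of
  sizes <- u$end - u$start
  list(n_aneuploid = sum(on_an), n_other = sum(!on_an),
       sizes_aneuploid = sizes[on_an], sizes_other = sizes[!on_an])
}
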