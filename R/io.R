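# Readers/writers for the plain-text formats the pipeline touches.
# All tables are TSV; intervals are 0-based half-open on disk (BED/BEDPE).

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("file '", basename(path), "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a per-sample SNP table
#'
#' Expects a TSV with header columns `chrom pos lrr baf genotype`; `genotype`
#' is an `"A:B"` allele-count pair or `"."`. Records are returned sorted by
#' (chrom, pos). Malformed rows are rejected with their row number.
#'
#' @param path file path.
#' @return data.frame with columns `chrom, pos, lrr, baf, genotype, n_a, n_b`.
#' @export
read_snp_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("chrom", "pos", "lrr", "baf", "genotype"), path)
  if (nrow(df) == 0) {
    df$n_a <- integer(); df$n_b <- integer()
    return(df)
  }
  bad <- which(is.na(df$baf) | df$baf < 0 | df$baf > 1)
  if (length(bad))
    stop("SNP table row ", bad[1], ": baf outside [0,1]", call. = FALSE)
  bad <- which(!is.finite(df$lrr))
  if (length(bad))
    stop("SNP table row ", bad[1], ": non-finite lrr", call. = FALSE)
  bad <- which(is.na(df$pos) | df$pos < 0)
  if (length(bad))
    stop("SNP table row ", bad[1], ": invalid position", call. = FALSE)
  gt <- parse_genotype(df$genotype)
  df$n_a <- gt$n_a
  df$n_b <- gt$n_b
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a SNP table
#' @param snps data.frame as returned by [read_snp_table()].
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  out <- snps[, c("chrom", "pos", "lrr", "baf", "genotype")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantal segment table
#'
#' BED5-like TSV `chrom start end quantal clone_id` with 0-based half-open
#' intervals. Output is sorted by (clone, chrom, start).
#'
#' @param path file path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("chrom", "start", "end", "quantal", "clone_id"), path)
  if (nrow(df)) {
    validate_intervals(df$chrom, df$start, df$end, what = "segment")
    if (any(!is.finite(df$quantal) | df$quantal <= 0))
      stop("segment with non-positive quantal value", call. = FALSE)
    df <- df[order(df$clone_id, df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a segment table
#' @param segments data.frame with `chrom start end quantal clone_id` (extra
#'   columns such as `state`, `corrected_quantal`, `unique` are preserved).
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read breakpoint junctions from BEDPE
#'
#' Ten standard BEDPE columns plus an optional 11th `contig` column. Strand
#' `+` maps to breakend side `tail` (retained sequence to the left of the
#' breakend), `-` to `head`; a simple deletion (`+`,`-`) is therefore a
#' tail-head junction. Breakends are canonically ordered and the orientation
#' class derived.
#'
#' @param path file path; header optional (detected on the first field).
#' @param clone_id clone identifier to attach when the name column does not
#'   encode one.
#' @return `junction_table` data.frame (see [make_junctions()]).
#' @export
read_junctions <- function(path, clone_id = "clone") {
  first <- readLines(path, n = 1L)
  has_header <- length(first) && grepl("^chrom", first)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(make_junctions(character(), integer(), character(),
                          character(), integer(), character()))
  if (ncol(df) < 10)
    stop("BEDPE requires 10 columns, found ", ncol(df), call. = FALSE)
  cn <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
          "name", "score", "strand1", "strand2")
  names(df)[seq_along(cn)] <- cn
  contig <- if (ncol(df) >= 11) as.character(df[[11]]) else NA_character_
  contig[!is.na(contig) & contig == "."] <- NA_character_
  side_of <- function(strand) {
    bad <- !strand %in% c("+", "-")
    if (any(bad))
      stop("unknown strand symbol '", strand[bad][1], "' in BEDPE", call. = FALSE)
    ifelse(strand == "+", "tail", "head")
  }
  validate_intervals(df$chrom1, df$start1, df$end1, what = "BEDPE end A")
  validate_intervals(df$chrom2, df$start2, df$end2, what = "BEDPE end B")
  make_junctions(df$chrom1, df$start1, side_of(df$strand1),
                 df$chrom2, df$start2, side_of(df$strand2),
                 name = df$name, clone_id = clone_id, contig = contig)
}

#' Write junctions as BEDPE
#' @param junctions `junction_table`.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @export
write_junctions <- function(junctions, path, header = TRUE) {
  strand_of <- function(side) ifelse(side == "tail", "+", "-")
  out <- data.frame(chrom1 = junctions$chrom_a, start1 = junctions$pos_a,
                    end1 = junctions$pos_a + 1L,
                    chrom2 = junctions$chrom_b, start2 = junctions$pos_b,
                    end2 = junctions$pos_b + 1L,
                    name = junctions$name, score = 0L,
                    strand1 = strand_of(junctions$side_a),
                    strand2 = strand_of(junctions$side_b),
                    contig = ifelse(is.na(junctions$contig), ".", junctions$contig),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Read a reference genome FASTA
#' @param path FASTA path.
#' @return named character vector of sequences (one per chromosome).
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write a reference genome FASTA
#' @param reference named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a genome table (`chrom length`)
#' @param path TSV path with header `chrom length`.
#' @return data.frame with `chrom` and `length`.
#' @export
read_genome_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("chrom", "length"), path)
  if (any(df$length <= 0)) stop("non-positive chromosome length", call. = FALSE)
  df
}

#' Write pipeline results as a report
#'
#' Writes machine-readable TSV tables (one per result component) plus a
#' human-readable `summary.txt` with 1-based inclusive coordinates.
#' Output is byte-identical for identical inputs.
#'
#' @param results named list; data.frame elements become `<name>.tsv`, scalar
#'   elements are printed in the summary.
#' @param dir output directory (created if needed).
#' @return invisibly the directory path.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_lines <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      write.table(x, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary_lines <- c(summary_lines,
                         sprintf("%s: %d record(s)", nm, nrow(x)))
    } else {
      vals <- paste(format(unlist(x), trim = TRUE), collapse = ", ")
      summary_lines <- c(summary_lines, sprintf("%s: %s", nm, vals))
    }
  }
  if (!length(summary_lines)) summary_lines <- "no results (zero events)"
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
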