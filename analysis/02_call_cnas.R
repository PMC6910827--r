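#!/usr/bin/env Rscript
# Copy-number calling: loss/gain thresholds with aneuploid correction,
# consecutive-segment merging (>90% span coverage), the >100 kb size floor,
# and the <70% reciprocal-overlap uniqueness filter against the sibling
# clones and the parental line.

suppressPackageStartupMessages(library(chromoshatter))
sim <- "results/simulated"
out <- "results"

clones <- c("shatter01", "chromoana01", "intact01")
segs <- do.call(rbind, lapply(clones, function(cl)
  read_segments(file.path(sim, paste0(cl, "_segments.tsv")))))
parental <- read_segments(file.path(sim, "parental_segments.tsv"))

calls <- call_quantal_states(segs, aneuploid_chrom = "chr1")
calls <- merge_consecutive(calls, coverage_threshold = 0.90)
calls <- filter_min_size(calls, min_size = 1e5)
par_calls <- filter_min_size(merge_consecutive(
  call_quantal_states(parental, aneuploid_chrom = "none")))
calls <- unique_cnas(calls, par_calls, threshold = 0.70)
write_segments(calls, file.path(out, "cna_calls.tsv"))

for (cl in clones) {
  n <- sum(calls$clone_id == cl)
  message(cl, ": ", n, " CNA call(s), ",
          sum(calls$unique[calls$clone_id == cl]), " unique")
}
part <- count_cnas_per_chromosome(calls, "chr1")
message("unique CNAs on the aneuploid chromosome: ", part$n_aneuploid,
        " vs elsewhere: ", part$n_other)

# recovery against the simulator's truth for the shattered clone
truth <- utils::read.delim(file.path(sim, "shatter01_true_cnas.tsv"))
sh <- calls[calls$clone_id == "shatter01", ]
hit <- vapply(seq_len(nrow(truth)), function(i)
  any(sh$chrom == truth$chrom[i] & sh$state == truth$state[i] &
      abs(sh$start - truth$start[i]) <= 5e4 &
      abs(sh$end - truth$end[i]) <= 5e4), logical(1))
message("shatter01 truth recovery (>100 kb, within one bin): ",
        sum(hit[truth$end - truth$start > 1e5]), "/",
        sum(truth$end - truth$start > 1e5))
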