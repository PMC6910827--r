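#!/usr/bin/env Rscript
# Haplotype assignment: which homolog do the de novo CNAs and junctions
# affect? CNAs are assigned from BAF shifts at phase-informative SNPs;
# junctions from allele counts among junction-supporting read pairs.

suppressPackageStartupMessages(library(chromoshatter))
sim <- "results/simulated"
out <- "results"

parental <- read_snp_table(file.path(sim, "parental_snps.tsv"))
baseline <- read_snp_table(file.path(sim, "intact01_snps.tsv"))
clone <- read_snp_table(file.path(sim, "shatter01_snps.tsv"))
info <- find_phase_informative_snps(parental, baseline, "chr1")
message(nrow(info), " phase-informative SNPs on chr1")

calls <- read_segments(file.path(out, "cna_calls.tsv"))
calls <- calls[calls$clone_id == "shatter01" & calls$unique, ]
verdicts <- lapply(seq_len(nrow(calls)), function(i)
  assign_cna_allele_baf(calls[i, ], info, clone))
calls$verdict <- vapply(verdicts, `[[`, character(1), "verdict")
calls$n_votes <- vapply(verdicts, `[[`, integer(1), "n_total")
write_segments(calls, file.path(out, "cna_haplotype_calls.tsv"))

fr <- summarize_affected_fraction(verdicts)
message(sprintf(
  "CNAs affecting the transferred homolog: %d/%d non-ambiguous (%.1f%%), %d ambiguous",
  fr$n_transferred, fr$n_transferred + fr$n_endogenous,
  100 * fr$fraction, fr$n_ambiguous))

rp <- utils::read.delim(file.path(sim, "shatter01_readpairs.tsv"))
jv <- do.call(rbind, lapply(split(rp, rp$junction_id), function(d) {
  hc <- assign_junction_allele_reads(d)
  data.frame(junction_id = d$junction_id[1], verdict = hc$verdict,
             n_pairs = hc$n_total, stringsAsFactors = FALSE)
}))
utils::write.table(jv, file.path(out, "junction_haplotype_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("junction verdicts: ",
        paste(names(table(jv$verdict)), table(jv$verdict),
              sep = "=", collapse = ", "))
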