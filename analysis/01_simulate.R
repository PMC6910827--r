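#!/usr/bin/env Rscript
# Simulate the study system: a trisomic clone whose transferred homolog was
# shattered in a micronucleus, a replicative-rearrangement clone, an intact
# trisomic sibling and the diploid parental line. Writes every downstream
# pipeline input plus the ground truth under results/simulated/.

suppressPackageStartupMessages(library(chromoshatter))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924

spec <- genome_spec()  # 3 x 10 Mb, SNPs every 5 kb, 30% informative, chr1 trisomic
genome <- simulate_reference(spec, seed = seed, sequence = TRUE)
write_reference(genome$reference, file.path(out, "reference.fa"))

shatter <- simulate_shattering(
  genome, k_breakpoints = 20, deletion_fraction = 0.4, seed = seed + 1,
  features = junction_feature_config(p_blunt = 0.2, p_microhomology = 0.5,
                                     p_insertion = 0.3, p_templated = 0.5),
  clone_id = "shatter01")
chromo <- simulate_chromoanasynthesis(genome, n_switches = 6,
                                      seed = seed + 2,
                                      clone_id = "chromoana01")
intact <- simulate_intact(genome, clone_id = "intact01")

message("shattering: ", nrow(shatter$derived_structure), " fragments, ",
        nrow(shatter$junctions), " junctions, ",
        nrow(true_cnas(shatter)), " true CNAs")
message("chromoanasynthesis: ", nrow(chromo$junctions), " junctions, copy states ",
        paste(sort(unique(chromo$cn_profile$cn_total[
          chromo$cn_profile$chrom == "chr1"])), collapse = "/"))

noise_baf <- 0.03
for (tr in list(shatter, chromo, intact)) {
  prof <- render_snp_profile(tr, noise_sd = noise_baf, seed = seed + 3)
  write_snp_table(prof$clone,
                  file.path(out, paste0(tr$clone_id, "_snps.tsv")))
  if (tr$clone_id == "shatter01")
    write_snp_table(prof$parental, file.path(out, "parental_snps.tsv"))
  segs <- render_quantal_segments(tr, bin_size = 5e4, noise_sd = 0.05,
                                  seed = seed + 4)
  write_segments(segs, file.path(out, paste0(tr$clone_id, "_segments.tsv")))
  write_segments(true_cnas(tr),
                 file.path(out, paste0(tr$clone_id, "_true_cnas.tsv")))
}
write_segments(render_parental_segments(genome, noise_sd = 0.05,
                                        seed = seed + 5),
               file.path(out, "parental_segments.tsv"))

rj <- render_junction_records(shatter, flank_len = 300, seed = seed + 6)
write_junctions(rj$junctions, file.path(out, "shatter01_junctions.bedpe"))
write_reference(rj$reference, file.path(out, "reference_edited.fa"))
utils::write.table(rj$features, file.path(out, "shatter01_true_features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
rp <- render_readpair_counts(shatter, coverage_mean = 8, error_rate = 0.01,
                             seed = seed + 7)
utils::write.table(rp, file.path(out, "shatter01_readpairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("inputs written to ", out)
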