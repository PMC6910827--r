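#!/usr/bin/env Rscript
# Breakpoint junction forensics on the shattered clone: orientation
# spectrum, microhomology/insertion classification from contigs, templated
# insertion search, breakpoint density and the chromothripsis hallmark
# panel.

suppressPackageStartupMessages(library(chromoshatter))
sim <- "results/simulated"
out <- "results"

junctions <- read_junctions(file.path(sim, "shatter01_junctions.bedpe"),
                            clone_id = "shatter01")
reference <- read_reference(file.path(sim, "reference_edited.fa"))

feats <- junction_features(junctions, reference, flank_len = 300)
utils::write.table(feats, file.path(out, "junction_features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("feature classes: ",
        paste(names(table(feats$feature_class)), table(feats$feature_class),
              sep = "=", collapse = ", "))
truth <- utils::read.delim(file.path(sim, "shatter01_true_features.tsv"))
m <- merge(truth, feats, by = "name")
message("agreement with planted truth: ",
        sum(m$mh_len == m$microhomology_len & m$ins_len == m$insertion_len),
        "/", nrow(m))

spect <- orientation_spectrum(junctions, min_span = 1e4)
mt <- multinomial_uniform_test(spect$counts)
message("orientation spectrum (>10 kb): ",
        paste(names(spect$counts), spect$counts, sep = "=", collapse = ", "),
        "; uniformity p = ", signif(mt$p_value, 3), " (", mt$method, ")")

bp <- breakpoints_per_chromosome(junctions, c("chr1", "chr2", "chr3"))
utils::write.table(bp, file.path(out, "breakpoints_per_chromosome.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth_prof <- utils::read.delim(file.path(sim, "shatter01_true_cnas.tsv"))
segs <- read_segments(file.path(sim, "shatter01_segments.tsv"))
osc <- copy_number_oscillations(round(segs$quantal[segs$chrom == "chr1"]))
panel <- chromothripsis_report(
  data.frame(chrom = segs$chrom, cn_total = round(segs$quantal)),
  junctions, feats, "chr1")
write_report(list(
  hallmark_panel = data.frame(
    metric = c("junctions_aneuploid", "junctions_other",
               "orientation_classes", "oscillation_transitions",
               "oscillation_states", "uniformity_p"),
    value = c(panel$n_junctions_aneuploid, panel$n_junctions_other,
              panel$n_orientation_classes, panel$oscillation_transitions,
              panel$oscillation_states,
              signif(panel$orientation_uniformity_p, 4))),
  breakpoints = bp), file.path(out, "hallmarks"))
message("hallmark panel written to ", file.path(out, "hallmarks"))
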