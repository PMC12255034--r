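#!/usr/bin/env Rscript
# Stage 1 — generate the coupled synthetic multi-omics dataset.
#
# One shared genome with canonical PQS motifs planted in every promoter,
# then two conditions over it: WT, and a DNMT1-knockout-like condition in
# which every true methylation level is halved. Outputs are the standard
# text formats the analysis stages read back (FASTA, TSV, bedGraph, BED),
# plus the generator's ground truth for reference.

suppressPackageStartupMessages(library(g4meth))

seed <- 42L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_chrom = 4L, n_genes = 1200L)
message("simulating WT/KO pair: ", cfg$n_genes, " genes, ",
        cfg$n_chrom, " chromosomes, seed ", seed)
pair <- simulate_pair(cfg, seed)

Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$sim$genome),
                            file.path(out, "genome.fa"))
write.table(pair$sim$anchors, file.path(out, "anchors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pair$sim$pqs, file.path(out, "planted_pqs_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (cond in c("wt", "ko")) {
  x <- pair[[cond]]
  write_cpg_calls(x$meth$calls, file.path(out, paste0("calls_", cond, ".tsv")))
  write_bedgraph(x$g4$track, file.path(out, paste0("g4_", cond, ".bedgraph")))
  write_bedgraph(x$g4$igg, file.path(out, paste0("igg_", cond, ".bedgraph")))
  write_bedgraph(x$atac$track,
                 file.path(out, paste0("atac_", cond, ".bedgraph")))
  write_bed(x$g4$peaks, file.path(out, paste0("g4_peaks_", cond, ".bed")))
  write_bed(x$atac$peaks,
            file.path(out, paste0("atac_peaks_", cond, ".bed")))
  write.table(x$g4$truth, file.path(out, paste0("g4_truth_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(pair$expr$de, file.path(out, "de_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = rownames(pair$expr$counts),
                       pair$expr$counts),
            file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("planted PQSs: ", nrow(pair$sim$pqs))
message("WT G4 peaks: ", nrow(pair$wt$g4$peaks),
        "; KO G4 peaks: ", nrow(pair$ko$g4$peaks))
message("wrote ", out)
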