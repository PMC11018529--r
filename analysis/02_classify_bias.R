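#!/usr/bin/env Rscript
# Homoeolog expression bias in the simulated hexaploid: TPM, expressed-gene
# filter, replicate averaging, triad relative expression, nearest-ideal-point
# categories, per-tissue category percentages, relative subgenome abundance
# and per-tissue up-regulated homoeolog counts. Reads results/simulated/,
# writes results/bias/.

library(subgenomeBias)

sim_dir <- "results/simulated"
out <- "results/bias"
stopifnot(dir.exists(sim_dir))

paths <- run_classify(file.path(sim_dir, "expression.tsv"),
                      file.path(sim_dir, "meta.tsv"),
                      file.path(sim_dir, "map.tsv"),
                      lengths_path = file.path(sim_dir, "lengths.tsv"),
                      out_dir = out)

pct <- read.delim(file.path(out, "percent.tsv"), check.names = FALSE)
cat("Category percentages (all tissues):\n")
print(round(pct[pct$tissue == "all_tissues", -1], 2))
ab <- read.delim(file.path(out, "abundance.tsv"))
cat("Relative subgenome abundance (%):\n")
print(ab)

# replicate-level differential expression per tissue (Welch t on log2(TPM+1),
# BH within tissue, |log2FC| >= 1)
m <- read_expression(file.path(sim_dir, "expression.tsv"),
                     file.path(sim_dir, "meta.tsv"))
len <- read.delim(file.path(sim_dir, "lengths.tsv"))
m <- filter_expressed(counts_to_tpm(m, setNames(len$length_bp, len$gene_id)))
map <- read_homoeolog_map(file.path(sim_dir, "map.tsv"), "triad")
up_all <- do.call(rbind, lapply(unique(m$meta$tissue), function(tt) {
  cbind(tissue = tt, upregulated_counts(m, map, tt)$counts)
}))
write.table(up_all, file.path(out, "upregulated_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Up-regulated homoeolog counts written to",
    file.path(out, "upregulated_counts.tsv"), "\n")
print(aggregate(n_up ~ up, up_all, sum))
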