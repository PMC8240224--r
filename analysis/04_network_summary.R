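#!/usr/bin/env Rscript

# Network descriptors. First summarizes a deterministic graph at the
# scale of the study's reported interaction network (1248 nodes, 5604
# edges) to show the descriptor arithmetic, then builds a co-enrichment
# edge list over the simulated symbols (enriched symbols densely
# connected, a sparse background elsewhere) and summarizes the subgraph
# induced by the selected candidates. Outputs land in results/network/.

suppressPackageStartupMessages(library(pepfreq))
library(data.table)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# study-scale ring-plus-chords graph: 1248 nodes, 5604 edges
n <- 1248L; e <- 5604L
from <- integer(0); to <- integer(0); k <- 1L
while (length(from) < e) {
  take <- min(n, e - length(from))
  i <- seq_len(take)
  from <- c(from, i); to <- c(to, ((i + k - 1L) %% n) + 1L)
  k <- k + 1L
}
gs <- graph_summary(data.table(from = sprintf("n%04d", from),
                               to = sprintf("n%04d", to)))
cat(sprintf("study-scale graph: %d nodes, %d edges, average degree %.2f, avg local clustering %.3f\n",
            gs$nodes, gs$edges, gs$average_degree,
            gs$average_local_clustering))

# co-enrichment edge list over the simulated truth
stopifnot(file.exists("results/sim/truth.tsv"))
truth <- fread("results/sim/truth.tsv")
set.seed(seed)
enr <- truth[enriched == TRUE, gene_symbol]
bg <- truth[enriched == FALSE, gene_symbol]
el <- rbind(
  if (length(enr) >= 2) as.data.table(t(combn(enr, 2))) else NULL,
  data.table(V1 = sample(bg, 150, replace = TRUE),
             V2 = sample(bg, 150, replace = TRUE)))[V1 != V2]
setnames(el, c("from", "to"))
fwrite(el, file.path(out, "edges.tsv"), sep = "\t", quote = FALSE,
       col.names = FALSE)

full <- graph_summary(el)
sel <- fread("results/comparison/candidates_TRYP.tsv")$gene_symbol
induced <- subnetwork_by_selection(el, sel)
cat(sprintf("simulated network: %d nodes, %d edges, average degree %.2f\n",
            full$nodes, full$edges, full$average_degree))
cat(sprintf("induced by %d selected candidates: %d nodes, %d edges, average degree %.2f, clustering %.3f\n",
            length(sel), induced$summary$nodes, induced$summary$edges,
            induced$summary$average_degree,
            induced$summary$average_local_clustering))

jsonlite::write_json(
  list(study_scale = gs[c("nodes", "edges", "average_degree",
                          "average_local_clustering")],
       simulated = full[c("nodes", "edges", "average_degree",
                          "average_local_clustering")],
       induced = induced$summary[c("nodes", "edges", "average_degree",
                                   "average_local_clustering")]),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote", out, "\n")
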