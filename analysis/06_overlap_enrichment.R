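#!/usr/bin/env Rscript

# Step 6 — overlap statistics: Fisher's-exact matrices between DEG clusters
# and DHS pattern gene sets, bivalency vs promoter opening, Dmrt binding vs
# opening, and preranked GSEA of opening/closing genes in the
# end-vs-start expression ranking.

suppressMessages(library(dhsdyn))

bundle <- read_fixture_bundle("results/fixture")
res <- analyze_bundle(bundle)
expr <- expression_values(bundle$counts)
times <- stage_times(bundle$counts$samples$stage)
universe <- bundle$truth$gene_id

deg <- timecourse_deg(expr, times)
deg_ids <- deg$gene_id[deg$is_deg]
cl <- cluster_profiles(expr, bundle$counts$samples$stage, genes = deg_ids,
                       k = 9, seed = 99L)
deg_clusters <- split(names(cl$cluster), paste0("cluster", cl$cluster))

## DEG clusters x DHS pattern sets
m1 <- overlap_matrix(deg_clusters, res$pattern_sets, universe)
write.table(data.frame(cluster = rownames(m1$p), -log10(m1$p),
                       check.names = FALSE),
            "results/overlap_degclusters_x_patterns.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("DEG clusters x DHS pattern sets:",
    sum(m1$q < 0.05), "of", length(m1$q), "cells enriched at q < 0.05\n")

## bivalent genes vs opening genes
dyn <- res$dynamics$genes
opening <- dyn$gene_id[dyn$class == "opening"]
bivalent <- res$marks$gene_id[res$marks$category == "bivalent"]
tab <- overlap_table(bivalent, opening, universe)
p_bo <- fisher_exact(tab["a"], tab["b"], tab["c"], tab["d"])
cat(sprintf("\n%d of %d bivalent genes open during differentiation (P = %.3g)\n",
            tab[["a"]], length(bivalent), p_bo))

## Dmrt-bound genes vs opening genes
dmrt <- bundle$truth$gene_id[bundle$truth$dmrt_bound]
tab2 <- overlap_table(dmrt, opening, universe)
p_do <- fisher_exact(tab2["a"], tab2["b"], tab2["c"], tab2["d"])
cat(sprintf("%d of %d Dmrt-bound genes open (P = %.3g)\n",
            tab2[["a"]], length(dmrt), p_do))
## Dmrt-bound vs bivalent (the repressor-bivalency association)
tab3 <- overlap_table(dmrt, bivalent, universe)
p_db <- fisher_exact(tab3["a"], tab3["b"], tab3["c"], tab3["d"])
cat(sprintf("%d Dmrt-bound genes are bivalent (P = %.3g)\n",
            tab3[["a"]], p_db))

## GSEA: opening/closing genes in the E16-vs-E12 expression ranking
lfc <- log2((rowMeans(expr[, times == max(times)]) + 1) /
              (rowMeans(expr[, times == min(times)]) + 1))
g_open <- gsea_preranked(lfc, opening, n_perm = 1000, seed = 5L)
closing <- dyn$gene_id[dyn$class == "closing"]
g_close <- gsea_preranked(lfc, closing, n_perm = 1000, seed = 5L)
cat(sprintf("\nGSEA, opening genes in E16/E12 ranking: ES = %.3f, p = %.3g\n",
            g_open$es, g_open$p))
cat(sprintf("GSEA, closing genes in E16/E12 ranking: ES = %.3f, p = %.3g\n",
            g_close$es, g_close$p))
gsea_tab <- data.frame(
  gene_set = c("opening", "closing"),
  es = c(g_open$es, g_close$es), nes = c(g_open$nes, g_close$nes),
  p = c(g_open$p, g_close$p),
  leading_edge = c(length(g_open$leading_edge),
                   length(g_close$leading_edge)))
write.table(gsea_tab, "results/gsea_opening_closing.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
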