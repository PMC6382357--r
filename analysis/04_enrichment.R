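#!/usr/bin/env Rscript
# Stage 4: over-representation of the 3D-EV-specific detection set and
# ranked running-sum enrichment over the 3D-EV abundance ordering.

source(file.path("analysis", "00_settings.R"))

mirna <- read_expression_matrix(data_path("mirna_fpkm.tsv"),
                                data_path("mirna_meta.tsv"))
cats <- read_category_db(data_path("categories.tsv"))

grouping <- sample_groups(mirna, by = c("condition", "entity"))
det <- call_detected(mirna, grouping,
                     threshold = SETTINGS$detection$threshold,
                     min_replicates = SETTINGS$detection$min_replicates)

universe <- rownames(det)[det[, "3D_EV"]]
query <- composite_set(det, include = "3D_EV", exclude = "2D_EV")

ora_res <- ora(query, universe, cats)
write_tsv(ora_res, res_path("ora.tsv"))

s <- mirna$samples
ev_2d <- s$sample_id[s$condition == "2D" & s$entity == "EV"]
ev_3d <- s$sample_id[s$condition == "3D" & s$entity == "EV"]
gsea_res <- gsea_ranked_mirnas(mirna, cats,
                               rank_by = SETTINGS$gsea$rank_by,
                               features = universe, samples = ev_3d,
                               group_a = ev_2d, group_b = ev_3d)
write_tsv(as.data.frame(gsea_res), res_path("gsea.tsv"))

message(sum(ora_res$significant), " categories over-represented; ",
        sum(gsea_res$p_exact < 0.05), " of ", nrow(gsea_res),
        " enriched in the ranked test at p < 0.05")
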