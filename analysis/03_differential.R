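#!/usr/bin/env Rscript
# Stage 3: 3D-vs-2D fold changes for miRNAs (cell and EV calls combined)
# and EV proteins, row-wise Z-scores with hierarchical ordering for
# heatmap-style display, and the top discriminating proteins.

source(file.path("analysis", "00_settings.R"))

mirna <- read_expression_matrix(data_path("mirna_fpkm.tsv"),
                                data_path("mirna_meta.tsv"))
protein <- read_expression_matrix(data_path("protein_abundance.tsv"),
                                  data_path("protein_meta.tsv"))

grp <- function(em, cond, ent) {
  s <- em$samples
  s$sample_id[s$condition == cond & s$entity == ent]
}

fc_cell <- fold_change(mirna, grp(mirna, "2D", "cell"),
                       grp(mirna, "3D", "cell"))
fc_ev <- fold_change(mirna, grp(mirna, "2D", "EV"), grp(mirna, "3D", "EV"))
fc_mirna <- combine_entity_calls(fc_cell, fc_ev)
write_tsv(fc_mirna, res_path("mirna_fold_change.tsv"))

fc_protein <- fold_change(protein, grp(protein, "2D", "EV"),
                          grp(protein, "3D", "EV"))
write_tsv(fc_protein, res_path("protein_fold_change.tsv"))

# Z-scored protein rows plus a clustering order for display
z <- zscore_rows(protein)
ord <- hierarchical_order(z, axis = "features")
write_tsv(data.frame(feature_id = feature_ids(protein)[ord$order],
                     display_rank = seq_along(ord$order)),
          res_path("protein_heatmap_order.tsv"))

top <- top_discriminating(protein, grp(protein, "2D", "EV"),
                          grp(protein, "3D", "EV"),
                          k = min(SETTINGS$top_k, nrow(protein$values)))
write_tsv(top, res_path("top_proteins.tsv"))

message(sum(fc_mirna$status == "ok"), " miRNA fold changes defined; top ",
        nrow(top), " proteins written")
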