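#!/usr/bin/env Rscript
# Stage 1: simulate the paired miRNA / protein study and write the raw
# tables that every downstream driver consumes.

source(file.path("analysis", "00_settings.R"))

cfg <- synthetic_config(seed = SETTINGS$seed)
ds <- generate_dataset(cfg)

write_expression_matrix(ds$mirna_matrix,
                        data_path("mirna_fpkm.tsv"),
                        data_path("mirna_meta.tsv"))
write_expression_matrix(ds$protein_matrix,
                        data_path("protein_abundance.tsv"),
                        data_path("protein_meta.tsv"))
write_tsv(as.data.frame(ds$edges), data_path("target_edges.tsv"))

# categories in long format (category_id, member_id)
cat_long <- do.call(rbind, lapply(ds$categories, function(cc)
  data.frame(category_id = cc$name, member_id = cc$members,
             stringsAsFactors = FALSE)))
write_tsv(cat_long, data_path("categories.tsv"))

# ground truth, kept separate from the analysis inputs
write_tsv(ds$truth$planted_edges, data_path("truth_planted_edges.tsv"))
write_tsv(
  data.frame(feature_id = names(ds$truth$true_log2fc),
             true_log2fc = unname(ds$truth$true_log2fc)),
  data_path("truth_log2fc.tsv"))

message("simulated ", nrow(ds$mirna_matrix$values), " miRNAs and ",
        nrow(ds$protein_matrix$values), " proteins at seed ",
        SETTINGS$seed)
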