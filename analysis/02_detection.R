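#!/usr/bin/env Rscript
# Stage 2: detection calls per condition/entity group, the four-way Venn
# partition, the composite "everywhere except 2D EVs" set, and
# housekeeping-style reference candidates.

source(file.path("analysis", "00_settings.R"))

mirna <- read_expression_matrix(data_path("mirna_fpkm.tsv"),
                                data_path("mirna_meta.tsv"))

grouping <- sample_groups(mirna, by = c("condition", "entity"))
det <- call_detected(mirna, grouping,
                     threshold = SETTINGS$detection$threshold,
                     min_replicates = SETTINGS$detection$min_replicates)

write_tsv(data.frame(feature_id = rownames(det), as.data.frame(det + 0)),
          res_path("detection_calls.tsv"))

part <- venn_partition(det)
write_tsv(data.frame(region = names(part$sizes),
                     n = as.integer(part$sizes)),
          res_path("venn_regions.tsv"))

shared <- composite_set(det, include = c("2D_cell", "3D_cell", "3D_EV"),
                        exclude = "2D_EV")
write_tsv(data.frame(feature_id = shared),
          res_path("shared_cells_3dev_only.tsv"))

hk <- select_housekeeping_candidates(mirna)
write_tsv(data.frame(feature_id = hk),
          res_path("housekeeping_candidates.tsv"))

message(sum(rowSums(det) > 0), " features detected in at least one group; ",
        length(shared), " shared by cells and 3D EVs but absent from 2D EVs")
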