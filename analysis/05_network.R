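#!/usr/bin/env Rscript
# Stage 5: miRNA-protein coregulation network (target evidence plus
# anti-correlated 3D-vs-2D deregulation), its connected components, and
# recovery scores against the simulated ground truth.

source(file.path("analysis", "00_settings.R"))

fc_mirna <- utils::read.delim(res_path("mirna_fold_change.tsv"))
fc_protein <- utils::read.delim(res_path("protein_fold_change.tsv"))
edges <- read_target_edges(data_path("target_edges.tsv"))

net <- build_network(fc_mirna, fc_protein, edges,
                     mode = SETTINGS$network$mode,
                     evidence = SETTINGS$network$evidence,
                     magnitude_threshold =
                       SETTINGS$network$magnitude_threshold)
clusters <- extract_clusters(net)

write_tsv(net$edges, res_path("network_edges.tsv"))
jsonlite::write_json(
  list(mirna_nodes = net$mirna_nodes, protein_nodes = net$protein_nodes,
       edges = net$edges, provenance = net$provenance,
       clusters = lapply(clusters, function(cl)
         cl[c("mirnas", "proteins", "shared_targets")])),
  res_path("network.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", res_path("network.json"))

truth <- utils::read.delim(data_path("truth_planted_edges.tsv"))
truth_key <- paste(truth$mirna_id, truth$protein_id)
found_key <- paste(net$edges$mirna_id, net$edges$protein_id)
tp <- sum(found_key %in% truth_key)
scores <- data.frame(
  n_edges = nrow(net$edges), n_clusters = length(clusters),
  precision = if (length(found_key)) tp / length(found_key) else NA,
  recall = tp / length(truth_key))
write_tsv(scores, res_path("network_scores.tsv"))

message(sprintf("%d edges in %d clusters; precision %.3f, recall %.3f",
                scores$n_edges, scores$n_clusters, scores$precision,
                scores$recall))
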