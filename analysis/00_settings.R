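# Shared settings for the numbered analysis drivers. Each driver sources
# this file, so a single edit here changes the whole workflow. Override
# the root seed with the EVINTEGRA_SEED environment variable.

suppressPackageStartupMessages(library(evintegra))

SETTINGS <- list(
  seed = as.integer(Sys.getenv("EVINTEGRA_SEED", "1")),
  results_dir = "results",
  data_dir = file.path("results", "data"),
  detection = list(threshold = 0, min_replicates = 1L),
  network = list(mode = "opposite_sign", evidence = "strong_or_weak",
                 magnitude_threshold = 0.5),
  gsea = list(rank_by = "mean_abundance"),
  top_k = 20L,
  yield = list(n_replicates = 4L, mean_ratio_2d = 80,
               mean_ratio_3d = 40, cv = 0.25)
)

dir.create(SETTINGS$data_dir, recursive = TRUE, showWarnings = FALSE)

res_path <- function(...) file.path(SETTINGS$results_dir, ...)
data_path <- function(...) file.path(SETTINGS$data_dir, ...)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
}
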