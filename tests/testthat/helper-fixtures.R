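# Small in-code fixtures shared across test files.

# a 2-condition x 2-entity x n_rep design for one cell line
toy_samples <- function(n_rep = 2L, cell_line = "MKN45") {
  grid <- expand.grid(replicate = seq_len(n_rep),
                      entity = c("cell", "EV"),
                      condition = c("2D", "3D"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", cell_line, grid$condition,
                        grid$entity, grid$replicate),
    cell_line = cell_line,
    condition = grid$condition,
    entity = grid$entity,
    replicate = grid$replicate,
    stringsAsFactors = FALSE)
}

toy_matrix <- function(values, n_rep = 2L, unit = "FPKM") {
  samples <- toy_samples(n_rep)
  stopifnot(ncol(values) == nrow(samples))
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples, unit_label = unit)
}

# random detection fixture: features x groups logical matrix
random_detection_fixture <- function(n_features, groups, seed) {
  set.seed(seed)
  det <- matrix(runif(n_features * length(groups)) > 0.5,
                nrow = n_features,
                dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                groups))
  structure(det, class = c("DetectionTable", "matrix"),
            threshold = 0, min_replicates = 1L)
}
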