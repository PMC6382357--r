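#' Configuration for the synthetic 2D/3D EV study generator
#'
#' Defines the emulated study: two gastric-cancer-like cell lines crossed
#' with culture condition (2D/3D) and entity (cell/EV), a small-RNA matrix
#' with many zeros in EV samples, and a planted coregulation structure in
#' which a set of miRNAs is upregulated in 3D while their strong-evidence
#' target proteins are downregulated in 3D EVs.
#'
#' @param n_mirna,n_protein Numbers of miRNA and protein features.
#' @param n_replicates Biological replicates per (cell line, condition,
#'   entity) group.
#' @param cell_lines Labels for the two cell lines.
#' @param n_planted_pairs Number of planted miRNA->protein pairs.
#' @param mirna_log2fc_3d Planted miRNA effect, log2(3D/2D), applied in
#'   both cell and EV samples.
#' @param protein_log2fc_3d Planted protein effect, log2(3D/2D), applied
#'   in 3D EV samples (and in cell samples when
#'   `protein_effect_in_cells = TRUE`).
#' @param noise_sd_log Replicate noise SD on the log2 scale.
#' @param zero_inflation_ev Probability that an EV small-RNA cell is zeroed
#'   (dropout); planted miRNAs are exempt.
#' @param baseline_log2_mean,baseline_log2_sd Feature baseline abundance
#'   distribution on the log2 scale.
#' @param frac_exclusive_per_group Fraction of features made exclusive to
#'   each (condition, entity) group (zero everywhere else).
#' @param n_decoy_edges Background (non-planted) target edges emitted
#'   alongside the planted ones.
#' @param n_background_categories,category_size_range Random categories
#'   added to the emitted category database.
#' @param protein_effect_in_cells Also apply the protein effect in cell
#'   samples.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_mirna = 200L,
                             n_protein = 150L,
                             n_replicates = 2L,
                             cell_lines = c("MKN45", "MKN74"),
                             n_planted_pairs = 20L,
                             mirna_log2fc_3d = 1.5,
                             protein_log2fc_3d = -1.0,
                             noise_sd_log = 0.25,
                             zero_inflation_ev = 0.4,
                             baseline_log2_mean = 6,
                             baseline_log2_sd = 2,
                             frac_exclusive_per_group = 0.05,
                             n_decoy_edges = 200L,
                             n_background_categories = 20L,
                             category_size_range = c(5L, 30L),
                             protein_effect_in_cells = FALSE,
                             seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna),
              n_protein = as.integer(n_protein),
              n_replicates = as.integer(n_replicates),
              cell_lines = cell_lines,
              n_planted_pairs = as.integer(n_planted_pairs),
              mirna_log2fc_3d = mirna_log2fc_3d,
              protein_log2fc_3d = protein_log2fc_3d,
              noise_sd_log = noise_sd_log,
              zero_inflation_ev = zero_inflation_ev,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              frac_exclusive_per_group = frac_exclusive_per_group,
              n_decoy_edges = as.integer(n_decoy_edges),
              n_background_categories = as.integer(n_background_categories),
              category_size_range = as.integer(category_size_range),
              protein_effect_in_cells = isTRUE(protein_effect_in_cells),
              seed = as.integer(seed))
  if (cfg$n_planted_pairs > min(cfg$n_mirna, cfg$n_protein))
    stop("n_planted_pairs exceeds min(n_mirna, n_protein)")
  if (cfg$zero_inflation_ev < 0 || cfg$zero_inflation_ev > 1)
    stop("zero_inflation_ev must be in [0, 1]")
  if (cfg$frac_exclusive_per_group < 0 || cfg$frac_exclusive_per_group > 1)
    stop("frac_exclusive_per_group must be in [0, 1]")
  if (cfg$noise_sd_log <= 0) stop("noise_sd_log must be > 0")
  if (length(cfg$cell_lines) < 1L) stop("need at least one cell line")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  class(cfg) <- "SyntheticConfig"
  cfg
}

design_samples <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      entity = c("cell", "EV"),
                      condition = c("2D", "3D"),
                      cell_line = cfg$cell_lines,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("cell_line", "condition", "entity", "replicate")]
  grid$sample_id <- sprintf("%s_%s_%s_r%d", grid$cell_line, grid$condition,
                            grid$entity, grid$replicate)
  grid[, c("sample_id", "cell_line", "condition", "entity", "replicate")]
}

#' Generate a synthetic 2D/3D cell+EV dataset with known ground truth
#'
#' Abundances are drawn log-normally around per-feature baselines with
#' multiplicative condition effects: planted miRNAs carry
#' `mirna_log2fc_3d` in all 3D samples; their target proteins carry
#' `protein_log2fc_3d` in 3D EV samples. EV small-RNA entries are
#' independently zeroed with probability `zero_inflation_ev` (planted
#' miRNAs exempt), emulating the sparse EV cargo. A configurable fraction
#' of features is made exclusive to each (condition, entity) group.
#'
#' @param config A [synthetic_config()].
#' @return List with `mirna_matrix`, `protein_matrix` (both
#'   `ExpressionMatrix`), `edges` (planted strong edges plus weak decoys),
#'   `categories` (a `CategoryDB` containing the planted-miRNA category
#'   `planted_3d_up` plus random background categories) and `truth`
#'   (planted edges, exclusive features per group, true log2 fold changes).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- config
  if (!inherits(cfg, "SyntheticConfig")) cfg <- do.call(synthetic_config, cfg)
  set.seed(cfg$seed)

  mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirna))
  protein_ids <- sprintf("PROT%03d", seq_len(cfg$n_protein))
  samples <- design_samples(cfg)
  is_3d <- samples$condition == "3D"
  is_ev <- samples$entity == "EV"

  planted_mirna <- sample(mirna_ids, cfg$n_planted_pairs)
  planted_protein <- sample(protein_ids, cfg$n_planted_pairs)

  draw_matrix <- function(ids, effect_log2) {
    base <- stats::rnorm(length(ids), cfg$baseline_log2_mean,
                         cfg$baseline_log2_sd)
    noise <- matrix(stats::rnorm(length(ids) * nrow(samples),
                                 0, cfg$noise_sd_log),
                    nrow = length(ids))
    log2v <- base + effect_log2 + noise
    vals <- 2^log2v
    dimnames(vals) <- list(ids, samples$sample_id)
    vals
  }

  # planted miRNA effect in all 3D samples (cells and EVs)
  m_eff <- matrix(0, cfg$n_mirna, nrow(samples),
                  dimnames = list(mirna_ids, samples$sample_id))
  m_eff[planted_mirna, is_3d] <- cfg$mirna_log2fc_3d
  mirna_vals <- draw_matrix(mirna_ids, m_eff)

  # planted protein effect in 3D EV samples (optionally cells too)
  p_cols <- if (cfg$protein_effect_in_cells) is_3d else (is_3d & is_ev)
  p_eff <- matrix(0, cfg$n_protein, nrow(samples),
                  dimnames = list(protein_ids, samples$sample_id))
  p_eff[planted_protein, p_cols] <- cfg$protein_log2fc_3d
  protein_vals <- draw_matrix(protein_ids, p_eff)

  # group-exclusive miRNAs: zero outside the designated (condition, entity)
  groups <- unique(paste(samples$condition, samples$entity, sep = "_"))
  sample_group <- paste(samples$condition, samples$entity, sep = "_")
  n_excl <- round(cfg$frac_exclusive_per_group * cfg$n_mirna)
  free <- setdiff(mirna_ids, planted_mirna)
  exclusive <- list()
  for (g in groups) {
    take <- if (n_excl > 0 && length(free) >= n_excl)
      sample(free, n_excl) else character(0)
    free <- setdiff(free, take)
    exclusive[[g]] <- take
    if (length(take))
      mirna_vals[take, sample_group != g] <- 0
  }

  # EV dropout for small RNA; planted miRNAs exempt; for EV-exclusive
  # features keep replicate 1 so the exclusivity truth stays detectable
  ev_cols <- which(is_ev)
  drop_mask <- matrix(stats::runif(cfg$n_mirna * length(ev_cols)) <
                        cfg$zero_inflation_ev,
                      nrow = cfg$n_mirna)
  rownames(drop_mask) <- mirna_ids
  drop_mask[planted_mirna, ] <- FALSE
  keep_rep1 <- samples$replicate[ev_cols] == 1L
  for (g in grep("_EV$", groups, value = TRUE)) {
    gi <- sample_group[ev_cols] == g
    drop_mask[exclusive[[g]], gi & keep_rep1] <- FALSE
  }
  mirna_vals[, ev_cols][drop_mask] <- 0

  planted_edges <- data.frame(mirna_id = planted_mirna,
                              protein_id = planted_protein,
                              evidence = rep("strong", length(planted_mirna)),
                              stringsAsFactors = FALSE)
  decoys <- data.frame(
    mirna_id = sample(mirna_ids, cfg$n_decoy_edges, replace = TRUE),
    protein_id = sample(protein_ids, cfg$n_decoy_edges, replace = TRUE),
    evidence = sample(c("strong", "weak"), cfg$n_decoy_edges,
                      replace = TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE)
  # a decoy may touch one planted endpoint (a hard negative) but never
  # both: an edge joining a truly up miRNA to a truly down protein would
  # make the planted truth ill-defined
  confounded <- decoys$mirna_id %in% planted_mirna &
    decoys$protein_id %in% planted_protein
  decoys <- decoys[!confounded, ]
  edges <- target_edges(rbind(planted_edges, decoys))

  cats <- list()
  if (length(planted_mirna) > 0)
    cats$planted_3d_up <- list(name = "planted_3d_up",
                               members = sort(planted_mirna))
  if (cfg$n_background_categories > 0) {
    sizes <- sample(seq(cfg$category_size_range[1L],
                        cfg$category_size_range[2L]),
                    cfg$n_background_categories, replace = TRUE)
    for (i in seq_len(cfg$n_background_categories)) {
      id <- sprintf("bg_cat_%02d", i)
      cats[[id]] <- list(name = id,
                         members = sort(sample(mirna_ids, sizes[i])))
    }
  }

  true_log2fc <- c(stats::setNames(rep(0, cfg$n_mirna), mirna_ids),
                   stats::setNames(rep(0, cfg$n_protein), protein_ids))
  true_log2fc[planted_mirna] <- cfg$mirna_log2fc_3d
  true_log2fc[planted_protein] <- cfg$protein_log2fc_3d

  list(
    mirna_matrix = expression_matrix(mirna_vals, samples, "FPKM"),
    protein_matrix = expression_matrix(
      protein_vals, samples, "normalized reporter abundance"),
    edges = edges,
    categories = category_db(cats),
    truth = list(planted_edges = planted_edges,
                 exclusive_features = exclusive,
                 true_log2fc = true_log2fc,
                 config = cfg)
  )
}

#' Generate per-replicate EV yield records
#'
#' Emulates nanoparticle-tracking yield experiments: per replicate, a total
#' particle count and a total cell count whose ratio (EVs per cell) is
#' log-normal with the requested condition means and coefficient of
#' variation. `cv = 0` gives exactly the condition mean.
#'
#' @param n_replicates Replicates per condition (>= 4, matching the
#'   at-least-four biological replicates of the emulated assay).
#' @param mean_ratio_2d,mean_ratio_3d Mean EVs-per-cell ratio per condition.
#' @param cv Coefficient of variation of the ratio.
#' @param total_cells_2d,total_cells_3d Cells retrieved per replicate.
#' @param seed Integer seed.
#' @return Data frame of class `YieldRecords` with columns `replicate_id`,
#'   `condition`, `total_particles`, `total_cells`, `ratio`.
#' @export
generate_yield_records <- function(n_replicates = 4L,
                                   mean_ratio_2d = 1000,
                                   mean_ratio_3d = 4000,
                                   cv = 0.2,
                                   total_cells_2d = 1e6,
                                   total_cells_3d = 3e5,
                                   seed = 1L) {
  if (n_replicates < 4L)
    stop("n_replicates must be >= 4 per condition")
  if (mean_ratio_2d <= 0 || mean_ratio_3d <= 0)
    stop("mean ratios must be positive")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(as.integer(seed))
  draw <- function(mean_ratio, n) {
    if (cv == 0) return(rep(mean_ratio, n))
    sdlog <- sqrt(log(1 + cv^2))
    # meanlog chosen so E[ratio] = mean_ratio
    stats::rlnorm(n, meanlog = log(mean_ratio) - sdlog^2 / 2, sdlog = sdlog)
  }
  r2 <- draw(mean_ratio_2d, n_replicates)
  r3 <- draw(mean_ratio_3d, n_replicates)
  out <- data.frame(
    replicate_id = c(sprintf("2D_r%d", seq_len(n_replicates)),
                     sprintf("3D_r%d", seq_len(n_replicates))),
    condition = rep(c("2D", "3D"), each = n_replicates),
    total_particles = c(r2 * total_cells_2d, r3 * total_cells_3d),
    total_cells = rep(c(total_cells_2d, total_cells_3d),
                      each = n_replicates),
    stringsAsFactors = FALSE)
  out$ratio <- out$total_particles / out$total_cells
  class(out) <- c("YieldRecords", "data.frame")
  out
}
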