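#' Classify fold changes into deregulation directions
#'
#' A feature is called `up` when its log2 fold change (3D vs 2D) is at
#' least `+threshold`, `down` when at most `-threshold`, `flat` otherwise
#' (including undefined fold changes).
#'
#' @param fc A fold-change table from [fold_change()].
#' @param threshold Magnitude threshold on the log2 scale.
#' @return The table with added `direction` column.
#' @export
deregulation_call <- function(fc, threshold = 0.5) {
  lfc <- fc$log2fc
  dir <- rep("flat", nrow(fc))
  dir[!is.na(lfc) & lfc >= threshold] <- "up"
  dir[!is.na(lfc) & lfc <= -threshold] <- "down"
  fc$direction <- dir
  fc
}

#' Combine cell and EV fold-change calls for one feature set
#'
#' miRNA deregulation can be assessed in donor cells and in EVs; the
#' default policy keeps a feature's call only where the two entities agree
#' in direction when both are defined, and falls back to whichever entity
#' has a defined fold change otherwise. The reported log2fc is the cell
#' value when available, else the EV value.
#'
#' @param fc_cell,fc_ev Fold-change tables from [fold_change()] over the
#'   same features.
#' @return A merged fold-change table (`status = "undefined_zero"` and
#'   `log2fc = NA` where the entities conflict or neither is defined).
#' @export
combine_entity_calls <- function(fc_cell, fc_ev) {
  stopifnot(identical(fc_cell$feature_id, fc_ev$feature_id))
  ok_c <- fc_cell$status == "ok"
  ok_e <- fc_ev$status == "ok"
  both <- ok_c & ok_e
  conflict <- both & (sign(fc_cell$log2fc) != sign(fc_ev$log2fc)) &
    sign(fc_cell$log2fc) != 0 & sign(fc_ev$log2fc) != 0
  out <- fc_cell
  use_ev <- !ok_c & ok_e
  out[use_ev, c("mean_a", "mean_b", "fc", "log2fc")] <-
    fc_ev[use_ev, c("mean_a", "mean_b", "fc", "log2fc")]
  out$status <- ifelse(ok_c | ok_e, "ok", "undefined_zero")
  out$status[conflict] <- "undefined_zero"
  out$log2fc[out$status != "ok"] <- NA_real_
  out$fc[out$status != "ok"] <- NA_real_
  out
}

#' Build the miRNA-to-protein coregulation network
#'
#' An edge (miRNA, protein) is retained when (1) a target edge with the
#' required evidence grade exists and (2) the two features are
#' anti-correlated: in `opposite_sign` mode their 3D-vs-2D deregulation
#' directions are strictly opposite (both non-flat); in `pearson` mode the
#' Pearson correlation of their expression across matched samples is at
#' most `r_max` (negative). Nodes without surviving edges are dropped.
#'
#' @param mirna_fc,protein_fc Fold-change tables (3D vs 2D) from
#'   [fold_change()] (miRNA calls possibly combined across entities via
#'   [combine_entity_calls()]).
#' @param edges A `TargetEdges` table.
#' @param mode `"opposite_sign"` or `"pearson"`.
#' @param evidence `"strong_or_weak"` or `"strong_only"`.
#' @param magnitude_threshold Log2 threshold for direction calls
#'   (opposite_sign mode).
#' @param r_max Maximum allowed Pearson correlation (pearson mode; must be
#'   negative).
#' @param mirna_matrix,protein_matrix Expression matrices for pearson
#'   mode; samples are matched on (cell_line, condition, replicate).
#' @return List of class `CoregulationNetwork`: `mirna_nodes`,
#'   `protein_nodes` (feature, log2fc, direction), `edges` (mirna_id,
#'   protein_id, evidence, criterion_mode) and `provenance` (parameters
#'   used).
#' @export
build_network <- function(mirna_fc, protein_fc, edges,
                          mode = c("opposite_sign", "pearson"),
                          evidence = c("strong_or_weak", "strong_only"),
                          magnitude_threshold = 0.5,
                          r_max = -0.5,
                          mirna_matrix = NULL, protein_matrix = NULL) {
  mode <- match.arg(mode)
  evidence <- match.arg(evidence)
  if (mode == "pearson") {
    if (is.null(mirna_matrix) || is.null(protein_matrix))
      stop("pearson mode needs mirna_matrix and protein_matrix")
    if (r_max >= 0) stop("r_max must be negative")
  }
  m_call <- deregulation_call(mirna_fc, magnitude_threshold)
  p_call <- deregulation_call(protein_fc, magnitude_threshold)
  m_dir <- stats::setNames(m_call$direction, m_call$feature_id)
  p_dir <- stats::setNames(p_call$direction, p_call$feature_id)

  if (evidence == "strong_only")
    edges <- edges[edges$evidence == "strong", , drop = FALSE]

  known_m <- edges$mirna_id %in% m_call$feature_id
  known_p <- edges$protein_id %in% p_call$feature_id
  skipped <- !(known_m & known_p)
  if (any(skipped))
    message(sum(skipped),
            " edge(s) skipped: feature absent from fold-change tables")
  edges <- edges[!skipped, , drop = FALSE]

  if (mode == "opposite_sign") {
    dm <- m_dir[edges$mirna_id]
    dp <- p_dir[edges$protein_id]
    keep <- (dm == "up" & dp == "down") | (dm == "down" & dp == "up")
  } else {
    key_m <- with(mirna_matrix$samples,
                  paste(cell_line, condition, replicate))
    key_p <- with(protein_matrix$samples,
                  paste(cell_line, condition, replicate))
    common <- intersect(key_m, key_p)
    if (length(common) < 4L)
      stop("pearson mode needs >= 4 matched samples")
    mi <- match(common, key_m)
    pi <- match(common, key_p)
    keep <- vapply(seq_len(nrow(edges)), function(e) {
      xm <- mirna_matrix$values[edges$mirna_id[e], mi]
      xp <- protein_matrix$values[edges$protein_id[e], pi]
      if (stats::sd(xm) == 0 || stats::sd(xp) == 0) return(FALSE)
      stats::cor(xm, xp, method = "pearson") <= r_max
    }, logical(1))
  }
  kept <- edges[keep, , drop = FALSE]
  kept$criterion_mode <- rep(mode, nrow(kept))
  rownames(kept) <- NULL
  class(kept) <- "data.frame"

  node_table <- function(call, ids) {
    out <- call[call$feature_id %in% ids,
                c("feature_id", "log2fc", "direction")]
    rownames(out) <- NULL
    out
  }
  structure(list(
    mirna_nodes = node_table(m_call, unique(kept$mirna_id)),
    protein_nodes = node_table(p_call, unique(kept$protein_id)),
    edges = kept,
    provenance = list(mode = mode, evidence = evidence,
                      magnitude_threshold = magnitude_threshold,
                      r_max = if (mode == "pearson") r_max else NA_real_)
  ), class = "CoregulationNetwork")
}

#' @export
print.CoregulationNetwork <- function(x, ...) {
  cat("CoregulationNetwork: ", nrow(x$mirna_nodes), " miRNAs, ",
      nrow(x$protein_nodes), " proteins, ", nrow(x$edges), " edges (",
      x$provenance$mode, " mode)\n", sep = "")
  invisible(x)
}

#' Extract coregulation clusters (connected components)
#'
#' Clusters are the connected components of the bipartite miRNA/protein
#' graph; a cluster may contain several miRNAs targeting the same protein.
#' Components are ordered by size (descending), ties broken by the
#' lexicographically smallest node.
#'
#' @param net A `CoregulationNetwork`.
#' @return List of clusters; each has `mirnas`, `proteins`, `edges` and
#'   `shared_targets` (proteins targeted by more than one miRNA in the
#'   cluster). Empty network gives an empty list.
#' @export
extract_clusters <- function(net) {
  if (nrow(net$edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna_id", "protein_id")], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  mirnas <- net$mirna_nodes$feature_id
  lapply(members, function(nodes) {
    m <- sort(intersect(nodes, mirnas))
    p <- sort(setdiff(nodes, m))
    e <- net$edges[net$edges$mirna_id %in% m & net$edges$protein_id %in% p,
                   , drop = FALSE]
    rownames(e) <- NULL
    shared <- names(which(table(e$protein_id) > 1L))
    list(mirnas = m, proteins = p, edges = e, shared_targets = shared)
  })
}
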