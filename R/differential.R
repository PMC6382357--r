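#' Per-feature fold change between two sample groups
#'
#' Fold change is the ratio of group means, `group_b / group_a`; with the
#' 2D culture as group a and 3D as group b this is the 3D-relative-to-2D
#' fold change. Missing values are excluded from the means. A zero (or
#' all-missing) denominator is handled per `zero_policy`: `"undefined"`
#' marks the record `undefined_zero`; `"epsilon"` adds `epsilon` to both
#' means before the ratio.
#'
#' @param em An `ExpressionMatrix`.
#' @param group_a,group_b Sample ids of the two groups (disjoint, each
#'   with at least one sample).
#' @param zero_policy `"undefined"` or `"epsilon"`.
#' @param epsilon Pseudo-abundance added under the epsilon policy.
#' @return Data frame with columns `feature_id`, `mean_a`, `mean_b`, `fc`,
#'   `log2fc`, `status`.
#' @export
fold_change <- function(em, group_a, group_b,
                        zero_policy = c("undefined", "epsilon"),
                        epsilon = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b))
    stop("each group needs >= 1 sample")
  miss <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  ma <- rowMeans(em$values[, group_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(em$values[, group_b, drop = FALSE], na.rm = TRUE)
  ma[is.nan(ma)] <- NA_real_
  mb[is.nan(mb)] <- NA_real_
  if (zero_policy == "epsilon") {
    ok <- !is.na(ma) & !is.na(mb)
    fc <- ifelse(ok, (mb + epsilon) / (ma + epsilon), NA_real_)
  } else {
    ok <- !is.na(ma) & !is.na(mb) & ma > 0
    fc <- ifelse(ok, mb / ma, NA_real_)
  }
  data.frame(feature_id = rownames(em$values),
             mean_a = ma, mean_b = mb,
             fc = fc, log2fc = log2(fc),
             status = ifelse(ok, "ok", "undefined_zero"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Row-wise Z-score scaling
#'
#' Each row is transformed to `(x - mean) / sd` with the sample standard
#' deviation (divisor n - 1), the scaling used for expression heatmaps.
#' Constant rows have zero variance and are emitted as all-missing with a
#' warning.
#'
#' @param em An `ExpressionMatrix` with >= 2 samples.
#' @return An `ExpressionMatrix` with `unit_label = "Z-score"`. Z-scored
#'   values may be negative; the returned object is exempt from the
#'   nonnegativity rule.
#' @export
zscore_rows <- function(em) {
  if (ncol(em$values) < 2L) stop("need >= 2 samples for Z-scores")
  m <- rowMeans(em$values)
  s <- apply(em$values, 1L, stats::sd)
  z <- (em$values - m) / s
  const <- !is.na(s) & s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) emitted as all-missing")
    z[const, ] <- NA_real_
  }
  out <- em
  out$values <- z
  out$unit_label <- "Z-score"
  out
}

#' Hierarchical clustering order under Euclidean distance
#'
#' Agglomerative clustering of features (rows) or samples (columns) on
#' Euclidean distances; Z-score the rows first when emulating expression
#' heatmaps. Merge heights are non-decreasing for the provided linkages.
#'
#' @param em An `ExpressionMatrix` without missing values on the chosen
#'   axis (impute or drop first).
#' @param axis `"features"` or `"samples"`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return List of class `ClusterResult`: `labels` (leaf order), `order`,
#'   `merge`, `height`, and the underlying `hclust` object.
#' @export
hierarchical_order <- function(em, axis = c("features", "samples"),
                               linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  x <- if (axis == "features") em$values else t(em$values)
  if (nrow(x) < 2L) stop("need >= 2 items on the chosen axis")
  if (anyNA(x))
    stop("missing values on the clustering axis; impute or drop first")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = linkage)
  structure(list(labels = hc$labels[hc$order],
                 order = hc$order,
                 merge = hc$merge,
                 height = hc$height,
                 hclust = hc),
            class = "ClusterResult")
}

#' Top-k most discriminating features between two groups
#'
#' Supervised marker selection: per-feature two-group test on log2
#' abundances (Welch t by default, exact Mann-Whitney as option), ranked
#' by ascending p-value with ties broken by |log2 fold change| descending,
#' then feature id. Features with zero variance and identical means in
#' both groups get p = 1 by convention.
#'
#' @param em An `ExpressionMatrix`.
#' @param group_a,group_b Sample ids (>= 2 each).
#' @param k Number of features to return (`k <=` feature count).
#' @param test `"t_welch"` or `"mannwhitney"`.
#' @param log_offset Offset added before log2 for the Welch test so zero
#'   abundances are representable; 1 is negligible on proteomics scales.
#' @return Data frame with `feature_id`, `p`, `log2fc` (b vs a), `rank`.
#' @export
top_discriminating <- function(em, group_a, group_b, k,
                               test = c("t_welch", "mannwhitney"),
                               log_offset = 1) {
  test <- match.arg(test)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples")
  if (k > nrow(em$values)) stop("k exceeds feature count")
  a <- em$values[, group_a, drop = FALSE]
  b <- em$values[, group_b, drop = FALSE]
  la <- log2(a + log_offset)
  lb <- log2(b + log_offset)
  p <- vapply(seq_len(nrow(em$values)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb)) return(1)
      return(0)
    }
    if (test == "t_welch")
      stats::t.test(xa, xb)$p.value
    else
      mann_whitney_exact(xa, xb)$p_two_sided
  }, numeric(1))
  log2fc <- rowMeans(lb) - rowMeans(la)
  ord <- order(p, -abs(log2fc), rownames(em$values))
  out <- data.frame(feature_id = rownames(em$values)[ord],
                    p = p[ord], log2fc = log2fc[ord],
                    rank = seq_len(nrow(em$values)),
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Relative qPCR expression by the comparative 2^-dCT method
#'
#' Per replicate pair, `delta_ct = ct_b - ct_a` (3D minus 2D) and
#' `rel_expr = 2^(-delta_ct)`; a relative expression above 1 means higher
#' abundance in condition b. Pairs with a missing CT are skipped with a
#' warning; individual replicate pairs are reported, not averaged.
#'
#' @param ct_table Data frame with columns `target_id`, `ct_a`, `ct_b`
#'   and optionally `replicate`.
#' @return Data frame with `target_id`, `replicate`, `ct_a`, `ct_b`,
#'   `delta_ct`, `rel_expr`.
#' @export
qpcr_relative_expression <- function(ct_table) {
  need <- c("target_id", "ct_a", "ct_b")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct_table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(ct_table$replicate))
    ct_table$replicate <- stats::ave(seq_len(nrow(ct_table)),
                                     ct_table$target_id, FUN = seq_along)
  ok <- !is.na(ct_table$ct_a) & !is.na(ct_table$ct_b)
  if (any(!ok))
    warning(sum(!ok), " CT pair(s) with missing values skipped")
  out <- ct_table[ok, c("target_id", "replicate", "ct_a", "ct_b")]
  out$delta_ct <- out$ct_b - out$ct_a
  out$rel_expr <- 2^(-out$delta_ct)
  rownames(out) <- NULL
  out
}

#' Loading-control-normalized densitometry ratio
#'
#' `(signal/control) / (signal_ref/control_ref)`: the band intensity of a
#' protein normalized to its endogenous loading control (e.g. tubulin for
#' cells, GAPDH for EVs), relative to the reference condition.
#'
#' @param signal,control Condition band intensities (`control > 0`).
#' @param signal_ref,control_ref Reference-condition band intensities.
#' @return The normalized ratio.
#' @export
control_normalized_ratio <- function(signal, control,
                                     signal_ref, control_ref) {
  if (any(c(control, control_ref) <= 0))
    stop("control intensities must be > 0")
  if (any(c(signal, signal_ref) < 0))
    stop("signal intensities must be >= 0")
  (signal / control) / (signal_ref / control_ref)
}
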