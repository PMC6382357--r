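#' Assign samples to groups by metadata columns
#'
#' @param em An `ExpressionMatrix`.
#' @param by Metadata columns to combine into a group label (any of
#'   `cell_line`, `condition`, `entity`).
#' @param sep Separator between column values in the label.
#' @return Named character vector, sample_id -> group label.
#' @export
sample_groups <- function(em, by = c("condition", "entity"), sep = "_") {
  bad <- setdiff(by, c("cell_line", "condition", "entity", "replicate"))
  if (length(bad)) stop("unknown grouping column(s): ",
                        paste(bad, collapse = ", "))
  lab <- do.call(paste, c(em$samples[by], sep = sep))
  stats::setNames(lab, em$samples$sample_id)
}

#' Call features detected per group
#'
#' A feature is detected in a group when its abundance exceeds `threshold`
#' (strictly) in at least `min_replicates` of the group's samples. The
#' defaults implement the FPKM > 0 rule with detection in at least one
#' biological replicate. Missing values never exceed the threshold.
#'
#' @param em An `ExpressionMatrix`.
#' @param grouping Named character vector sample_id -> group (e.g. from
#'   [sample_groups()]); every sample must be assigned.
#' @param threshold Strict abundance threshold.
#' @param min_replicates Minimum number of samples above threshold.
#' @return Logical feature-by-group matrix of class `DetectionTable`, with
#'   the rule parameters stored in attributes.
#' @export
call_detected <- function(em, grouping = sample_groups(em),
                          threshold = 0, min_replicates = 1L) {
  ids <- em$samples$sample_id
  miss <- setdiff(ids, names(grouping))
  if (length(miss))
    stop("sample(s) not assigned to a group: ", paste(miss, collapse = ", "))
  grouping <- grouping[ids]
  groups <- unique(grouping)
  hits <- !is.na(em$values) & em$values > threshold
  det <- vapply(groups, function(g) {
    cols <- which(grouping == g)
    if (!length(cols)) stop("empty group: ", g)
    rowSums(hits[, cols, drop = FALSE]) >= min_replicates
  }, logical(nrow(em$values)))
  det <- matrix(det, nrow = nrow(em$values),
                dimnames = list(rownames(em$values), groups))
  structure(det, class = c("DetectionTable", "matrix"),
            threshold = threshold, min_replicates = min_replicates)
}

#' Partition detected features into Venn regions
#'
#' Every detected feature is assigned to exactly one region, identified by
#' the set of groups it is detected in (labels joined by `"&"`). Regions
#' are pairwise disjoint and their union is the union of the per-group
#' detected sets.
#'
#' @param det A `DetectionTable`.
#' @param groups Ordered group labels to partition over (default: all
#'   columns of `det`).
#' @return List of class `FeatureSetPartition`: `regions` (named list of
#'   feature vectors), `sizes` (named integer vector) and `groups`.
#' @export
venn_partition <- function(det, groups = colnames(det)) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  miss <- setdiff(groups, colnames(det))
  if (length(miss)) stop("unknown group(s): ", paste(miss, collapse = ", "))
  sub <- det[, groups, drop = FALSE]
  any_det <- rowSums(sub) > 0
  sig <- apply(sub[any_det, , drop = FALSE], 1L, function(row)
    paste(groups[row], collapse = "&"))
  regions <- split(names(sig), factor(sig, levels = unique(sig)))
  # order regions by the group list for stable output
  ord <- order(vapply(strsplit(names(regions), "&", fixed = TRUE),
                      length, integer(1)),
               names(regions))
  regions <- regions[ord]
  structure(list(regions = regions,
                 sizes = vapply(regions, length, integer(1)),
                 groups = groups),
            class = "FeatureSetPartition")
}

#' Composite detection set: detected in all `include`, in no `exclude`
#'
#' Builds derived sets such as "present in 2D and 3D cells and in 3D EVs
#' but absent from 2D EVs" from a detection table.
#'
#' @param det A `DetectionTable`.
#' @param include Groups the features must be detected in.
#' @param exclude Groups the features must not be detected in.
#' @return Character vector of feature ids.
#' @export
composite_set <- function(det, include, exclude = character(0)) {
  miss <- setdiff(c(include, exclude), colnames(det))
  if (length(miss)) stop("unknown group(s): ", paste(miss, collapse = ", "))
  keep <- rowSums(det[, include, drop = FALSE]) == length(include)
  if (length(exclude))
    keep <- keep & rowSums(det[, exclude, drop = FALSE]) == 0
  rownames(det)[keep]
}

#' Small-RNA biotype composition of detected features per group
#'
#' @param em An `ExpressionMatrix`.
#' @param biotypes Named vector feature_id -> biotype (see
#'   [biotype_map()]).
#' @param grouping Named vector sample_id -> group.
#' @param threshold,min_replicates Detection rule parameters.
#' @return Data frame with columns `group`, `biotype`, `n`, `percentage`.
#'   Percentages sum to 100 within each group; a group with no detected
#'   features gets `NA` percentages.
#' @export
biotype_composition <- function(em, biotypes,
                                grouping = sample_groups(em),
                                threshold = 0, min_replicates = 1L) {
  det <- call_detected(em, grouping, threshold, min_replicates)
  expressed <- rownames(det)[rowSums(det) > 0]
  miss <- setdiff(expressed, names(biotypes))
  if (length(miss))
    stop("feature(s) missing from biotype map: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) ", ...")
  out <- do.call(rbind, lapply(colnames(det), function(g) {
    feats <- rownames(det)[det[, g]]
    counts <- table(factor(biotypes[feats], levels = BIOTYPE_LEVELS))
    total <- sum(counts)
    data.frame(group = g, biotype = names(counts),
               n = as.integer(counts),
               percentage = if (total > 0) 100 * as.numeric(counts) / total
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select housekeeping candidates for qPCR normalization
#'
#' A candidate must be expressed in every sample (abundance > 0), strongly
#' detected in every sample (abundance > 10000), and stable across samples:
#' every pairwise between-sample ratio within 0.5 to 1.5, enforced as
#' max/min <= 1.5 across all samples. An empty result is a legal outcome.
#'
#' @param em An `ExpressionMatrix` with >= 2 samples.
#' @param detect_threshold Strong-detection threshold (default 10000 FPKM).
#' @param fc_range Allowed fold-change interval.
#' @param pairwise If `FALSE`, the stability rule compares group means
#'   instead of the strictest pairwise ratio.
#' @param grouping Grouping used when `pairwise = FALSE`.
#' @return Character vector of candidate feature ids.
#' @export
select_housekeeping_candidates <- function(em, detect_threshold = 10000,
                                           fc_range = c(0.5, 1.5),
                                           pairwise = TRUE,
                                           grouping = NULL) {
  if (ncol(em$values) < 2L) stop("need >= 2 samples")
  v <- em$values
  ok <- apply(v, 1L, function(x) {
    if (anyNA(x)) return(FALSE)
    if (any(x <= 0) || any(x <= detect_threshold)) return(FALSE)
    if (pairwise) {
      ratio <- max(x) / min(x)
    } else {
      if (is.null(grouping)) stop("grouping required when pairwise = FALSE")
      m <- tapply(x, grouping[colnames(v)], mean)
      ratio <- max(m) / min(m)
    }
    ratio <= fc_range[2L] && 1 / ratio >= fc_range[1L]
  })
  rownames(v)[ok]
}
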