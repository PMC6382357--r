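#' Construct an expression matrix with grouped sample metadata
#'
#' The central container of the package: a nonnegative feature-by-sample
#' abundance matrix (FPKM for small RNA, normalized reporter abundance for
#' protein) together with the sample sheet describing the 2D/3D culture
#' design. Missing values (`NA`) are permitted and are distinct from zero:
#' proteomics abundances can be missing-not-zero, whereas FPKM zeros are
#' true zeros.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature identifiers, column names sample identifiers.
#'   All non-missing entries must be >= 0.
#' @param samples Data frame with columns `sample_id`, `cell_line`,
#'   `condition` (one of `"2D"`, `"3D"`), `entity` (one of `"cell"`,
#'   `"EV"`) and `replicate` (positive integer). Row order defines the
#'   column order of `values`.
#' @param unit_label Character scalar naming the abundance unit.
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples, unit_label = "FPKM") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have feature ids as row names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  neg <- which(!is.na(values) & values < 0)
  if (length(neg))
    stop("negative abundance in ", length(neg), " cell(s)")
  samples <- validate_sample_meta(samples)
  if (ncol(values) != nrow(samples))
    stop("column count (", ncol(values), ") != sample count (",
         nrow(samples), ")")
  if (is.null(colnames(values))) {
    colnames(values) <- samples$sample_id
  } else if (!identical(colnames(values), samples$sample_id)) {
    if (!setequal(colnames(values), samples$sample_id))
      stop("matrix columns and sample sheet disagree")
    values <- values[, samples$sample_id, drop = FALSE]
  }
  structure(
    list(values = values, samples = samples, unit_label = unit_label),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples [", x$unit_label, "]\n", sep = "")
  cat("  groups:",
      paste(sort(unique(interaction(x$samples$condition, x$samples$entity,
                                    sep = "/", drop = TRUE))),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature identifiers of an expression matrix
#' @param em An `ExpressionMatrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(em) rownames(em$values)

validate_sample_meta <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "condition", "entity", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(samples$condition), c("2D", "3D"))
  if (length(bad))
    stop("condition must be '2D' or '3D', got: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$entity), c("cell", "EV"))
  if (length(bad))
    stop("entity must be 'cell' or 'EV', got: ", paste(bad, collapse = ", "))
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1))
    stop("replicate must be a positive integer")
  key <- interaction(samples$cell_line, samples$condition, samples$entity,
                     samples$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (cell_line, condition, entity, replicate) tuples")
  rownames(samples) <- NULL
  samples
}

#' Read an expression matrix and its sample sheet from delimited text
#'
#' The matrix file holds feature ids in the first column and one column per
#' sample; the sample sheet defines the canonical sample order, so the
#' matrix columns may appear in any order. Empty cells and `"NA"` parse as
#' missing (not zero); negative or non-numeric cells are rejected.
#'
#' @param path Matrix file (TSV by default).
#' @param meta_path Sample sheet with columns `sample_id`, `cell_line`,
#'   `condition`, `entity`, `replicate`.
#' @param sep Field delimiter, `"\t"` or `","`.
#' @param unit_label Abundance unit recorded on the returned object.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, meta_path, sep = "\t",
                                   unit_label = "FPKM") {
  meta <- read_sample_meta(meta_path, sep = sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), quote = "",
                           comment.char = "")
  fid <- as.character(raw[[1L]])
  dat <- raw[, -1L, drop = FALSE]
  missing_in_meta <- setdiff(names(dat), meta$sample_id)
  if (length(missing_in_meta))
    stop("sample(s) absent from sample sheet: ",
         paste(missing_in_meta, collapse = ", "))
  missing_in_matrix <- setdiff(meta$sample_id, names(dat))
  if (length(missing_in_matrix))
    stop("sample(s) absent from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  vals <- vapply(dat, function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (any(is.na(num) & !is.na(col)))
      stop("non-numeric abundance value(s) in matrix")
    num
  }, numeric(length(fid)))
  vals <- matrix(vals, nrow = length(fid),
                 dimnames = list(fid, names(dat)))
  if (any(!is.na(vals) & vals < 0)) stop("negative abundance")
  expression_matrix(vals[, meta$sample_id, drop = FALSE], meta,
                    unit_label = unit_label)
}

#' Read a sample sheet
#' @inheritParams read_expression_matrix
#' @return Validated sample data frame.
#' @export
read_sample_meta <- function(meta_path, sep = "\t") {
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  validate_sample_meta(meta)
}

#' Write an expression matrix and sample sheet to delimited text
#'
#' Values are written with 15 significant digits so that a write/read
#' round trip preserves them to at least 12 significant digits.
#'
#' @param em An `ExpressionMatrix`.
#' @param path,meta_path Output files.
#' @param sep Field delimiter.
#' @export
write_expression_matrix <- function(em, path, meta_path, sep = "\t") {
  vals <- format(em$values, digits = 15, trim = TRUE, scientific = FALSE)
  vals[is.na(em$values)] <- "NA"
  out <- cbind(feature_id = rownames(em$values), as.data.frame(vals))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, meta_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read miRNA-to-protein target edges
#'
#' Three-column delimited text (`mirna_id`, `protein_id`, `evidence`),
#' evidence graded `"strong"` (reporter-assay validated) or `"weak"`
#' (high-throughput support). Duplicate pairs are collapsed keeping the
#' stronger grade; first-appearance order is preserved.
#'
#' @param path Edge list file.
#' @param sep Field delimiter.
#' @return Data frame of class `TargetEdges` with columns `mirna_id`,
#'   `protein_id`, `evidence`.
#' @export
read_target_edges <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("mirna_id", "protein_id", "evidence")
  if (!all(need %in% names(df)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  target_edges(df[need])
}

#' Validate and deduplicate a target edge table
#' @param df Data frame with columns `mirna_id`, `protein_id`, `evidence`.
#' @return Deduplicated edge data frame (strong grade wins).
#' @export
target_edges <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$evidence), c("strong", "weak"))
  if (length(bad))
    stop("evidence must be 'strong' or 'weak', got: ",
         paste(bad, collapse = ", "))
  if (nrow(df) == 0L) {
    rownames(df) <- NULL
    class(df) <- c("TargetEdges", "data.frame")
    return(df)
  }
  key <- paste(df$mirna_id, df$protein_id, sep = "\r")
  first <- !duplicated(key)
  has_strong <- tapply(df$evidence == "strong", key, any)
  out <- df[first, , drop = FALSE]
  out$evidence <- as.character(
    ifelse(has_strong[paste(out$mirna_id, out$protein_id, sep = "\r")],
           "strong", "weak"))
  rownames(out) <- NULL
  class(out) <- c("TargetEdges", "data.frame")
  out
}

#' Read category definitions (long or GMT format)
#'
#' Auto-detects the dialect: rows of exactly two tab-separated fields are
#' read as long format (`category_id`, `member_id`); anything else is read
#' as GMT (`name`, `description`, then members). Members are deduplicated
#' per category; an empty category is an error.
#'
#' @param path Category file.
#' @return A named list of class `CategoryDB`; each element has `name` and
#'   `members` (character vector).
#' @export
read_category_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty category file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 2L)) {
    header <- tolower(fields[[1L]])
    if (identical(header, c("category_id", "member_id")))
      fields <- fields[-1L]
    cat_id <- vapply(fields, `[[`, "", 1L)
    member <- vapply(fields, `[[`, "", 2L)
    sets <- split(member, factor(cat_id, levels = unique(cat_id)))
    db <- lapply(names(sets), function(id)
      list(name = id, members = unique(sets[[id]])))
    names(db) <- names(sets)
  } else {
    db <- lapply(fields, function(f) {
      if (length(f) < 3L)
        stop("GMT line with fewer than 3 fields: ", f[[1L]])
      list(name = f[[1L]], members = unique(f[-(1:2)]))
    })
    names(db) <- vapply(db, `[[`, "", "name")
  }
  category_db(db)
}

#' Validate a category database
#' @param db Named list; each element a list with `name` and non-empty
#'   `members`.
#' @return The validated list, classed `CategoryDB`.
#' @export
category_db <- function(db) {
  if (anyDuplicated(names(db)))
    stop("duplicate category ids")
  empty <- names(db)[vapply(db, function(x) length(x$members) == 0L,
                            logical(1))]
  if (length(empty))
    stop("empty category after parsing: ", paste(empty, collapse = ", "))
  structure(db, class = "CategoryDB")
}

#' Read a feature-to-biotype map
#'
#' Two-column delimited text (`feature_id`, `biotype`); biotypes are
#' restricted to the nine Ensembl/miRBase small-RNA classes used for
#' composition profiling.
#'
#' @param path Map file.
#' @param sep Field delimiter.
#' @return Named character vector feature_id -> biotype.
#' @export
read_biotype_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  biotype_map(stats::setNames(df[[2L]], df[[1L]]))
}

#' The closed set of small-RNA biotype labels
#' @export
BIOTYPE_LEVELS <- c("miRNA", "misc_RNA", "mt_tRNA", "ribozyme", "rRNA",
                    "scaRNA", "scRNA", "snoRNA", "snRNA")

#' Validate a biotype map against the closed label set
#' @param map Named character vector feature_id -> biotype.
#' @return The validated map.
#' @export
biotype_map <- function(map) {
  bad <- setdiff(unique(map), BIOTYPE_LEVELS)
  if (length(bad))
    stop("biotype label(s) outside the closed set: ",
         paste(bad, collapse = ", "))
  map
}
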