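#' Hypergeometric over-representation analysis
#'
#' For each category, tests whether the query set overlaps the category
#' more than expected given the reference universe, using the upper-tail
#' hypergeometric probability P(X >= k). Following the inclusion rules
#' used for miRNA category analysis, a category is flagged significant
#' only when its nominal p-value is below `alpha` AND the overlap contains
#' at least `min_overlap` (default two) query features.
#' Benjamini-Hochberg q-values are reported alongside but do not drive the
#' significance flag.
#'
#' @param query Feature set of interest (must be a subset of `universe`).
#' @param universe Reference feature set (e.g. all miRNAs detected in the
#'   relevant compartment).
#' @param db A `CategoryDB`; members are intersected with the universe
#'   before testing.
#' @param alpha Nominal significance level.
#' @param min_overlap Minimum overlap for the significance flag.
#' @return Data frame sorted by p with columns `category_id`, `N`, `K`,
#'   `n`, `k`, `p`, `q`, `significant`.
#' @export
ora <- function(query, universe, db, alpha = 0.05, min_overlap = 2L) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query feature(s) outside universe: ",
         paste(utils::head(outside, 10L), collapse = ", "),
         if (length(outside) > 10L) ", ...")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(db), function(id) {
    members <- intersect(db[[id]]$members, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    # upper tail: P(X >= k)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category_id = id, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha & out$k >= min_overlap
  out <- out[order(out$p, out$category_id), ]
  rownames(out) <- NULL
  out
}

#' Running-sum enrichment statistic for a ranked list
#'
#' Walks down the ranked list adding +(N - k) at category members and -k
#' elsewhere (unweighted, Kolmogorov-Smirnov-type set enrichment), so the
#' path always ends at zero. The statistic is the maximum absolute
#' deviation, capturing accumulation of members at either extreme of the
#' list; its exact tail probability comes from
#' [exact_p_running_sum()].
#'
#' @param ranked_ids Ordered feature ids (no duplicates).
#' @param members Category member set (non-empty subset of `ranked_ids`).
#' @return List of class `RunningSumResult`: `N`, `k`, `rs_path`
#'   (length-N integer path), `rs_max`, `p_exact`.
#' @export
running_sum <- function(ranked_ids, members) {
  if (anyDuplicated(ranked_ids)) stop("duplicate ids in ranked list")
  members <- unique(members)
  if (!length(members)) stop("empty member set")
  outside <- setdiff(members, ranked_ids)
  if (length(outside))
    stop("member(s) not in ranked list: ", paste(outside, collapse = ", "))
  N <- length(ranked_ids)
  k <- length(members)
  incr <- ifelse(ranked_ids %in% members, N - k, -k)
  rs_path <- cumsum(incr)
  rs_max <- max(abs(rs_path))
  structure(list(N = N, k = k, rs_path = rs_path, rs_max = rs_max,
                 p_exact = exact_p_running_sum(N, k, rs_max)),
            class = "RunningSumResult")
}

#' Exact p-value of the running-sum maximum by dynamic programming
#'
#' Under the null, the k category members are uniformly placed among the N
#' list positions; this computes P(max |RS| >= s) exactly by a lattice-path
#' dynamic program. After i positions with j members seen, the running sum
#' equals j*N - i*k, so the DP tracks the probability mass over
#' (position, members-used) states whose path has never reached +/- s,
#' advancing with the hypergeometric transition probabilities
#' (k - j)/(N - i) for a member and 1 minus that otherwise. The result is
#' 1 minus the surviving mass. All arithmetic is on probabilities between 0 and 1
#' (no large path counts), keeping the floating-point error at the level
#' of N*k rounding operations (well below 1e-10 for N in the thousands).
#'
#' @param N List length.
#' @param k Number of category members, 0 < k <= N.
#' @param s Threshold for the maximum absolute running sum; `s <= 0`
#'   returns 1 (every path attains |RS| >= 0).
#' @return P(max |RS| >= s), between 0 and 1.
#' @export
exact_p_running_sum <- function(N, k, s) {
  N <- as.integer(N); k <- as.integer(k)
  if (k <= 0L || k > N) stop("need 0 < k <= N")
  if (s <= 0) return(1)
  if (s > k * (N - k)) return(0)
  # prob[j + 1] = P(j members among first i positions, |RS| < s so far)
  prob <- c(1, rep(0, k))
  j_all <- 0:k
  for (i in 0:(N - 1L)) {
    p_member <- pmax(0, pmin(1, (k - j_all) / (N - i)))
    new <- prob * (1 - p_member)
    new[-1L] <- new[-1L] + (prob * p_member)[-(k + 1L)]
    # kill states whose running sum j*N - (i+1)*k has reached +/- s
    rs <- j_all * N - (i + 1L) * k
    new[abs(rs) >= s] <- 0
    prob <- new
  }
  p <- 1 - sum(prob)
  min(max(p, 0), 1)
}

#' Ranked-list set enrichment over a category database
#'
#' Ranks features (descending) by average abundance or by log2 fold
#' change, ties broken by feature id, then applies [running_sum()] per
#' category. Categories with fewer than two members in the ranked list are
#' skipped with a message.
#'
#' @param em An `ExpressionMatrix`.
#' @param db A `CategoryDB`.
#' @param rank_by `"mean_abundance"` or `"log2fc"`.
#' @param features Features forming the ranked list (default: features
#'   detected in at least one sample under the FPKM > 0 rule).
#' @param samples Samples whose mean drives `rank_by = "mean_abundance"`
#'   (default all).
#' @param group_a,group_b Sample groups for `rank_by = "log2fc"` (a = 2D,
#'   b = 3D).
#' @param min_members Minimum category members in the list (default 2).
#' @return Data frame with columns `category_id`, `N`, `k`, `rs_max`,
#'   `p_exact`, sorted by `p_exact`; the per-category `RunningSumResult`
#'   objects are attached as attribute `"results"`.
#' @export
gsea_ranked_mirnas <- function(em, db,
                               rank_by = c("mean_abundance", "log2fc"),
                               features = NULL, samples = NULL,
                               group_a = NULL, group_b = NULL,
                               min_members = 2L) {
  rank_by <- match.arg(rank_by)
  if (is.null(features)) {
    hits <- !is.na(em$values) & em$values > 0
    features <- rownames(em$values)[rowSums(hits) > 0]
  }
  if (!length(features)) stop("empty ranked list")
  if (rank_by == "mean_abundance") {
    if (is.null(samples)) samples <- colnames(em$values)
    key <- rowMeans(em$values[features, samples, drop = FALSE], na.rm = TRUE)
  } else {
    if (is.null(group_a) || is.null(group_b))
      stop("group_a and group_b required for rank_by = 'log2fc'")
    fc <- fold_change(em, group_a, group_b, zero_policy = "epsilon")
    key <- stats::setNames(fc$log2fc, fc$feature_id)[features]
  }
  ranked <- features[order(-key, features)]
  results <- list()
  rows <- list()
  for (id in names(db)) {
    members <- intersect(db[[id]]$members, ranked)
    if (length(members) < min_members) {
      message("skipping category '", id, "': ", length(members),
              " member(s) in ranked list")
      next
    }
    rs <- running_sum(ranked, members)
    results[[id]] <- rs
    rows[[id]] <- data.frame(category_id = id, N = rs$N, k = rs$k,
                             rs_max = rs$rs_max, p_exact = rs$p_exact,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(structure(data.frame(category_id = character(0), N = integer(0),
                                k = integer(0), rs_max = numeric(0),
                                p_exact = numeric(0)),
                     results = list(), ranked = ranked))
  out <- do.call(rbind, rows)
  out <- out[order(out$p_exact, out$category_id), ]
  rownames(out) <- NULL
  attr(out, "results") <- results
  attr(out, "ranked") <- ranked
  out
}
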