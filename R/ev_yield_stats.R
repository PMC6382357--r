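#' Per-condition EVs-per-cell summaries
#'
#' The EVs-per-cell ratio of a replicate is its total isolated particle
#' count divided by the total number of cells retrieved from the culture;
#' summaries are the mean and sample standard deviation of the replicate
#' ratios per condition. Fewer than four replicates in a condition
#' triggers a warning; a single replicate yields an undefined (`NA`) SD.
#'
#' @param records Data frame with columns `condition`, `total_particles`,
#'   `total_cells` (e.g. from [generate_yield_records()]).
#' @return Data frame with `condition`, `n`, `mean_ratio`, `sd_ratio`.
#' @export
evs_per_cell <- function(records) {
  if (any(records$total_cells <= 0)) stop("total_cells must be > 0")
  if (any(records$total_particles < 0)) stop("total_particles must be >= 0")
  ratio <- records$total_particles / records$total_cells
  conds <- unique(records$condition)
  n_per <- vapply(conds, function(cd) sum(records$condition == cd),
                  integer(1))
  if (any(n_per < 4L))
    warning("condition(s) with fewer than 4 replicates (at least 4 ",
            "recommended): ",
            paste0(conds[n_per < 4L], " (", n_per[n_per < 4L], ")",
                   collapse = ", "))
  out <- do.call(rbind, lapply(conds, function(cd) {
    r <- ratio[records$condition == cd]
    data.frame(condition = cd, n = length(r), mean_ratio = mean(r),
               sd_ratio = if (length(r) > 1L) stats::sd(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Exact Mann-Whitney U test
#'
#' U is computed from rank sums with ties mid-ranked. The p-value is exact
#' (full dynamic-programming enumeration of the null U distribution) when
#' n1 + n2 <= 20 and there are no ties, otherwise a normal approximation
#' with tie correction and continuity correction is used. The two-sided
#' exact p is P(U <= min(U, n1*n2 - U)) doubled and capped at 1.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param alternative `"two_sided"`, `"greater"` (a shifted above b) or
#'   `"less"`.
#' @return List of class `ExactTestResult`: `u_statistic` (U of sample a),
#'   `n1`, `n2`, `p_two_sided` (the p-value for the chosen alternative),
#'   `alternative`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two_sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("empty sample")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (!has_ties && n <= 20L) {
    pu <- null_u_distribution(n1, n2)      # P(U = 0..n1*n2)
    cdf <- cumsum(pu)
    p <- switch(alternative,
      two_sided = min(1, 2 * cdf[min(u, n1 * n2 - u) + 1L]),
      greater = 1 - if (u >= 1) cdf[u] else 0,   # P(U >= u)
      less = cdf[u + 1L])
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma <- sqrt(n1 * n2 / 12 *
                    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    if (sigma == 0) return(structure(
      list(u_statistic = u, n1 = n1, n2 = n2, p_two_sided = 1,
           alternative = alternative, method = "normal_approx"),
      class = "ExactTestResult"))
    cc <- 0.5  # continuity correction toward the mean
    d <- u - mu
    z <- switch(alternative,
      two_sided = (d - sign(d) * cc) / sigma,
      greater = (d - cc) / sigma,
      less = (d + cc) / sigma)
    p <- switch(alternative,
      two_sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    p <- min(1, max(p, .Machine$double.xmin))
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, n1 = n1, n2 = n2, p_two_sided = p,
                 alternative = alternative, method = method),
            class = "ExactTestResult")
}

# Exact null distribution of U for sample sizes n1, n2 (no ties):
# rank-sum DP counting, for each j <= n1 and each achievable sum, the
# number of j-subsets of ranks 1..n with that sum.
null_u_distribution <- function(n1, n2) {
  n <- n1 + n2
  max_w <- sum((n2 + 1):n)           # max rank sum of sample 1
  ways <- matrix(0, nrow = n1 + 1L, ncol = max_w + 1L)
  ways[1L, 1L] <- 1
  for (i in seq_len(n)) {
    for (j in rev(seq_len(min(i, n1)))) {
      w <- (i + 1L):(max_w + 1L)
      ways[j + 1L, w] <- ways[j + 1L, w] + ways[j, w - i]
    }
  }
  w_counts <- ways[n1 + 1L, ]
  min_w <- n1 * (n1 + 1) / 2
  u_counts <- w_counts[(min_w + 1L):(min_w + n1 * n2 + 1L)]
  u_counts / choose(n, n1)
}

#' Size distribution summary (mode and mean)
#'
#' The mean is arithmetic; the mode is the center of the most populated
#' histogram bin, with bins centered on multiples of `bin_width` (ties go
#' to the smaller center), following nanoparticle-tracking size reporting.
#'
#' @param size_samples_nm Positive particle sizes in nm.
#' @param bin_width_nm Histogram bin width in nm (> 0).
#' @return List with `mode` and `mean` (nm).
#' @export
size_summary <- function(size_samples_nm, bin_width_nm = 10) {
  if (!length(size_samples_nm)) stop("need >= 1 size")
  if (any(size_samples_nm <= 0)) stop("sizes must be positive")
  if (bin_width_nm <= 0) stop("bin_width_nm must be > 0")
  centers <- round(size_samples_nm / bin_width_nm) * bin_width_nm
  counts <- table(centers)
  best <- max(counts)
  mode <- min(as.numeric(names(counts)[counts == best]))
  list(mode = mode, mean = mean(size_samples_nm))
}
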