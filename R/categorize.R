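#' Configuration for the adaptive categorization search
#'
#' @param k_max Maximum number of categories the adaptive search will
#'   consider.  The search is capped (default 10) to bound the computational
#'   burden of growing the partition.
#' @param k_fixed Optional fixed number of categories.  When supplied, the
#'   adaptive p-value stopping rule is disabled and the linear search simply
#'   grows the partition to exactly `k_fixed` categories (must lie in
#'   `[2, k_max]`).
#' @param min_category_fraction Minimum fraction of the sample that every
#'   category must hold, in `[0, 0.5)`.  Candidate boundaries that would
#'   create an undersized category are excluded during the search.  The
#'   application mode for right-skewed concentration data uses 0.10.
#'
#' @return An object of class `amc_config`.
#' @export
#' @examples
#' amc_config(k_fixed = 3, min_category_fraction = 0.10)
amc_config <- function(k_max = 10L, k_fixed = NULL, min_category_fraction = 0) {
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 2L) {
    .amc_error("amc_config_error", "`k_max` must be an integer >= 2")
  }
  if (!is.null(k_fixed)) {
    k_fixed <- as.integer(k_fixed)
    if (is.na(k_fixed) || k_fixed < 2L || k_fixed > k_max) {
      .amc_error("amc_config_error",
                 "`k_fixed` must satisfy 2 <= k_fixed <= k_max")
    }
  }
  if (!is.numeric(min_category_fraction) || length(min_category_fraction) != 1L ||
      is.na(min_category_fraction) ||
      min_category_fraction < 0 || min_category_fraction >= 0.5) {
    .amc_error("amc_config_error",
               "`min_category_fraction` must lie in [0, 0.5)")
  }
  structure(list(k_max = k_max, k_fixed = k_fixed,
                 min_category_fraction = as.numeric(min_category_fraction)),
            class = "amc_config")
}

.as_config <- function(config) {
  if (inherits(config, "amc_config")) return(config)
  if (is.null(config)) return(amc_config())
  do.call(amc_config, as.list(config))
}

#' Reciprocal-F loss of a categorization
#'
#' Computes the within- and between-category sums of squares of a grouping of
#' a continuous exposure, the one-way ANOVA F statistic with degrees of
#' freedom `(k - 1, n - k)`, and the loss defined as the reciprocal of that F
#' statistic:
#' \deqn{L = \frac{SS_{within}/(n-k)}{SS_{between}/(k-1)}.}
#' Minimizing the loss maximizes the separation between categories relative
#' to the spread within them.
#'
#' @param values Numeric vector of n observations of one exposure.
#' @param labels Integer category labels in `0:(k - 1)`, every category
#'   nonempty.
#' @param k Number of categories (>= 2, with `n > k`).
#'
#' @return A list with components `loss`, `f_statistic`, `within`, `between`
#'   and `p_value` (upper tail of the F distribution).  A perfect partition
#'   (`within == 0`) has `loss = 0` and infinite `f_statistic`.
#'
#' @details A partition in which all category means coincide (e.g. a constant
#'   input) has zero between-category variation; the loss is undefined there
#'   and a condition of class `amc_degenerate_error` is signalled.
#' @export
#' @examples
#' amc_loss(c(1, 2, 3, 4, 10), c(0, 0, 0, 0, 1), k = 2)
amc_loss <- function(values, labels, k) {
  values <- .assert_exposure(values)
  n <- length(values)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) {
    .amc_error("amc_config_error", "`k` must be an integer >= 2")
  }
  if (length(labels) != n) {
    .amc_error("amc_input_error", "`labels` must match `values` in length")
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= k)) {
    .amc_error("amc_input_error", "`labels` must lie in 0:(k - 1)")
  }
  counts <- tabulate(labels + 1L, nbins = k)
  if (any(counts == 0L)) {
    .amc_error("amc_input_error", "every category 0:(k - 1) must be nonempty")
  }
  if (n <= k) {
    .amc_error("amc_input_error", "need n > k for the F statistic")
  }
  .partition_stats(values, labels, counts, k)
}

# Core sums-of-squares computation shared by amc_loss and the categorizers.
.partition_stats <- function(values, labels, counts, k) {
  n <- length(values)
  grand <- mean(values)
  sums <- vapply(0:(k - 1L), function(g) sum(values[labels == g]), 0.0)
  means <- sums / counts
  within <- sum((values - means[labels + 1L])^2)
  between <- sum(counts * (means - grand)^2)
  total <- within + between
  tol <- 1e-12 * max(total, 1)
  if (between <= tol) {
    .amc_error("amc_degenerate_error",
               "degenerate partition: between-category variation is zero, loss undefined")
  }
  if (within <= 1e-12 * total) {
    loss <- 0
    f <- Inf
  } else {
    loss <- (within / (n - k)) / (between / (k - 1))
    f <- 1 / loss
  }
  list(loss = loss, f_statistic = f, within = within, between = between,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# ---------------------------------------------------------------------------
# Categorization objects.
#
# A categorization stores k - 1 strictly increasing thresholds interpreted as
# half-open upper bounds: category j holds values in (t_{j-1}, t_j], so a new
# observation exactly at a threshold falls in the lower category.  Thresholds
# produced by the search are midpoints between consecutive distinct sorted
# values, which guarantees that tied observations always share a label.

.new_categorization <- function(values, thresholds, labels, counts, k, method,
                                stats = NULL, degenerate = FALSE) {
  structure(list(
    thresholds = as.numeric(thresholds),
    k = as.integer(k),
    labels = as.integer(labels),
    counts = as.integer(counts),
    n = length(values),
    loss = if (is.null(stats)) NA_real_ else stats$loss,
    f_statistic = if (is.null(stats)) NA_real_ else stats$f_statistic,
    p_value = if (is.null(stats)) NA_real_ else stats$p_value,
    within = if (is.null(stats)) NA_real_ else stats$within,
    between = if (is.null(stats)) NA_real_ else stats$between,
    method = method,
    degenerate = isTRUE(degenerate)
  ), class = "amc_categorization")
}

# Build a categorization from boundary positions `cuts` (indices into the
# sorted data: a cut at b separates sorted positions b and b + 1).
.from_cuts <- function(values, xs, ps, cuts, method) {
  n <- length(xs)
  k <- length(cuts) + 1L
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  within <- sum(.seg_ss(ps, starts, ends))
  total <- .seg_ss(ps, 1L, n)
  between <- max(total - within, 0)
  thresholds <- (xs[cuts] + xs[cuts + 1L]) / 2
  labels <- findInterval(values, thresholds, left.open = TRUE)
  if (within <= 1e-12 * total) {
    loss <- 0
    f <- Inf
  } else {
    loss <- (within / (n - k)) / (between / (k - 1))
    f <- 1 / loss
  }
  stats <- list(loss = loss, f_statistic = f, within = within, between = between,
                p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  .new_categorization(values, thresholds, labels, ends - starts + 1L, k,
                      method, stats)
}

# Recover cut positions in the sorted sample from stored thresholds.
.cuts_from_thresholds <- function(thresholds, xs) {
  if (length(thresholds) == 0L) return(integer(0))
  findInterval(thresholds, xs)
}

#' Exhaustively optimal categorization (testing oracle)
#'
#' Enumerates every placement of `k - 1` boundaries between consecutive
#' distinct sorted values — `choose(n - 1, k - 1)` placements when all values
#' are distinct — and returns the contiguous partition minimizing the
#' reciprocal-F loss.  Exists as the exact reference for the linear search
#' and is capped at `n <= 30`; use [amc_categorize()] in production.
#'
#' @param values Numeric exposure vector (n <= 30).
#' @param k Number of categories (>= 2).
#' @param config An [amc_config()]; only `min_category_fraction` is used.
#'
#' @return An `amc_categorization`.  Attributes `n_enumerated` (boundary sets
#'   actually evaluated, after collapsing ties) and `search_space`
#'   (`choose(n - 1, k - 1)`) record the combinatorial size.
#' @export
exhaustive_categorize <- function(values, k, config = amc_config()) {
  values <- .assert_exposure(values)
  config <- .as_config(config)
  n <- length(values)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) {
    .amc_error("amc_config_error", "`k` must be an integer >= 2")
  }
  if (n > 30L) {
    .amc_error("amc_config_error",
               "exhaustive search is capped at n <= 30; use amc_categorize()")
  }
  if (n <= k) {
    .amc_error("amc_infeasible_k_error", "need n > k observations")
  }
  xs <- sort(values)
  ps <- .prefix_sums(xs)
  admissible <- which(diff(xs) > 0)
  if (length(admissible) < k - 1L) {
    .amc_error("amc_infeasible_k_error",
               sprintf("only %d distinct values; cannot form %d categories",
                       length(admissible) + 1L, k))
  }
  combos <- if (length(admissible) == 1L) {
    matrix(admissible, nrow = 1L)
  } else {
    utils::combn(admissible, k - 1L)
  }
  starts <- rbind(1L, combos + 1L)
  ends <- rbind(combos, n)
  if (config$min_category_fraction > 0) {
    min_count <- ceiling(config$min_category_fraction * n)
    ok <- colSums((ends - starts + 1L) >= min_count) == k
    if (!any(ok)) {
      .amc_error("amc_no_candidate_error",
                 "minimum-category-fraction constraint excludes every partition")
    }
    combos <- combos[, ok, drop = FALSE]
    starts <- starts[, ok, drop = FALSE]
    ends <- ends[, ok, drop = FALSE]
  }
  within <- colSums(matrix(.seg_ss(ps, starts, ends), nrow = k))
  best <- which.min(within)
  out <- .from_cuts(values, xs, ps, sort(combos[, best]), method = "exhaustive")
  attr(out, "n_enumerated") <- ncol(combos)
  attr(out, "search_space") <- choose(n - 1, k - 1)
  out
}

#' Add one boundary to an existing categorization
#'
#' One step of the incremental linear search: all previously found boundaries
#' are kept and a single new boundary, searched over every admissible
#' position inside every existing category, is added so that the loss of the
#' resulting `k + 1`-category partition is minimal.  Cost is O(n) candidate
#' evaluations (each O(1) via prefix sums).
#'
#' @param values Numeric exposure vector.
#' @param current The current `amc_categorization` (from a previous step, or
#'   a single-category start).
#' @param config An [amc_config()]; only `min_category_fraction` is used.
#'
#' @return An `amc_categorization` with `current$k + 1` categories whose
#'   threshold set contains `current$thresholds`.
#' @export
linear_search_step <- function(values, current, config = amc_config()) {
  values <- .assert_exposure(values)
  config <- .as_config(config)
  if (!inherits(current, "amc_categorization")) {
    .amc_error("amc_input_error", "`current` must be an amc_categorization")
  }
  n <- length(values)
  xs <- sort(values)
  ps <- .prefix_sums(xs)
  cuts <- .cuts_from_thresholds(current$thresholds, xs)
  cand <- setdiff(which(diff(xs) > 0), cuts)
  k <- length(cuts) + 1L
  if (length(cand)) {
    seg <- findInterval(cand, cuts) + 1L
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    left <- .seg_ss(ps, starts[seg], cand)
    right <- .seg_ss(ps, cand + 1L, ends[seg])
    seg_ss_all <- .seg_ss(ps, starts, ends)
    new_within <- sum(seg_ss_all) - seg_ss_all[seg] + left + right
    if (config$min_category_fraction > 0) {
      min_count <- ceiling(config$min_category_fraction * n)
      keep <- (cand - starts[seg] + 1L) >= min_count &
        (ends[seg] - cand) >= min_count
      cand <- cand[keep]
      new_within <- new_within[keep]
    }
  }
  if (!length(cand)) {
    .amc_error("amc_no_candidate_error",
               "no admissible boundary position remains for an additional category")
  }
  best <- cand[which.min(new_within)]
  .from_cuts(values, xs, ps, sort(c(cuts, best)), method = "amc")
}

.single_category <- function(values, method, degenerate) {
  .new_categorization(values, numeric(0), rep(0L, length(values)),
                      length(values), 1L, method, degenerate = degenerate)
}

#' Adaptive mixture categorization of one exposure
#'
#' Categorizes a continuous exposure by incrementally adding boundaries with
#' [linear_search_step()].  With `k_fixed` set in `config`, the partition is
#' grown to exactly that many categories.  Otherwise k is selected
#' adaptively: starting from k = 2, the F-test p-value (df `k - 1`, `n - k`)
#' is tracked, and the search stops at the first k whose p-value fails to
#' decrease (returning the previous k), at `k_max`, or as soon as the
#' within-category variation reaches zero.  P-values are compared on the
#' log scale, so the rule is unaffected by floating-point underflow of
#' extremely small p-values.
#'
#' Because every boundary is chosen to maximize the F statistic, the
#' resulting p-value is strongly anti-conservative and on realistic
#' continuous data typically keeps decreasing well past any visible cluster
#' structure, so the adaptive rule often runs to `k_max`.  When the category
#' count should match substantive structure (a known number of latent
#' states, or low/medium/high reporting), fix it with `k_fixed`.
#'
#' @param values Numeric exposure vector (length >= 2, finite).
#' @param config An [amc_config()].
#'
#' @return An `amc_categorization` carrying the thresholds, labels, per
#'   category counts, loss, F statistic and p-value of the selected
#'   partition.  A constant input yields a single-category result flagged
#'   `degenerate = TRUE` rather than an error, so batch runs over many
#'   exposures are robust.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200, mean = sample(1:4, 200, TRUE), sd = 0.33)
#' amc_categorize(x, amc_config(k_fixed = 4))
amc_categorize <- function(values, config = amc_config()) {
  values <- .assert_exposure(values)
  config <- .as_config(config)
  n <- length(values)
  if (diff(range(values)) == 0) {
    return(.single_category(values, "amc", degenerate = TRUE))
  }
  start <- .single_category(values, "amc", degenerate = FALSE)
  if (!is.null(config$k_fixed)) {
    cur <- start
    for (k in 2:config$k_fixed) {
      cur <- linear_search_step(values, cur, config)
    }
    return(cur)
  }
  k_cap <- min(config$k_max, n - 1L)
  cur <- linear_search_step(values, start, config)  # k = 2
  log_p <- function(cc) {
    stats::pf(cc$f_statistic, cc$k - 1, length(values) - cc$k,
              lower.tail = FALSE, log.p = TRUE)
  }
  while (cur$k < k_cap) {
    if (cur$within <= 1e-12 * (cur$within + cur$between)) {
      return(cur)  # perfect fit; F is unbounded beyond this point
    }
    nxt <- tryCatch(linear_search_step(values, cur, config),
                    amc_no_candidate_error = function(e) NULL)
    if (is.null(nxt)) {
      return(cur)
    }
    if (nxt$within <= 1e-12 * (nxt$within + nxt$between)) {
      return(nxt)
    }
    # Equal (log) p-values count as non-decreasing and end the search.
    if (log_p(nxt) >= log_p(cur)) {
      return(cur)
    }
    cur <- nxt
  }
  cur
}

#' Fixed-quantile categorization (baseline)
#'
#' Assigns categories by the sample quantiles at `i/q`, `i = 1..q - 1` — the
#' default practice of quantile-based mixture methods.  Tied values always
#' share a label; quantile cutoffs that coincide (heavy ties) are collapsed,
#' so the returned number of categories can be below `q`.
#'
#' @param values Numeric exposure vector with `n >= q`.
#' @param q Number of quantile groups (>= 2, default quartiles).
#'
#' @return An `amc_categorization` (method `"quantile"`).
#' @export
#' @examples
#' quantile_categorize(1:8, q = 4)$labels  # 0 0 1 1 2 2 3 3
quantile_categorize <- function(values, q = 4L) {
  values <- .assert_exposure(values)
  q <- as.integer(q)
  if (is.na(q) || q < 2L) {
    .amc_error("amc_config_error", "`q` must be an integer >= 2")
  }
  n <- length(values)
  if (n < q) {
    .amc_error("amc_infeasible_k_error", "need n >= q observations")
  }
  breaks <- unname(stats::quantile(values, probs = seq_len(q - 1L) / q))
  thresholds <- unique(breaks)
  raw <- findInterval(values, thresholds, left.open = TRUE)
  occupied <- sort(unique(raw))
  k <- length(occupied)
  if (k < 2L) {
    .amc_error("amc_infeasible_k_error",
               sprintf("too few distinct values to form %d nonempty quantile groups", q))
  }
  labels <- match(raw, occupied) - 1L
  thresholds <- thresholds[occupied[-1L]]
  counts <- tabulate(labels + 1L, nbins = k)
  if (n <= k) {
    .amc_error("amc_infeasible_k_error", "need n > k for the F statistic")
  }
  stats <- .partition_stats(values, labels, counts, k)
  .new_categorization(values, thresholds, labels, counts, k, "quantile", stats)
}

#' Apply stored thresholds to (new) data
#'
#' Labels values by half-open intervals `(t_{j-1}, t_j]`: a value exactly at
#' a threshold falls in the lower category.
#'
#' @param values Numeric vector.
#' @param thresholds Increasing numeric thresholds (possibly empty).
#' @return Integer labels in `0:length(thresholds)`.
#' @export
apply_thresholds <- function(values, thresholds) {
  findInterval(values, sort(thresholds), left.open = TRUE)
}

#' Categorize every column of an exposure table
#'
#' @param data Data frame or matrix of numeric exposure columns.
#' @param config An [amc_config()].
#' @param method `"amc"` (default) or `"quantile"`.
#' @param q Number of quantile groups for the quantile method.
#' @return Named list of `amc_categorization` objects, one per column.
#' @export
amc_batch <- function(data, config = amc_config(), method = c("amc", "quantile"),
                      q = 4L) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, TRUE))) {
    bad <- names(data)[!vapply(data, is.numeric, TRUE)]
    .amc_error("amc_input_error",
               sprintf("non-numeric exposure column(s): %s",
                       paste(bad, collapse = ", ")))
  }
  out <- lapply(data, function(col) {
    if (method == "amc") amc_categorize(col, config) else quantile_categorize(col, q)
  })
  names(out) <- names(data)
  out
}

#' Summarize a list of categorizations as a data frame
#'
#' @param categorizations Named list of `amc_categorization` objects (as
#'   returned by [amc_batch()]).
#' @return A data frame with one row per exposure: `exposure`, `k`, `loss`,
#'   `f_statistic`, `p_value`, `degenerate`, and the thresholds collapsed
#'   into a `;`-separated string.
#' @export
categorization_table <- function(categorizations) {
  data.frame(
    exposure = names(categorizations),
    k = vapply(categorizations, function(cc) cc$k, 0L),
    loss = vapply(categorizations, function(cc) cc$loss, 0.0),
    f_statistic = vapply(categorizations, function(cc) cc$f_statistic, 0.0),
    p_value = vapply(categorizations, function(cc) cc$p_value, 0.0),
    degenerate = vapply(categorizations, function(cc) cc$degenerate, TRUE),
    thresholds = vapply(categorizations, function(cc) {
      paste(signif(cc$thresholds, 8), collapse = ";")
    }, ""),
    row.names = NULL
  )
}

#' @export
print.amc_categorization <- function(x, ...) {
  cat(sprintf("Categorization (%s): k = %d, n = %d%s\n", x$method, x$k, x$n,
              if (x$degenerate) " [degenerate: constant input]" else ""))
  if (x$k > 1L) {
    cat("  thresholds:", paste(signif(x$thresholds, 6), collapse = ", "), "\n")
    cat("  counts:    ", paste(x$counts, collapse = ", "), "\n")
    cat(sprintf("  loss = %.6g, F = %.6g, p = %.3g\n",
                x$loss, x$f_statistic, x$p_value))
  }
  invisible(x)
}
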