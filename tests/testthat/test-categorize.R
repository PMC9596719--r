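# amc_core: loss, exhaustive search, linear search, adaptive selection,
# quantile baseline.

test_that("amc_loss matches hand-computed sums of squares and conventions", {
  # zero within-category variance => loss 0, unbounded F
  st <- amc_loss(c(1, 1, 2, 2), c(0, 0, 1, 1), k = 2)
  expect_equal(st$within, 0)
  expect_equal(st$loss, 0)
  expect_identical(st$f_statistic, Inf)

  # within = 5, between = 45 on {1,2,3,4} | {10}
  st <- amc_loss(c(1, 2, 3, 4, 10), c(0, 0, 0, 0, 1), k = 2)
  expect_equal(st$within, 5)
  expect_equal(st$between, 45)
  expect_equal(st$loss, (5 / 3) / 45)
  orc <- oracle_anova_f(c(1, 2, 3, 4, 10), c(0, 0, 0, 0, 1))
  expect_equal(st$f_statistic, orc$f, tolerance = 1e-12)

  # all category means equal -> degenerate, not infinite
  expect_error(amc_loss(c(5, 5, 5, 5), c(0, 1, 0, 1), k = 2),
               class = "amc_degenerate_error")
  expect_error(amc_loss(c(1, 2, 1, 2), c(0, 0, 1, 1), k = 2),
               class = "amc_degenerate_error")
})

test_that("amc_loss rejects malformed partitions", {
  expect_error(amc_loss(c(1, 2, 3), c(0, 0, 0), k = 2), class = "amc_input_error")
  expect_error(amc_loss(c(1, 2, 3), c(0, 1, 2), k = 3), class = "amc_input_error") # n == k
  expect_error(amc_loss(c(1, 2, 3, 4), c(0, 1, 1, 3), k = 4), class = "amc_input_error")
})

test_that("loss equals reciprocal ANOVA F and SS decompose, on random inputs", {
  set.seed(481)
  for (rep in 1:60) {
    n <- sample(6:40, 1)
    k <- sample(2:4, 1)
    x <- random_exposure(n, ties = rep %% 3 == 0)
    lab <- random_labels(n, k)
    st <- tryCatch(amc_loss(x, lab, k), amc_degenerate_error = function(e) NULL)
    if (is.null(st)) next
    orc <- oracle_anova_f(x, lab)
    expect_equal(st$f_statistic, orc$f, tolerance = 1e-9)
    expect_equal(st$p_value, orc$p, tolerance = 1e-9)
    expect_equal(st$loss * st$f_statistic, 1, tolerance = 1e-9)
    total <- sum((x - mean(x))^2)
    expect_equal(st$within + st$between, total, tolerance = 1e-9 * total)
  }
})

test_that("exhaustive search enumerates C(n-1, k-1) splits and finds the optimum", {
  # 16 distinct observations, k = 2 -> 15 candidate splits
  x16 <- seq(0.5, 8, by = 0.5)
  e <- exhaustive_categorize(x16, 2)
  expect_identical(attr(e, "n_enumerated"), 15L)
  expect_equal(attr(e, "search_space"), choose(15, 1))

  e <- exhaustive_categorize(c(1, 2, 3, 4, 10), 2)
  expect_identical(e$labels, c(0L, 0L, 0L, 0L, 1L))
  expect_identical(e$counts, c(4L, 1L))
  expect_equal(e$loss, (5 / 3) / 45)

  # three exact duplicate clusters: boundaries at the distinct-value gaps
  e <- exhaustive_categorize(c(1, 1, 2, 2, 3, 3), 3)
  expect_equal(e$thresholds, c(1.5, 2.5))
  expect_equal(e$loss, 0)

  expect_error(exhaustive_categorize(c(1, 1, 1, 2, 2), 3),
               class = "amc_infeasible_k_error")
  expect_error(exhaustive_categorize(rnorm(31), 2), class = "amc_config_error")
})

test_that("exhaustive loss agrees with an independent brute-force enumeration", {
  set.seed(7002)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    x <- random_exposure(n)
    e <- exhaustive_categorize(x, k)
    expect_equal(e$loss, oracle_best_loss(x, k), tolerance = 1e-9)
  }
})

test_that("linear search keeps previous cutoffs and adds the best new one", {
  # dominant between-cluster variance: first boundary falls between clusters
  set.seed(11)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  s2 <- linear_search_step(x, amcgc:::.single_category(x, "amc", FALSE))
  expect_identical(s2$k, 2L)
  expect_true(s2$thresholds > 1 && s2$thresholds < 4)

  # from the k = 2 optimum of [1,2,3,4,10]: keeps 7, adds 2.5
  # (enumerating the 3 admissible inner boundaries gives withins 2, 1, 2)
  e2 <- exhaustive_categorize(c(1, 2, 3, 4, 10), 2)
  s3 <- linear_search_step(c(1, 2, 3, 4, 10), e2)
  expect_equal(s3$thresholds, c(2.5, 7))
  expect_equal(s3$loss, 1 / 49)

  # all categories exhausted -> no admissible boundary
  e <- exhaustive_categorize(c(1, 1, 2, 2, 3, 3), 3)
  expect_error(linear_search_step(c(1, 1, 2, 2, 3, 3), e),
               class = "amc_no_candidate_error")
})

test_that("greedy linear-search loss is bounded below by the exhaustive loss", {
  set.seed(9035)
  for (rep in 1:30) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    x <- random_exposure(n)
    greedy <- amc_categorize(x, amc_config(k_fixed = k))
    exact <- exhaustive_categorize(x, k)
    expect_gte(greedy$loss, exact$loss - 1e-12)
    if (k == 2L) {
      expect_equal(greedy$loss, exact$loss, tolerance = 1e-12)
    }
  }
})

test_that("adaptive selection stops at the first p-value increase", {
  # A 16-observation draw from three normal components (means 1, 2, 3, sd
  # 0.33) on which the rule demonstrably fires: the F-test p-value drops
  # from k = 2 to k = 3 and rises again at k = 4 (path verified below with
  # stats::pf on independently recomputed F statistics).
  x <- c(0.511, 1.52, 0.684, 0.696, 0.341, 0.91, 1.896, 1.793, 1.965,
         2.141, 1.743, 2.573, 2.743, 3.004, 2.95, 2.768)
  res <- amc_categorize(x)
  expect_identical(res$k, 3L)

  logp <- function(cc) {
    f <- oracle_anova_f(x, cc$labels)
    stats::pf(f$f, cc$k - 1, length(x) - cc$k, lower.tail = FALSE, log.p = TRUE)
  }
  c2 <- exhaustive_categorize(x, 2)
  c3 <- linear_search_step(x, c2)
  c4 <- linear_search_step(x, c3)
  expect_lt(logp(c3), logp(c2))
  expect_gte(logp(c4), logp(c3))
  expect_equal(res$thresholds, c3$thresholds)
})

test_that("adaptive selection respects its caps and degenerate contract", {
  set.seed(551)
  x <- rnorm(400)
  expect_lte(amc_categorize(x)$k, 10L)
  expect_lte(amc_categorize(x, amc_config(k_max = 5))$k, 5L)

  # fixed-k contract regardless of the p-value path
  expect_identical(amc_categorize(x, amc_config(k_fixed = 3))$k, 3L)

  cc <- amc_categorize(rep(2.2, 40))
  expect_identical(cc$k, 1L)
  expect_true(cc$degenerate)
  expect_identical(cc$labels, rep(0L, 40))
})

test_that("minimum category fraction excludes undersized candidates", {
  set.seed(88)
  # heavy right tail: unconstrained search isolates the few extremes
  x <- c(rnorm(95), rnorm(5, 12))
  uncon <- amc_categorize(x, amc_config(k_fixed = 3))
  expect_lt(min(uncon$counts), 10)
  con <- amc_categorize(x, amc_config(k_fixed = 3, min_category_fraction = 0.10))
  expect_gte(min(con$counts), 10)
})

test_that("labels are monotone in the values and ties always share a label", {
  set.seed(6120)
  for (rep in 1:25) {
    x <- round(rnorm(sample(20:80, 1)), if (rep %% 2) 1 else 0)
    if (diff(range(x)) == 0) next
    cfgs <- list(amc_config(), amc_config(k_fixed = 3))
    for (cfg in cfgs) {
      cc <- tryCatch(amc_categorize(x, cfg),
                     amc_no_candidate_error = function(e) NULL)
      if (is.null(cc)) next
      ord <- order(x)
      expect_true(all(diff(cc$labels[ord]) >= 0))
      expect_true(all(tapply(cc$labels, x, function(l) length(unique(l))) == 1L))
      expect_identical(sum(cc$counts), cc$n)
      expect_true(all(cc$counts >= 1L))
    }
  }
})

test_that("quantile categorization uses i/q cutoffs and shares tied labels", {
  expect_identical(quantile_categorize(1:8, 4)$labels,
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(quantile_categorize(1:8, 2)$labels,
                   c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

  # 60% tied minimum: all tied values share label 0, collapsed cutoffs drop
  set.seed(4)
  x <- c(rep(0, 60), runif(40, 1, 5))
  qc <- quantile_categorize(x, 4)
  expect_true(all(qc$labels[x == 0] == 0L))
  expect_gte(qc$counts[1], 60L)
  expect_lte(qc$k, 4L)

  expect_error(quantile_categorize(c(1, 1, 1, 1), 4),
               class = "amc_infeasible_k_error")
  # loss fields populated for the induced partition
  st <- oracle_anova_f(1:8, quantile_categorize(1:8, 4)$labels)
  expect_equal(quantile_categorize(1:8, 4)$f_statistic, st$f, tolerance = 1e-9)
})

test_that("thresholds are half-open upper bounds and round-trip labels", {
  x <- c(1, 2, 3, 4, 10)
  cc <- exhaustive_categorize(x, 2)
  expect_identical(apply_thresholds(x, cc$thresholds), cc$labels)
  # a value exactly at the threshold falls in the lower category
  expect_identical(apply_thresholds(c(cc$thresholds, cc$thresholds + 1e-9),
                                    cc$thresholds), c(0L, 1L))
})

test_that("batch categorization handles mixed columns and serializes", {
  set.seed(31)
  d <- data.frame(a = rnorm(60, rep(c(0, 6), each = 30)), b = rep(1.5, 60))
  cats <- amc_batch(d, amc_config(k_fixed = 2))
  expect_named(cats, c("a", "b"))
  expect_identical(cats$a$k, 2L)
  expect_true(cats$b$degenerate)  # constant column flagged, not an error
  tab <- categorization_table(cats)
  expect_identical(tab$exposure, c("a", "b"))
  expect_identical(tab$k, c(2L, 1L))
  expect_error(amc_batch(data.frame(a = 1:5, b = letters[1:5])),
               class = "amc_input_error")
})
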