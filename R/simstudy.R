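#' Define a latent-state simulation scenario
#'
#' The generative model used throughout the simulation studies: each of `m`
#' exposures has a hidden 4-level state `Z_j` drawn per subject from a
#' multinomial with probabilities `alpha`, and the observed exposure is drawn
#' from the normal component attached to that state (defaults
#' `N(1, 0.33^2) .. N(4, 0.33^2)`).  The outcome depends on the latent
#' states, not the observed concentrations:
#' \itemize{
#'   \item `two_exposure`: `Y = beta1 Z_1 + beta2 Z_2 + e` — the bias study
#'     (m = 5, n = 200 by default).
#'   \item `monotonic`: `Y = sum_{i=1..10} beta_i Z_i + e` with
#'     `beta_1..7 = 0.1`, `beta_8..10 = -0.1`, so `psi_true = 0.4`.
#'   \item `nonmonotonic`: the first 5 exposures act through dummy-coded
#'     states with level effects `(0, 1, -1, 0)` — an inverted-U shape no
#'     single ordinal score captures.
#' }
#' `e ~ N(0, sigma^2)` with `sigma = 1`.
#'
#' @param n Sample size.
#' @param m Number of exposures.
#' @param alpha State probabilities (length 4, positive, summing to 1).
#' @param effect_model `"two_exposure"`, `"monotonic"` or `"nonmonotonic"`.
#' @param betas Effect vector: length 2 for `two_exposure` (defaults
#'   `c(0.5, 0.5)`); length 10 for `monotonic` (defaults
#'   `c(rep(0.1, 7), rep(-0.1, 3))`); a 5 x 4 matrix of per-level effects for
#'   `nonmonotonic` (defaults rows `c(0, 1, -1, 0)`).
#' @param means,sds Component means and standard deviations (length 4).
#' @param sigma Outcome noise standard deviation.
#'
#' @return An object of class `amc_scenario` with `psi_true` filled in (sum
#'   of per-category-increment effects).
#' @export
sim_scenario <- function(n, m,
                         alpha = c(0.25, 0.25, 0.25, 0.25),
                         effect_model = c("two_exposure", "monotonic", "nonmonotonic"),
                         betas = NULL,
                         means = 1:4, sds = rep(0.33, 4), sigma = 1) {
  effect_model <- match.arg(effect_model)
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 10L || is.na(m) || m < 1L) {
    .amc_error("amc_config_error", "`n` and `m` must be positive (n >= 10)")
  }
  if (length(alpha) != 4L || any(alpha <= 0) || any(alpha >= 1) ||
      abs(sum(alpha) - 1) > 1e-8) {
    .amc_error("amc_config_error",
               "`alpha` must be 4 probabilities in (0,1) summing to 1")
  }
  if (length(means) != 4L || length(sds) != 4L || any(sds <= 0)) {
    .amc_error("amc_config_error", "need 4 component means and positive sds")
  }
  if (is.null(betas)) {
    betas <- switch(effect_model,
                    two_exposure = c(0.5, 0.5),
                    monotonic = c(rep(0.1, 7), rep(-0.1, 3)),
                    nonmonotonic = matrix(rep(c(0, 1, -1, 0), each = 5), nrow = 5))
  }
  n_causal <- switch(effect_model, two_exposure = 2L, monotonic = 10L,
                     nonmonotonic = 5L)
  if (effect_model == "nonmonotonic") {
    betas <- as.matrix(betas)
    if (!all(dim(betas) == c(5L, 4L))) {
      .amc_error("amc_config_error",
                 "`betas` must be a 5 x 4 matrix for the nonmonotonic model")
    }
  } else if (length(betas) != n_causal) {
    .amc_error("amc_config_error",
               sprintf("`betas` must have length %d for the %s model",
                       n_causal, effect_model))
  }
  if (m < n_causal) {
    .amc_error("amc_config_error",
               sprintf("`m` must be >= %d for the %s model", n_causal, effect_model))
  }
  psi_true <- sum(betas)
  structure(list(n = n, m = m, alpha = as.numeric(alpha),
                 effect_model = effect_model, betas = betas,
                 means = as.numeric(means), sds = as.numeric(sds),
                 sigma = sigma, psi_true = psi_true),
            class = "amc_scenario")
}

#' The four bias-study scenarios
#'
#' Preset `two_exposure` scenarios crossing state proportions (equal
#' `0.25 x 4` vs. unequal `0.4, 0.3, 0.2, 0.1`) with effect directions (both
#' positive `0.5, 0.5` vs. mixed `1.5, -0.5`); `psi_true = 1` in all four.
#'
#' @param id Scenario number 1-4.
#' @param n Sample size (default 200).
#' @param m Number of exposures (default 5).
#' @return An `amc_scenario`.
#' @export
bias_scenario <- function(id, n = 200L, m = 5L) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > 4L) {
    .amc_error("amc_config_error", "`id` must be 1, 2, 3 or 4")
  }
  alpha <- if (id %in% c(1L, 2L)) rep(0.25, 4) else c(0.4, 0.3, 0.2, 0.1)
  betas <- if (id %in% c(1L, 3L)) c(0.5, 0.5) else c(1.5, -0.5)
  sim_scenario(n = n, m = m, alpha = alpha, effect_model = "two_exposure",
               betas = betas)
}

#' Draw one dataset from a scenario
#'
#' @param scenario An `amc_scenario`.
#' @param seed Optional integer seed (the ambient RNG stream is used when
#'   `NULL`, so study runners can seed once and draw repeatedly).
#'
#' @return List with `exposures` (n x m data frame, columns `X1..Xm`),
#'   `latent` (n x m integer matrix of states 0-3) and `outcome`.
#' @export
generate_dataset <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "amc_scenario")) {
    .amc_error("amc_config_error", "`scenario` must come from sim_scenario()")
  }
  .with_seed(seed, {
    n <- scenario$n; m <- scenario$m
    latent <- matrix(sample.int(4L, n * m, replace = TRUE,
                                prob = scenario$alpha) - 1L,
                     nrow = n, ncol = m)
    x <- matrix(stats::rnorm(n * m,
                             mean = scenario$means[latent + 1L],
                             sd = scenario$sds[latent + 1L]),
                nrow = n, ncol = m)
    colnames(x) <- colnames(latent) <- paste0("X", seq_len(m))
    eps <- if (scenario$sigma > 0) stats::rnorm(n, 0, scenario$sigma) else 0
    signal <- switch(scenario$effect_model,
      two_exposure = latent[, 1L] * scenario$betas[1L] +
        latent[, 2L] * scenario$betas[2L],
      monotonic = drop(latent[, 1:10] %*% scenario$betas),
      nonmonotonic = {
        s <- 0
        for (j in 1:5) s <- s + scenario$betas[j, latent[, j] + 1L]
        s
      })
    list(exposures = as.data.frame(x), latent = latent,
         outcome = signal + eps)
  })
}

#' Truth specification for variable-selection scoring
#'
#' Which terms a perfect analysis would place in the top (positive) and
#' bottom (negative) weight-rank sets.  Monotonic model: ordinal terms
#' `X1..X7` positive, `X8..X10` negative.  Nonmonotonic model: dummy terms
#' `X1_1..X5_1` (level-1 effects +1) positive and `X1_2..X5_2` (level-2
#' effects -1) negative.
#'
#' @param scenario An `amc_scenario` with a `monotonic` or `nonmonotonic`
#'   effect model.
#' @return List with `positive` and `negative` character vectors of term
#'   names.
#' @export
selection_truth <- function(scenario) {
  switch(scenario$effect_model,
    monotonic = list(positive = paste0("X", 1:7),
                     negative = paste0("X", 8:10)),
    nonmonotonic = list(positive = paste0("X", 1:5, "_1"),
                        negative = paste0("X", 1:5, "_2")),
    .amc_error("amc_config_error",
               "selection truth is defined for the monotonic and nonmonotonic models"))
}

.rank_sets <- function(weights, truth) {
  n_top <- length(truth$positive)
  n_bottom <- length(truth$negative)
  if (length(weights) < n_top + n_bottom) {
    .amc_error("amc_config_error",
               "fewer weight terms than required rank-set slots")
  }
  ord <- names(weights)[order(-weights)]  # stable: ties keep input order
  list(top = ord[seq_len(n_top)],
       bottom = ord[seq.int(length(ord) - n_bottom + 1L, length(ord))])
}

#' True positive rate of weight-based variable selection
#'
#' Sorts the signed weights in descending order and counts how many truly
#' positive-effect terms land among the largest `length(truth$positive)`
#' weights (`TP1`) and how many truly negative-effect terms land among the
#' smallest `length(truth$negative)` weights (`TP2`);
#' `TPR = (TP1 + TP2) / P` with `P` the number of causal terms.
#'
#' @param weights Named numeric vector of signed weights covering all terms.
#' @param truth A truth specification from [selection_truth()] (or any list
#'   with `positive` / `negative` term names).
#' @return TPR in `[0, 1]`.
#' @export
compute_tpr <- function(weights, truth) {
  sets <- .rank_sets(weights, truth)
  tp <- sum(truth$positive %in% sets$top) + sum(truth$negative %in% sets$bottom)
  tp / (length(truth$positive) + length(truth$negative))
}

#' False positive rate of weight-based variable selection
#'
#' Counts non-causal terms occupying the counted top/bottom rank sets,
#' divided by the total number of non-causal terms present.
#'
#' @inheritParams compute_tpr
#' @return FPR in `[0, 1]`.
#' @export
compute_fpr <- function(weights, truth) {
  sets <- .rank_sets(weights, truth)
  causal <- c(truth$positive, truth$negative)
  noncausal <- setdiff(names(weights), causal)
  if (!length(noncausal)) {
    return(0)
  }
  fp <- sum(sets$top %in% noncausal) + sum(sets$bottom %in% noncausal)
  fp / length(noncausal)
}

.new_metrics <- function(study, method, scenario, reps, n_ok, values) {
  structure(c(list(study = study, method = method, n = scenario$n,
                   m = scenario$m, effect_model = scenario$effect_model,
                   psi_true = scenario$psi_true, reps = as.integer(reps),
                   n_ok = as.integer(n_ok),
                   n_failed = as.integer(reps) - as.integer(n_ok)),
              values),
            class = "amc_metrics")
}

#' Bias study for the joint mixture effect
#'
#' Repeatedly draws a `two_exposure` dataset, categorizes every exposure
#' (adaptive AMC or fixed quantiles), fits the ordinal-coded linear
#' g-computation model and records `psi_estimate - psi_true`.
#'
#' @param scenario An `amc_scenario` with `effect_model = "two_exposure"`.
#' @param method `"amc"` or `"quantile"`.
#' @param reps Number of simulation replicates.
#' @param seed Integer seed for the whole study.
#' @param config AMC search configuration.  Defaults to `k_fixed = 4`,
#'   matching the 4-state latent structure of the generative model; the
#'   adaptive p-value rule is anti-conservative on continuous data (see
#'   [amc_categorize()]) and would dilute the ordinal effect over `k_max`
#'   categories.
#' @param q Quantile groups for the quantile arm.
#'
#' @return An `amc_metrics` object with `bias_mean`, the per-replicate
#'   `bias` vector, and failure counts (replicates whose fit failed are
#'   dropped from the average and counted).
#' @export
run_bias_study <- function(scenario, method = c("amc", "quantile"),
                           reps = 1000L, seed = NULL,
                           config = amc_config(k_fixed = 4L), q = 4L) {
  method <- match.arg(method)
  if (!identical(scenario$effect_model, "two_exposure")) {
    .amc_error("amc_config_error", "the bias study uses the two_exposure model")
  }
  bias <- .with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      d <- generate_dataset(scenario)
      tryCatch({
        fit <- amc_gcomp(d$exposures, d$outcome, coding = "ordinal",
                         family = "linear", method = method,
                         config = config, q = q)
        fit$psi - scenario$psi_true
      }, error = function(e) NA_real_)
    }, 0.0)
  })
  .new_metrics("bias", method, scenario, reps, sum(!is.na(bias)),
               list(bias_mean = mean(bias, na.rm = TRUE), bias = bias))
}

#' Variable-selection (TPR/FPR) study
#'
#' Repeatedly draws a dataset, categorizes every exposure, codes it (ordinal
#' for the monotonic model, dummy for the nonmonotonic model), fits the
#' linear g-computation model, and scores the signed weights with
#' [compute_tpr()] and [compute_fpr()].
#'
#' @param scenario An `amc_scenario` with a `monotonic` or `nonmonotonic`
#'   effect model.
#' @inheritParams run_bias_study
#'
#' @return An `amc_metrics` object with `tpr_mean`, `fpr_mean` and the
#'   per-replicate `tpr` / `fpr` vectors.
#' @export
run_tpr_study <- function(scenario, method = c("amc", "quantile"),
                          reps = 1000L, seed = NULL,
                          config = amc_config(k_fixed = 4L), q = 4L) {
  method <- match.arg(method)
  truth <- selection_truth(scenario)
  coding <- if (identical(scenario$effect_model, "monotonic")) "ordinal" else "dummy"
  res <- .with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      d <- generate_dataset(scenario)
      tryCatch({
        fit <- amc_gcomp(d$exposures, d$outcome, coding = coding,
                         family = "linear", method = method,
                         config = config, q = q)
        c(compute_tpr(fit$weights, truth), compute_fpr(fit$weights, truth))
      }, error = function(e) c(NA_real_, NA_real_))
    }, c(0.0, 0.0))
  })
  .new_metrics("tpr", method, scenario, reps, sum(!is.na(res[1L, ])),
               list(tpr_mean = mean(res[1L, ], na.rm = TRUE),
                    fpr_mean = mean(res[2L, ], na.rm = TRUE),
                    tpr = res[1L, ], fpr = res[2L, ]))
}

#' @export
print.amc_metrics <- function(x, ...) {
  cat(sprintf("%s study, %s arm: n = %d, m = %d, %d/%d replicates ok\n",
              x$study, x$method, x$n, x$m, x$n_ok, x$reps))
  if (!is.null(x$bias_mean)) {
    cat(sprintf("  mean bias = %.4f (psi_true = %g)\n", x$bias_mean, x$psi_true))
  }
  if (!is.null(x$tpr_mean)) {
    cat(sprintf("  mean TPR = %.3f, mean FPR = %.3f\n", x$tpr_mean, x$fpr_mean))
  }
  invisible(x)
}
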