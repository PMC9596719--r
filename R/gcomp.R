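#' Build a coded design matrix from categorized exposures
#'
#' Translates per-exposure category labels into regression terms.  Ordinal
#' coding enters each exposure as a single integer score `0..k-1` (one
#' category increment per unit); dummy coding enters `k - 1` indicator
#' columns per exposure with the lowest category as the reference, allowing
#' non-monotonic category effects.  Covariates are appended untransformed
#' (numeric) or expanded to indicators with the first level as reference
#' (factor/character).
#'
#' @param categorizations Named list of `amc_categorization` objects or plain
#'   integer label vectors (`0`-based).
#' @param coding `"ordinal"` or `"dummy"`.
#' @param covariates Optional data frame of covariates.
#'
#' @return An object of class `amc_design`: list with `matrix` (n x p),
#'   `coding` and `term_map` (data frame: `column`, `exposure`, `level`,
#'   `is_covariate`).
#' @export
code_design <- function(categorizations, coding = c("ordinal", "dummy"),
                        covariates = NULL) {
  coding <- match.arg(coding)
  if (is.null(names(categorizations)) || any(names(categorizations) == "")) {
    .amc_error("amc_input_error", "`categorizations` must be a named list")
  }
  labs <- lapply(categorizations, function(cc) {
    if (inherits(cc, "amc_categorization")) cc$labels else as.integer(cc)
  })
  n <- unique(lengths(labs))
  if (length(n) != 1L) {
    .amc_error("amc_input_error", "exposures differ in length")
  }
  cols <- list()
  map <- list()
  for (nm in names(labs)) {
    z <- labs[[nm]]
    k <- max(z) + 1L
    if (k < 2L) {
      warning(sprintf("exposure '%s' has a single category; dropped from the design", nm))
      next
    }
    if (coding == "ordinal") {
      cols[[nm]] <- as.numeric(z)
      map[[nm]] <- data.frame(column = nm, exposure = nm, level = "ordinal",
                              is_covariate = FALSE)
    } else {
      for (lev in 1:(k - 1L)) {
        cn <- sprintf("%s_%d", nm, lev)
        cols[[cn]] <- as.numeric(z == lev)
        map[[cn]] <- data.frame(column = cn, exposure = nm,
                                level = as.character(lev), is_covariate = FALSE)
      }
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      .amc_error("amc_input_error", "`covariates` must have one row per observation")
    }
    chr <- vapply(covariates, function(v) is.character(v) || is.logical(v), TRUE)
    covariates[chr] <- lapply(covariates[chr], factor)
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    for (cn in colnames(mm)) {
      cols[[cn]] <- mm[, cn]
      map[[cn]] <- data.frame(column = cn, exposure = NA_character_,
                              level = NA_character_, is_covariate = TRUE)
    }
  }
  if (!length(cols)) {
    .amc_error("amc_input_error", "design has no usable exposure terms")
  }
  structure(list(matrix = do.call(cbind, cols),
                 coding = coding,
                 term_map = do.call(rbind, c(map, list(make.row.names = FALSE)))),
            class = "amc_design")
}

#' Direction-normalized mixture weights
#'
#' Scales regression coefficients so that the positive weights sum to 1 and
#' the negative weights sum to -1 (each direction normalized by the absolute
#' total of coefficients sharing its sign).  Signs are retained, so ranking
#' terms by signed weight is well-defined.
#'
#' @param coefficients Named numeric vector of exposure-term coefficients.
#' @return Named numeric vector of signed weights (zero coefficients keep
#'   weight zero).
#' @export
#' @examples
#' mixture_weights(c(a = 0.5, b = 0.5, c = -0.25))  # 0.5, 0.5, -1
mixture_weights <- function(coefficients) {
  w <- coefficients
  pos <- coefficients > 0
  neg <- coefficients < 0
  if (any(pos)) w[pos] <- coefficients[pos] / sum(coefficients[pos])
  if (any(neg)) w[neg] <- coefficients[neg] / abs(sum(coefficients[neg]))
  w
}

#' Fit the g-computation model on a coded design
#'
#' Fits a generalized linear model of the outcome on all coded exposure
#' terms plus covariates (identity link for continuous outcomes, logit link
#' for binary ones).  The joint mixture effect \eqn{\psi} — the expected
#' change in the linear predictor when every exposure moves up one category
#' simultaneously — is the sum of the exposure-term coefficients; covariates
#' contribute to the fit but not to \eqn{\psi} or the weights.
#'
#' @param design An `amc_design` from [code_design()].
#' @param outcome Numeric outcome vector (0/1 for `family = "logistic"`).
#' @param family `"linear"` or `"logistic"`.
#'
#' @return An object of class `amc_gcomp_fit`: exposure `coefficients`,
#'   `covariate_coefficients`, `psi`, signed `weights`, `coding`, `family`,
#'   `term_map`, `n`.
#' @export
fit_gcomp <- function(design, outcome, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (!inherits(design, "amc_design")) {
    .amc_error("amc_input_error", "`design` must come from code_design()")
  }
  X <- design$matrix
  n <- nrow(X)
  if (length(outcome) != n) {
    .amc_error("amc_input_error", "`outcome` must match the design in length")
  }
  if (n <= ncol(X) + 1L) {
    .amc_error("amc_input_error", "need more observations than model terms")
  }
  if (family == "logistic" && !all(outcome %in% c(0, 1))) {
    .amc_error("amc_input_error", "logistic family requires a 0/1 outcome")
  }
  df <- data.frame(.y = outcome, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                               collapse = " + ")))
  fit <- if (family == "linear") {
    stats::lm(fml, data = df)
  } else {
    stats::glm(fml, data = df, family = stats::binomial())
  }
  if (family == "logistic" && !fit$converged) {
    .amc_error("amc_convergence_error",
               sprintf("logistic fit did not converge in %d iterations (possible separation)",
                       fit$iter),
               iterations = fit$iter)
  }
  beta <- stats::coef(fit)[-1L]
  names(beta) <- colnames(X)
  if (anyNA(beta)) {
    .amc_error("amc_collinearity_error",
               sprintf("rank-deficient design; aliased column(s): %s",
                       paste(names(beta)[is.na(beta)], collapse = ", ")),
               columns = names(beta)[is.na(beta)])
  }
  exp_terms <- design$term_map$column[!design$term_map$is_covariate]
  exp_beta <- beta[exp_terms]
  structure(list(
    coefficients = exp_beta,
    covariate_coefficients = beta[setdiff(names(beta), exp_terms)],
    psi = sum(exp_beta),
    weights = mixture_weights(exp_beta),
    coding = design$coding,
    family = family,
    term_map = design$term_map,
    n = n
  ), class = "amc_gcomp_fit")
}

#' Categorize-then-fit mixture pipeline
#'
#' End-to-end estimation: categorize every exposure column (adaptive AMC
#' search or fixed quantiles), code the categories, and fit the
#' g-computation model.  Supplying `thresholds` freezes categorization at
#' previously estimated cutoffs instead of re-searching.
#'
#' @param exposures Data frame of numeric exposure columns.
#' @param outcome Outcome vector.
#' @param covariates Optional covariate data frame.
#' @param coding `"ordinal"` or `"dummy"`.
#' @param family `"linear"` or `"logistic"`.
#' @param method `"amc"` or `"quantile"`.
#' @param config An [amc_config()] for the AMC search.
#' @param q Quantile groups for `method = "quantile"`.
#' @param thresholds Optional named list of threshold vectors to apply as-is.
#'
#' @return An `amc_gcomp_fit` with the per-exposure `categorizations` and
#'   `thresholds` attached.
#' @export
amc_gcomp <- function(exposures, outcome, covariates = NULL,
                      coding = c("ordinal", "dummy"),
                      family = c("linear", "logistic"),
                      method = c("amc", "quantile"),
                      config = amc_config(), q = 4L, thresholds = NULL) {
  coding <- match.arg(coding)
  family <- match.arg(family)
  method <- match.arg(method)
  exposures <- as.data.frame(exposures)
  if (!is.null(thresholds)) {
    cats <- lapply(names(exposures), function(nm) {
      if (is.null(thresholds[[nm]])) {
        .amc_error("amc_config_error",
                   sprintf("no thresholds supplied for exposure '%s'", nm))
      }
      apply_thresholds(exposures[[nm]], thresholds[[nm]])
    })
    names(cats) <- names(exposures)
  } else {
    cats <- amc_batch(exposures, config = config, method = method, q = q)
  }
  design <- code_design(cats, coding = coding, covariates = covariates)
  fit <- fit_gcomp(design, outcome, family = family)
  fit$categorizations <- cats
  fit$thresholds <- if (is.null(thresholds)) {
    lapply(cats, function(cc) if (inherits(cc, "amc_categorization")) cc$thresholds)
  } else {
    thresholds
  }
  fit
}

#' Percentile bootstrap over a full analysis pipeline
#'
#' Resamples individuals (rows) with replacement and re-runs the supplied
#' pipeline on each resample — re-estimating categorization thresholds inside
#' the resample when the pipeline does so — returning percentile 2.5%/97.5%
#' bounds for every quantity the pipeline reports.
#'
#' @param data Data frame of raw rows to resample.
#' @param pipeline Function taking a resampled data frame and returning a
#'   named numeric vector of quantities.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; results are reproducible given the seed.
#'
#' @return List with `ci` (matrix, rows = quantities, columns `lower`,
#'   `upper`), `draws` (n_boot x quantities, `NA` where a quantity was absent
#'   from a resample), and `n_failed`.  Resamples on which the pipeline
#'   errors are skipped; more than 10% failures is an error.
#' @export
bootstrap_ci <- function(data, pipeline, n_boot = 1000L, seed = NULL) {
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 2L) {
    .amc_error("amc_config_error", "`n_boot` must be >= 2")
  }
  data <- as.data.frame(data)
  n <- nrow(data)
  draws <- .with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(pipeline(data[idx, , drop = FALSE]), error = function(e) NULL)
    })
  })
  failed <- vapply(draws, is.null, TRUE)
  if (sum(failed) > 0.1 * n_boot) {
    .amc_error("amc_bootstrap_error",
               sprintf("%d of %d bootstrap resamples failed (> 10%%)",
                       sum(failed), n_boot))
  }
  ok <- draws[!failed]
  all_names <- unique(unlist(lapply(ok, names)))
  mat <- matrix(NA_real_, nrow = n_boot, ncol = length(all_names),
                dimnames = list(NULL, all_names))
  for (b in which(!failed)) {
    mat[b, names(draws[[b]])] <- draws[[b]]
  }
  ci <- t(apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, draws = mat, n_failed = sum(failed))
}

#' Bootstrap confidence intervals for a g-computation fit
#'
#' Convenience wrapper around [bootstrap_ci()] for the
#' categorize-then-fit pipeline: rows of `exposures`, `outcome` and
#' `covariates` are resampled jointly and the entire pipeline, including the
#' categorization search, is repeated on each resample (set
#' `refit_thresholds = FALSE` to freeze the full-data thresholds instead).
#'
#' @inheritParams amc_gcomp
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param refit_thresholds Re-estimate categorization per resample (default)
#'   or reuse the full-data thresholds.
#'
#' @return The full-data `amc_gcomp_fit` augmented with `ci` (list with
#'   `psi`, `weights`, and for logistic fits `or`), `n_boot`, `seed` and
#'   `boot` (the [bootstrap_ci()] result).
#' @export
bootstrap_gcomp <- function(exposures, outcome, covariates = NULL,
                            coding = "ordinal", family = "linear",
                            method = "amc", config = amc_config(), q = 4L,
                            n_boot = 1000L, seed = NULL,
                            refit_thresholds = TRUE) {
  exposures <- as.data.frame(exposures)
  full <- amc_gcomp(exposures, outcome, covariates, coding, family, method,
                    config, q)
  frozen <- if (refit_thresholds) NULL else full$thresholds
  m <- ncol(exposures)
  dat <- data.frame(.outcome = outcome, exposures, check.names = FALSE)
  if (!is.null(covariates)) {
    dat <- cbind(dat, as.data.frame(covariates))
  }
  cov_names <- if (is.null(covariates)) NULL else names(as.data.frame(covariates))
  pipeline <- function(d) {
    fit <- amc_gcomp(d[names(exposures)], d$.outcome,
                     covariates = if (is.null(cov_names)) NULL else d[cov_names],
                     coding = coding, family = family, method = method,
                     config = config, q = q, thresholds = frozen)
    c(psi = fit$psi, fit$weights)
  }
  boot <- bootstrap_ci(dat, pipeline, n_boot = n_boot, seed = seed)
  full$ci <- list(psi = boot$ci["psi", ],
                  weights = boot$ci[setdiff(rownames(boot$ci), "psi"), ,
                                    drop = FALSE])
  if (family == "logistic") {
    full$ci$or <- exp(boot$ci["psi", ])
  }
  full$n_boot <- as.integer(n_boot)
  full$seed <- seed
  full$boot <- boot
  full
}

#' Odds ratio of a joint mixture effect
#'
#' Under a logistic model, `exp(psi)` is the odds ratio comparing the
#' population with every exposure one category higher against the observed
#' one; confidence bounds map through the same transform.
#'
#' @param x A numeric \eqn{\psi} (log odds) or an `amc_gcomp_fit` from a
#'   logistic fit.
#' @return For numeric input, `exp(x)`; for a fit, a list with `or` and,
#'   when bootstrap intervals are present, `ci`.
#' @export
odds_ratio <- function(x) {
  if (is.numeric(x)) {
    return(exp(x))
  }
  if (!inherits(x, "amc_gcomp_fit")) {
    .amc_error("amc_input_error", "`x` must be numeric or an amc_gcomp_fit")
  }
  if (!identical(x$family, "logistic")) {
    .amc_error("amc_config_error", "odds ratios require a logistic fit")
  }
  out <- list(or = exp(x$psi))
  if (!is.null(x$ci)) {
    out$ci <- exp(x$ci$psi)
  }
  out
}

#' @export
print.amc_gcomp_fit <- function(x, ...) {
  cat(sprintf("G-computation fit (%s outcome, %s coding), n = %d\n",
              x$family, x$coding, x$n))
  cat(sprintf("  joint mixture effect psi = %.4f", x$psi))
  if (!is.null(x$ci)) {
    cat(sprintf("  [95%% CI %.4f, %.4f; %d bootstraps]",
                x$ci$psi["lower"], x$ci$psi["upper"], x$n_boot))
  }
  cat("\n")
  if (identical(x$family, "logistic")) {
    cat(sprintf("  odds ratio exp(psi) = %.4f\n", exp(x$psi)))
  }
  cat("  weights:\n")
  w <- sort(x$weights, decreasing = TRUE)
  print(round(w, 4))
  invisible(x)
}
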