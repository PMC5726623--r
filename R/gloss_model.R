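# Linear gloss-prediction model and the synthetic observer.
#
# Perceived gloss is modelled as a linear function of the four highlight
# statistics (number, mean size, percentage area, strength). A synthetic
# observer with known weights generates noisy responses on the experimental
# design grid so the fitting machinery can be validated by parameter
# recovery.

GLOSS_FEATURES <- c("number", "mean_size", "pct_area", "strength")

#' Experimental design grid
#'
#' Cartesian product of the stimulus factors in deterministic order
#' (smoothness varies fastest, then alpha, shape, intensity). The default
#' levels are the full design: 5 smoothness x 7 spread x 5 shapes x
#' 2 intensities = 350 conditions; with 4 repetitions, 1,400 trials.
#'
#' @param smoothness,alpha,shapes,intensity factor levels.
#' @param repetitions trials per condition (1 = conditions only).
#' @return `data.frame` with one row per condition (x repetition), columns
#'   `shape`, `smoothness`, `alpha`, `intensity` (+ `rep` if repetitions > 1).
#' @export
enumerate_design <- function(smoothness = c(0.2, 0.3, 0.4, 0.5, 0.6),
                             alpha = c(0, 0.04, 0.08, 0.12, 0.16, 0.32, 0.6),
                             shapes = c("blob1", "blob2", "blob3",
                                        "sphere", "cylinder"),
                             intensity = c(0.5, 1.5),
                             repetitions = 1L) {
  g <- expand.grid(smoothness = smoothness, alpha = alpha, shape = shapes,
                   intensity = intensity, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("shape", "smoothness", "alpha", "intensity")]
  if (repetitions > 1) {
    g <- g[rep(seq_len(nrow(g)), each = repetitions), ]
    g$rep <- rep(seq_len(repetitions), times = nrow(g) / repetitions)
    rownames(g) <- NULL
  }
  g
}

#' Synthetic observer parameters
#'
#' @param intercept scalar baseline response.
#' @param weights named (or ordered) numeric vector of length 4: weights on
#'   the standardized features number, mean_size, pct_area, strength.
#' @param noise_sd Gaussian response noise SD, >= 0.
#' @param seed integer RNG seed.
#' @return object of class `observer_params`.
#' @export
observer_params <- function(intercept = 0,
                            weights = c(number = 0.1, mean_size = -0.2,
                                        pct_area = -0.5, strength = 0.4),
                            noise_sd = 0.1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(weights) != 4) stop("weights must have length 4")
  names(weights) <- GLOSS_FEATURES
  structure(list(intercept = intercept, weights = weights,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "observer_params")
}

standardize_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  z <- sweep(sweep(x, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
  list(z = z, mean = mu, sd = sdv)
}

#' Generate synthetic perceived-gloss responses
#'
#' Adds a `response` column: intercept + weights . standardized features +
#' Gaussian noise. Features are standardized over the valid records; invalid
#' records receive `NA` responses. Deterministic for a fixed seed, and the
#' caller's RNG stream is left untouched.
#'
#' @param records data frame with the four feature columns and (optionally)
#'   an `invalid` logical column.
#' @param params an `observer_params`.
#' @return `records` with a `response` column.
#' @export
synth_observer <- function(records, params) {
  stopifnot(all(GLOSS_FEATURES %in% names(records)))
  ok <- valid_rows(records)
  x <- as.matrix(records[ok, GLOSS_FEATURES])
  z <- standardize_cols(x)$z
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(params$seed)
  eps <- if (params$noise_sd > 0) stats::rnorm(nrow(z), 0, params$noise_sd) else 0
  records$response <- NA_real_
  records$response[ok] <- params$intercept +
    as.numeric(z %*% params$weights) + eps
  records
}

valid_rows <- function(records) {
  ok <- stats::complete.cases(records[, GLOSS_FEATURES])
  if ("invalid" %in% names(records)) ok <- ok & !records$invalid
  ok
}

#' Fit the linear gloss model
#'
#' Ordinary least squares of `response` on the four highlight statistics,
#' solved through the normal equations on internally standardized features
#' (so weights are comparable across features); coefficients are reported on
#' both the standardized and the raw scale, together with R^2 and per-feature
#' Spearman (rho) and Pearson correlations with the response. Invalid
#' records and records without a response are excluded.
#'
#' @param records data frame with feature columns, `response`, and
#'   (optionally) `invalid`.
#' @return object of class `model_fit`: `coefficients` (standardized scale,
#'   intercept first), `raw_coefficients`, `r_squared`, `spearman`,
#'   `pearson`, `n_used`, `se` (standard errors, standardized scale).
#' @export
fit_linear <- function(records) {
  stopifnot(all(GLOSS_FEATURES %in% names(records)),
            "response" %in% names(records))
  ok <- valid_rows(records) & !is.na(records$response)
  n <- sum(ok)
  if (n < 6) stop("need at least 6 valid records to fit")
  x <- as.matrix(records[ok, GLOSS_FEATURES])
  y <- records$response[ok]
  # collinearity guard naming the offending pair
  cc <- suppressWarnings(stats::cor(x))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-10)) {
    bad <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf("features '%s' and '%s' are exactly collinear",
                 GLOSS_FEATURES[bad[1]], GLOSS_FEATURES[bad[2]]))
  }
  std <- standardize_cols(x)
  X <- cbind(`(Intercept)` = 1, std$z)
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) stop("feature matrix is rank deficient")
  beta <- solve(xtx, crossprod(X, y))[, 1]
  fitted <- as.numeric(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  sigma2 <- sse / max(n - length(beta), 1)
  se <- sqrt(diag(solve(xtx)) * sigma2)
  sdv <- ifelse(std$sd > 0, std$sd, 1)
  raw_w <- beta[-1] / sdv
  raw_b0 <- beta[1] - sum(beta[-1] * std$mean / sdv)
  spearman <- vapply(GLOSS_FEATURES, function(f)
    suppressWarnings(stats::cor(x[, f], y, method = "spearman")), 0)
  pearson <- vapply(GLOSS_FEATURES, function(f)
    suppressWarnings(stats::cor(x[, f], y)), 0)
  structure(list(coefficients = beta,
                 raw_coefficients = c(`(Intercept)` = unname(raw_b0), raw_w),
                 r_squared = max(0, min(1, r2)),
                 spearman = spearman, pearson = pearson,
                 n_used = n, se = se),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: n = %d, R^2 = %.4f\n", x$n_used, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Per-subset linear fits
#'
#' Splits the records by the given factor columns and fits the linear model
#' within each level combination (mirroring the all-factors / per-intensity /
#' per-shape / per-spread analysis blocks). Subsets too small (or too
#' degenerate) to fit are recorded as unfittable rather than raising.
#'
#' @param records record data frame.
#' @param split_factors character vector of column names; empty for the
#'   single global fit.
#' @return `data.frame` with one row per subset: the split levels, `n_used`,
#'   `r_squared`, `fitted` flag, standardized weights `w_*`, and the four
#'   Spearman correlations `rho_*`.
#' @export
subset_analysis <- function(records, split_factors = character(0)) {
  groups <- if (length(split_factors) == 0) list(`all` = records)
    else split(records, records[, split_factors, drop = FALSE], drop = TRUE,
               sep = "|")
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    lev <- if (length(split_factors))
      as.data.frame(sub[1, split_factors, drop = FALSE], row.names = NULL)
    else data.frame(subset = "all")
    fit <- tryCatch(fit_linear(sub), error = function(e) NULL)
    if (is.null(fit)) {
      cbind(lev, data.frame(n_used = sum(valid_rows(sub) & !is.na(sub$response)),
                            r_squared = NA_real_, fitted = FALSE,
                            t(stats::setNames(rep(NA_real_, 4),
                                              paste0("w_", GLOSS_FEATURES))),
                            t(stats::setNames(rep(NA_real_, 4),
                                              paste0("rho_", GLOSS_FEATURES)))))
    } else {
      cbind(lev, data.frame(n_used = fit$n_used, r_squared = fit$r_squared,
                            fitted = TRUE,
                            t(stats::setNames(unname(fit$coefficients[-1]),
                                              paste0("w_", GLOSS_FEATURES))),
                            t(stats::setNames(unname(fit$spearman),
                                              paste0("rho_", GLOSS_FEATURES)))))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
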