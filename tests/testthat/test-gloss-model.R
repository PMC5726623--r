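# synthetic feature table shaped like a statistics CSV
fake_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(number = runif(n, 1, 8),
             mean_size = runif(n, 5, 200),
             pct_area = runif(n, 0, 0.3),
             strength = runif(n, 0.3, 0.5),
             invalid = FALSE)
}

test_that("the design grid enumerates the full factorial", {
  d <- enumerate_design()
  expect_equal(nrow(d), 350)
  expect_equal(length(unique(d$shape)), 5)
  expect_equal(length(unique(d$alpha)), 7)
  d4 <- enumerate_design(repetitions = 4)
  expect_equal(nrow(d4), 1400)
  d1 <- enumerate_design(smoothness = 0.4, alpha = 0, shapes = "blob1",
                         intensity = 1.5)
  expect_equal(nrow(d1), 1)
  # deterministic order
  expect_identical(d, enumerate_design())
})

test_that("the synthetic observer is linear, seeded and respects validity", {
  rec <- fake_records(60)
  rec$invalid[1:5] <- TRUE
  pars <- observer_params(intercept = 2, weights = c(0.3, -0.1, -0.6, 0.5),
                          noise_sd = 0, seed = 9)
  out <- synth_observer(rec, pars)
  expect_true(all(is.na(out$response[1:5])))
  expect_false(anyNA(out$response[-(1:5)]))
  # exact linearity at zero noise: refit recovers the weights exactly
  fit <- fit_linear(out)
  expect_equal(unname(fit$coefficients[-1]), c(0.3, -0.1, -0.6, 0.5),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # same seed, same responses; different seed differs
  pars_n <- observer_params(noise_sd = 0.2, seed = 5)
  expect_identical(synth_observer(rec, pars_n)$response,
                   synth_observer(rec, pars_n)$response)
  pars_m <- observer_params(noise_sd = 0.2, seed = 6)
  expect_false(identical(synth_observer(rec, pars_n)$response,
                         synth_observer(rec, pars_m)$response))
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_observer(rec, pars_n)); after <- runif(1)
  expect_identical(before, after)
})

test_that("OLS matches the hand-computed normal equations", {
  rec <- fake_records(12, seed = 3)
  rec$response <- 2 * rec$number  # y = 2x on one feature, others inert
  fit <- fit_linear(rec)
  expect_equal(unname(fit$raw_coefficients["number"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$raw_coefficients["(Intercept)"]), 0,
               tolerance = 1e-8)
  expect_equal(unname(fit$raw_coefficients[c("mean_size", "pct_area",
                                             "strength")]),
               rep(0, 3), tolerance = 1e-8)
  # independent route: solve the raw normal equations directly
  X <- cbind(1, as.matrix(rec[, c("number", "mean_size", "pct_area",
                                  "strength")]))
  beta <- solve(t(X) %*% X, t(X) %*% rec$response)[, 1]
  expect_equal(unname(fit$raw_coefficients), unname(beta), tolerance = 1e-6)
  # R^2 definition against the independent fit
  yhat <- X %*% beta
  r2 <- 1 - sum((rec$response - yhat)^2) /
    sum((rec$response - mean(rec$response))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)
})

test_that("degenerate fits are rejected with informative errors", {
  rec <- fake_records(20)
  rec$response <- rnorm(20)
  rec$mean_size <- 3 * rec$pct_area  # exact collinearity
  expect_error(fit_linear(rec), "mean_size.*pct_area|pct_area.*mean_size")
  few <- fake_records(5)
  few$response <- 1:5
  expect_error(fit_linear(few), "at least 6")
  # constant response: R^2 defined as 0
  rc <- fake_records(30)
  rc$response <- 1
  expect_equal(fit_linear(rc)$r_squared, 0)
})

test_that("R^2 is invariant under affine rescaling of a feature", {
  rec <- fake_records(80, seed = 8)
  rec <- synth_observer(rec, observer_params(noise_sd = 0.3, seed = 2))
  f1 <- fit_linear(rec)
  rec2 <- rec
  rec2$pct_area <- 100 * rec2$pct_area - 7
  f2 <- fit_linear(rec2)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  expect_equal(f2$spearman, f1$spearman, tolerance = 1e-12)
})

test_that("negative pct_area weighting yields a negative rank correlation", {
  rec <- fake_records(120, seed = 10)
  pars <- observer_params(intercept = 0, weights = c(0, 0, -0.8, 0),
                          noise_sd = 0.05, seed = 3)
  fit <- fit_linear(synth_observer(rec, pars))
  expect_lt(fit$spearman[["pct_area"]], 0)
})

test_that("excluding invalid records never increases n_used", {
  rec <- fake_records(50)
  rec <- synth_observer(rec, observer_params(noise_sd = 0.1, seed = 4))
  full <- fit_linear(rec)$n_used
  rec$invalid[1:10] <- TRUE
  expect_lte(fit_linear(rec)$n_used, full)
  expect_equal(fit_linear(rec)$n_used, 40)
})

test_that("subset analysis mirrors the factor blocks", {
  rec <- rbind(cbind(fake_records(60, seed = 20), intensity = 0.5),
               cbind(fake_records(60, seed = 21), intensity = 1.5))
  # two-regime observer: opposite pct_area weight per intensity level
  lo <- synth_observer(rec[rec$intensity == 0.5, ],
                       observer_params(weights = c(0.1, 0, -0.7, 0.2),
                                       noise_sd = 0.05, seed = 1))
  hi <- synth_observer(rec[rec$intensity == 1.5, ],
                       observer_params(weights = c(0.1, 0, 0.7, 0.2),
                                       noise_sd = 0.05, seed = 2))
  rec <- rbind(lo, hi)
  tab <- subset_analysis(rec, "intensity")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$fitted))
  glob <- subset_analysis(rec)
  expect_equal(nrow(glob), 1)
  expect_equal(glob$r_squared, fit_linear(rec)$r_squared)
  # each regime fits better than the pooled model
  expect_true(all(tab$r_squared > glob$r_squared))
  # under-sized subsets are recorded, not fatal
  rec$tiny <- rep(c("a", "b"), c(nrow(rec) - 3, 3))
  tab2 <- subset_analysis(rec, "tiny")
  expect_false(all(tab2$fitted))
  expect_equal(sum(tab2$fitted), 1)
})

test_that("weights are recovered within Monte-Carlo tolerance", {
  rec <- fake_records(296, seed = 30)
  truth <- c(0.25, -0.15, -0.5, 0.4)
  hits <- 0
  for (r in 1:40) {
    out <- synth_observer(rec, observer_params(intercept = 1, weights = truth,
                                               noise_sd = 0.1,
                                               seed = 1000 + r))
    fit <- fit_linear(out)
    w <- fit$coefficients[-1]
    se <- fit$se[-1]
    hits <- hits + all(abs(w - truth) <= 3 * se)
  }
  expect_gte(hits / 40, 0.95)
})
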