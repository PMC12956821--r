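fixture_metadata <- function(n = 300, seed = 50,
                             effects = list(
                               intercept = 1,
                               "object_type.zoomorph_figurine" = 0.4,
                               "object_type.personal_ornament" = -0.3
                             ),
                             noise_sd = 0.2) {
  generate_artifact_metadata(
    metadata_spec(n, effect_map = effects, noise_sd = noise_sd, seed = seed)
  )
}

test_that("the intercept-only model estimates the response mean", {
  md <- fixture_metadata(150, seed = 3)
  fit <- fit_entropy_rate_model(md, entropy_rate ~ 1)
  expect_equal(
    unname(fit$coefficients["(Intercept)", "Estimate"]),
    mean(md$entropy_rate)
  )
  expect_equal(fit$df, 1)
  expect_equal(fit$residual_df, 149)
})

test_that("treatment coding uses the declared reference levels", {
  md <- fixture_metadata(250, seed = 8)
  fit <- fit_entropy_rate_model(md, entropy_rate ~ object_type)
  # intercept is the mean at the reference level "tool"
  expect_equal(
    unname(fit$coefficients["(Intercept)", "Estimate"]),
    mean(md$entropy_rate[md$object_type == "tool"])
  )
  expect_true("object_typezoomorph_figurine" %in% rownames(fit$coefficients))
})

test_that("changing the reference level moves coefficients, not the fit", {
  md <- fixture_metadata(200, seed = 12)
  f1 <- fit_entropy_rate_model(md, entropy_rate ~ object_type + volume)
  md2 <- md
  md2$object_type <- stats::relevel(md2$object_type, "other")
  fit2 <- stats::lm(entropy_rate ~ object_type + volume, data = md2)
  expect_equal(f1$aic, stats::AIC(fit2), tolerance = 1e-9)
  expect_equal(f1$r_squared, summary(fit2)$r.squared, tolerance = 1e-9)
  expect_equal(unname(stats::fitted(f1$fit)), unname(stats::fitted(fit2)),
    tolerance = 1e-9
  )
  expect_false(isTRUE(all.equal(
    f1$coefficients["(Intercept)", "Estimate"],
    stats::coef(fit2)[["(Intercept)"]]
  )))
})

test_that("rank-deficient designs are refused with the collinear term named", {
  md <- fixture_metadata(100, seed = 21)
  md$volume2 <- md$volume
  expect_error(
    fit_entropy_rate_model(md, entropy_rate ~ volume + volume2),
    "volume2"
  )
})

test_that("nested models never lose R2 and AIC penalizes exactly 2 per parameter", {
  md <- fixture_metadata(200, seed = 31)
  rhs <- c("1", "volume", "volume + max_date", "volume + max_date + object_type")
  fits <- lapply(rhs, function(r) {
    fit_entropy_rate_model(md, stats::as.formula(paste("entropy_rate ~", r)))
  })
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # at (essentially) equal likelihood the AIC difference is 2 per parameter:
  # duplicate-information predictors add nothing but the penalty
  set.seed(77)
  md$noise <- stats::rnorm(nrow(md))
  f_base <- fit_entropy_rate_model(md, entropy_rate ~ volume)
  ll_base <- as.numeric(stats::logLik(f_base$fit))
  f_noise <- fit_entropy_rate_model(md, entropy_rate ~ volume + noise)
  ll_noise <- as.numeric(stats::logLik(f_noise$fit))
  expect_equal(
    (f_noise$aic - f_base$aic) + 2 * (ll_noise - ll_base), 2,
    tolerance = 1e-9
  )
})

test_that("the model ladder is built in theoretical order", {
  rhs <- build_model_ladder(
    base_terms = c("volume", "max_date", "object_type"),
    alternative_terms = c("site", "preservation"),
    interaction_terms = c("volume*preservation", "volume*object_type")
  )
  expect_equal(rhs[1:4], c(
    "1", "volume", "volume + max_date",
    "volume + max_date + object_type"
  ))
  expect_true("volume + max_date + object_type + preservation" %in% rhs)
  expect_true("max_date + object_type + volume*preservation" %in% rhs)
  expect_true("max_date + volume*object_type" %in% rhs)
})

test_that("stepwise AIC selects the truly informative term", {
  hits <- vapply(1:50, function(s) {
    md <- fixture_metadata(200, seed = 5000 + s)
    sel <- stepwise_aic_selection(md)
    with_type <- grepl("object_type", sel$ladder$formula)
    # AIC drops when object_type enters the cumulative ladder (row 4 vs 3)
    drop_ok <- sel$ladder$aic[4] < sel$ladder$aic[3]
    drop_ok && grepl("object_type", sel$best_formula)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("coefficient recovery: injected effects fall inside their 95% CIs", {
  truth <- c(
    intercept = 1, "object_type.zoomorph_figurine" = 0.25,
    volume = 0.003
  )
  covered <- vapply(1:50, function(s) {
    md <- generate_artifact_metadata(metadata_spec(
      400,
      effect_map = as.list(truth), noise_sd = 0.2, seed = 7000 + s
    ))
    fit <- fit_entropy_rate_model(md, entropy_rate ~ object_type + volume)
    ci <- stats::confint(fit$fit)
    zf <- ci["object_typezoomorph_figurine", ]
    zf[1] <= 0.25 && 0.25 <= zf[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("all coefficients stay within 3 SE of truth at n = 400", {
  md <- generate_artifact_metadata(metadata_spec(
    400,
    effect_map = list(
      intercept = 1, "object_type.zoomorph_figurine" = 0.25,
      "preservation.fragmented" = -0.15, volume = 0.003
    ),
    noise_sd = 0.2, seed = 314
  ))
  fit <- fit_entropy_rate_model(
    md, entropy_rate ~ object_type + preservation + volume
  )
  co <- fit$coefficients
  truth <- stats::setNames(rep(0, nrow(co)), rownames(co))
  truth["(Intercept)"] <- 1
  truth["object_typezoomorph_figurine"] <- 0.25
  truth["preservationfragmented"] <- -0.15
  truth["volume"] <- 0.003
  z <- abs(co[, "Estimate"] - truth[rownames(co)]) / co[, "Std. Error"]
  expect_true(all(z < 3))
})

test_that("semipartial R2 is the R2 drop and is zero for redundant terms", {
  md <- fixture_metadata(250, seed = 61)
  sp <- semipartial_r2(md, entropy_rate ~ object_type + volume, "object_type",
    n_boot = 200, seed = 1
  )
  full <- summary(stats::lm(entropy_rate ~ object_type + volume, md))$r.squared
  red <- summary(stats::lm(entropy_rate ~ volume, md))$r.squared
  expect_equal(sp$delta_r2, full - red)
  expect_gt(sp$ci[1], 0) # a real effect: lower bound above zero
  expect_equal(sp$ci[2], 1)

  # a term with no injected effect has a near-zero lower bound
  sp0 <- semipartial_r2(md, entropy_rate ~ object_type + max_date, "max_date",
    n_boot = 200, seed = 2
  )
  expect_lt(sp0$delta_r2, 0.05)
  expect_lt(sp0$ci[1], 0.03)
})

test_that("a small volume slope explains a small variance share", {
  md <- generate_artifact_metadata(metadata_spec(
    400,
    effect_map = list(
      intercept = 1, "object_type.zoomorph_figurine" = 0.3, volume = 0.003
    ),
    noise_sd = 0.2, seed = 99
  ))
  sp <- semipartial_r2(md, entropy_rate ~ object_type + volume, "volume",
    n_boot = 100, seed = 3
  )
  expect_lt(sp$delta_r2, 0.05)
})

test_that("diagnostics flag constructed violations and pass clean fits", {
  md <- fixture_metadata(200, seed = 74)
  fit <- fit_entropy_rate_model(md, entropy_rate ~ object_type)
  d <- model_diagnostics(fit)
  expect_false(d$degenerate)
  expect_true(d$normality_ok)

  # inject variance increasing with the fitted value
  md2 <- md
  set.seed(72)
  lp <- attr(md, "linear_predictor")
  md2$entropy_rate <- lp + stats::rnorm(nrow(md2), 0, 0.05 + 0.6 * (lp - min(lp)))
  d2 <- model_diagnostics(fit_entropy_rate_model(md2, entropy_rate ~ object_type))
  expect_false(d2$homoscedastic)

  # zero-noise toy fit is reported as degenerate
  toy <- data.frame(x = 1:20, entropy_rate = 2 + 3 * (1:20))
  toy_fit <- suppressWarnings(fit_entropy_rate_model(toy, entropy_rate ~ x))
  expect_warning(d3 <- model_diagnostics(toy_fit), "degenerate")
  expect_true(d3$degenerate)
})

test_that("normality diagnostics are calibrated on Gaussian residuals", {
  ok <- vapply(1:40, function(s) {
    md <- fixture_metadata(150, seed = 8000 + s)
    d <- model_diagnostics(fit_entropy_rate_model(md, entropy_rate ~ object_type))
    isTRUE(d$normality_ok)
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})
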