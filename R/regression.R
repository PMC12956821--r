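# Linear models predicting a sequence's information density (entropy rate
# by default) from artifact metadata, compared by AIC along a theoretically
# ordered ladder, with semipartial R-squared effect sizes.

#' Coerce artifact metadata factors to their declared reference levels
#'
#' Treatment (dummy) coding is used throughout; the intercept is the mean
#' at the reference levels: tool / antler / Geissenkloesterle /
#' almost_complete.
#'
#' @param data metadata data frame.
#' @return the data with factor columns releveled.
#' @export
as_artifact_factors <- function(data) {
  for (nm in names(artifact_levels)) {
    if (nm %in% names(data)) {
      lv <- artifact_levels[[nm]]
      present <- unique(as.character(data[[nm]]))
      levels_use <- c(
        intersect(lv, present),
        setdiff(present, lv)
      )
      data[[nm]] <- factor(as.character(data[[nm]]), levels = levels_use)
    }
  }
  data
}

#' Fit a linear model for a sequence statistic
#'
#' Ordinary least squares with treatment-coded factors. Rows with missing
#' values in the model variables are dropped listwise with a message.
#'
#' @param data joined features + metadata data frame.
#' @param formula model formula; the response defaults to `entropy_rate`
#'   but any feature column can be used.
#' @return object of class `sign_model`: the `lm` fit plus `coefficients`
#'   (estimate, SE, t, p), `aic`, `f_stat`, `df`, `residual_df`,
#'   `r_squared`, `n`.
#' @export
fit_entropy_rate_model <- function(data, formula = entropy_rate ~ 1) {
  data <- as_artifact_factors(data)
  vars <- all.vars(formula)
  vars <- intersect(vars, names(data))
  complete <- stats::complete.cases(data[vars])
  if (any(!complete)) {
    message(sum(!complete), " row(s) with missing values dropped")
    data <- data[complete, , drop = FALSE]
  }
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(
      "rank-deficient model; collinear term(s): ",
      paste(bad, collapse = ", ")
    )
  }
  p <- length(stats::coef(fit))
  n <- nrow(data)
  if (n < p + 2) stop("need at least 2 more rows than parameters")
  sm <- summary(fit)
  f_stat <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
  f_p <- if (is.null(sm$fstatistic)) {
    NA_real_
  } else {
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
      lower.tail = FALSE
    )
  }
  structure(
    list(
      fit = fit,
      formula = formula,
      coefficients = stats::coef(sm),
      aic = stats::AIC(fit),
      f_stat = f_stat,
      f_p = f_p,
      df = p,
      residual_df = fit$df.residual,
      r_squared = sm$r.squared,
      residuals = stats::residuals(fit),
      n = n
    ),
    class = "sign_model"
  )
}

#' @export
print.sign_model <- function(x, ...) {
  cat(sprintf(
    "<sign_model> %s\n  n = %d, df = %d, AIC = %.1f, F = %.2f (res. df %d), R2 = %.3f\n",
    deparse(x$formula), x$n, x$df, x$aic, x$f_stat, x$residual_df,
    x$r_squared
  ))
  invisible(x)
}

#' Build the theoretically ordered model ladder
#'
#' Constructs right-hand-side specifications: the intercept-only baseline,
#' then the base terms added cumulatively one at a time, then each
#' alternative term appended to the full base, then each interaction
#' specification (`"a*b"` strings, expanding to main effects plus
#' interaction) combined with the remaining base terms.
#'
#' @param base_terms terms added cumulatively, in theoretical order.
#' @param alternative_terms each appended (alone) to the full base.
#' @param interaction_terms `"a*b"` strings; base terms already implied by
#'   the interaction are not repeated.
#' @return character vector of RHS formulas, starting with `"1"`.
#' @export
build_model_ladder <- function(base_terms = c("volume", "max_date", "object_type"),
                               alternative_terms = c("site", "preservation", "material"),
                               interaction_terms = character(0)) {
  rhs <- "1"
  for (i in seq_along(base_terms)) {
    rhs <- c(rhs, paste(base_terms[seq_len(i)], collapse = " + "))
  }
  for (a in alternative_terms) {
    rhs <- c(rhs, paste(c(base_terms, a), collapse = " + "))
  }
  for (ia in interaction_terms) {
    parts <- strsplit(ia, "*", fixed = TRUE)[[1]]
    rest <- setdiff(base_terms, parts)
    rhs <- c(rhs, paste(c(rest, ia), collapse = " + "))
  }
  rhs
}

#' Stepwise AIC model comparison
#'
#' Fits every model of the ladder (see [build_model_ladder()]) and ranks
#' them by AIC, lower preferred. The full ladder is reported; the best
#' model is the AIC minimum.
#'
#' @param data joined features + metadata data frame.
#' @param response name of the response column (default `"entropy_rate"`).
#' @param base_terms,alternative_terms,interaction_terms see
#'   [build_model_ladder()]; alternatively supply `ladder` directly.
#' @param ladder optional explicit character vector of RHS specifications.
#' @return list with `ladder` (data frame: formula, df, residual_df, f, p,
#'   aic, delta_aic), `fits` (list of `sign_model`), `best` (the minimum-AIC
#'   `sign_model`), `best_formula`.
#' @export
stepwise_aic_selection <- function(data, response = "entropy_rate",
                                   base_terms = c("volume", "max_date", "object_type"),
                                   alternative_terms = c("site", "preservation", "material"),
                                   interaction_terms = character(0),
                                   ladder = NULL) {
  if (is.null(ladder)) {
    ladder <- build_model_ladder(base_terms, alternative_terms, interaction_terms)
  }
  fits <- lapply(ladder, function(rhs) {
    fit_entropy_rate_model(
      data,
      stats::as.formula(paste(response, "~", rhs))
    )
  })
  tab <- data.frame(
    formula = paste("Intercept", ifelse(ladder == "1", "", paste("+", ladder))),
    df = vapply(fits, function(f) f$df, numeric(1)),
    residual_df = vapply(fits, function(f) f$residual_df, numeric(1)),
    f = vapply(fits, function(f) f$f_stat, numeric(1)),
    p = vapply(fits, function(f) f$f_p, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$formula <- trimws(tab$formula)
  tab$delta_aic <- tab$aic - min(tab$aic)
  best <- which.min(tab$aic)
  list(
    ladder = tab, fits = fits, best = fits[[best]],
    best_formula = tab$formula[best]
  )
}

#' Semipartial R-squared of one model term
#'
#' The drop in R-squared when `dropped_term` is removed from the full
#' model — the effect-size measure for a predictor's unique contribution.
#' Uncertainty is assessed by a nonparametric bootstrap over rows; the
#' interval is one-sided, `[lower 5th percentile, 1]`.
#'
#' @param data joined features + metadata data frame.
#' @param full_formula full model formula.
#' @param dropped_term term to remove (as it appears in the formula).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level of the one-sided bound.
#' @return list with `delta_r2`, `ci` (`c(lower, 1)`), and `boot` (the
#'   bootstrap draws).
#' @export
semipartial_r2 <- function(data, full_formula, dropped_term,
                           n_boot = 1000, seed = 1, conf = 0.95) {
  reduced <- stats::update(full_formula, paste("~ . -", dropped_term))
  data <- as_artifact_factors(data)
  vars <- intersect(all.vars(full_formula), names(data))
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  dr2 <- function(d) {
    r_full <- summary(stats::lm(full_formula, data = d))$r.squared
    r_red <- summary(stats::lm(reduced, data = d))$r.squared
    max(0, r_full - r_red)
  }
  observed <- dr2(data)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(data), replace = TRUE)
      tryCatch(dr2(data[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  lower <- unname(stats::quantile(boot, 1 - conf))
  list(delta_r2 = observed, ci = c(lower, 1), boot = boot)
}

#' Residual diagnostics for a fitted model
#'
#' Checks the assumptions behind the Gaussian linear model: Shapiro-Wilk
#' for residual normality, Breusch-Pagan for homoscedasticity, and the
#' correlation of absolute residuals with fitted values. All checks are
#' flags, never hard failures; near-zero residual variance raises a
#' degenerate-residual flag instead of testing.
#'
#' @param model a `sign_model`.
#' @param alpha flag threshold for the tests.
#' @return list with the test statistics/p-values and logical flags
#'   `normality_ok`, `homoscedastic`, `degenerate`.
#' @export
model_diagnostics <- function(model, alpha = 0.05) {
  res <- model$residuals
  if (stats::sd(res) < 1e-10) {
    warning("residual variance is (near) zero: degenerate fit")
    return(list(
      degenerate = TRUE, normality_ok = NA, homoscedastic = NA,
      shapiro_p = NA_real_, bp_p = NA_real_, abs_resid_fitted_cor = NA_real_
    ))
  }
  sh <- stats::shapiro.test(res)
  # Breusch-Pagan needs at least one regressor; an intercept-only model has
  # nothing to be heteroscedastic against
  bp <- if (model$df > 1) lmtest::bptest(model$fit) else NULL
  rf <- stats::cor(abs(res), stats::fitted(model$fit))
  list(
    degenerate = FALSE,
    shapiro_w = unname(sh$statistic),
    shapiro_p = sh$p.value,
    bp_stat = if (is.null(bp)) NA_real_ else unname(bp$statistic),
    bp_p = if (is.null(bp)) NA_real_ else bp$p.value,
    abs_resid_fitted_cor = rf,
    normality_ok = sh$p.value > alpha,
    homoscedastic = if (is.null(bp)) NA else bp$p.value > alpha
  )
}
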