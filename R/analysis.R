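#' Count GLMs for lethal acute toxicosis
#'
#' Fits a generalized linear model with log link to a nonnegative-integer
#' response, with either a negative-binomial distribution (dispersion
#' estimated by maximum likelihood) or a Poisson distribution. The number of
#' estimated parameters counts the negative-binomial dispersion, so
#' information criteria are comparable across the two families.
#'
#' @param table data.frame of run summaries (one row per run).
#' @param response name of the count response column.
#' @param terms character vector of predictor columns.
#' @param family `"negative_binomial"` (default) or `"poisson"`.
#' @param interaction include all pairwise interactions of `terms`.
#' @return an object of class `graztox_glm`.
#' @export
fit_count_glm <- function(table, response, terms,
                          family = c("negative_binomial", "poisson"),
                          interaction = FALSE) {
  family <- match.arg(family)
  y <- table[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be nonnegative integers", call. = FALSE)
  form <- count_formula(response, terms, interaction)
  fit <- if (family == "negative_binomial") {
    tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = table)),
      error = function(e) stop("negative-binomial fit failed to converge: ",
                               conditionMessage(e), call. = FALSE))
  } else {
    stats::glm(form, data = table, family = stats::poisson(link = "log"))
  }
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as_graztox_glm(fit, family)
}

count_formula <- function(response, terms, interaction) {
  rhs <- if (interaction && length(terms) > 1)
    paste0("(", paste(terms, collapse = " + "), ")^2")
  else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

as_graztox_glm <- function(fit, family, extra = list()) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  cf <- summary(fit)$coefficients
  pcol <- grep("^Pr\\(", colnames(cf))
  coefs <- data.frame(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    p_value = if (length(pcol)) cf[, pcol[1]] else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  obj <- c(list(
    family = family, link = "log",
    coefficients = coefs,
    theta = if (family == "negative_binomial") fit$theta else NA_real_,
    log_lik = as.numeric(ll), k = k, n = n,
    aic = stats::AIC(fit),
    aicc = aicc(stats::AIC(fit), k = k, n = n),
    deviance = stats::deviance(fit),
    df_residual = stats::df.residual(fit),
    fit = fit
  ), extra)
  class(obj) <- "graztox_glm"
  obj
}

#' @export
print.graztox_glm <- function(x, ...) {
  cat(sprintf("%s GLM (%s link), n = %d\n", x$family, x$link, x$n))
  print(x$coefficients, digits = 4)
  if (!is.na(x$theta)) cat(sprintf("theta = %.3f\n", x$theta))
  cat(sprintf("logLik = %.2f (k = %d), AIC = %.1f, AICc = %.1f\n",
              x$log_lik, x$k, x$aic, x$aicc))
  cat(sprintf("residual deviance = %.2f on %d degrees of freedom\n",
              x$deviance, x$df_residual))
  if (!is.null(x$adj_r_squared))
    cat(sprintf("adjusted R^2 = %.3f\n", x$adj_r_squared))
  invisible(x)
}

#' @export
coef.graztox_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.graztox_glm <- function(object, ...) object$coefficients

#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)` where `k` counts every estimated
#' parameter (including a negative-binomial dispersion or a Gaussian error
#' variance).
#'
#' @param object a `graztox_glm`, any model with `logLik`/`nobs` methods, or
#'   a plain AIC value (then supply `k` and `n`).
#' @param k,n parameter count and sample size (only for a numeric `object`).
#' @param ... unused.
#' @return the corrected criterion.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.numeric <- function(object, k, n, ...) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  object + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aicc.graztox_glm <- function(object, ...) object$aicc

#' @rdname aicc
#' @export
aicc.default <- function(object, ...) {
  ll <- stats::logLik(object)
  aicc.numeric(stats::AIC(object), k = attr(ll, "df"),
               n = stats::nobs(object))
}

#' Percent change implied by a log-link coefficient
#'
#' For a log-link model a coefficient `b` multiplies the expected count by
#' `exp(b)` per unit predictor; this transform reports that as
#' `100 * (1 - exp(b))`, so a negative coefficient reads as a positive
#' percent decrease (and an increase comes out negative).
#'
#' @param coef log-link coefficient.
#' @return percent decrease in the expected count per unit predictor.
#' @export
percent_change <- function(coef) {
  100 * (1 - exp(coef))
}

#' Standardized coefficients and relative influence
#'
#' Refits the main-effects-only model with z-scored predictors (mean 0,
#' population standard deviation 1) so coefficient magnitudes are comparable
#' across predictors, and reports the pairwise influence ratios
#' `|beta_a / beta_b|`.
#'
#' @param table data.frame of runs.
#' @param response response column name.
#' @param terms predictor column names.
#' @param family `"negative_binomial"`, `"poisson"` or `"gaussian"`.
#' @return list with `betas` (named vector) and `influence_ratio` (matrix of
#'   `|beta_row / beta_col|`).
#' @export
standardized_betas <- function(table, response, terms,
                               family = c("negative_binomial", "poisson",
                                          "gaussian")) {
  family <- match.arg(family)
  zt <- table
  for (tm in terms) {
    v <- table[[tm]]
    s <- pop_sd(v)
    if (s == 0) stop("constant predictor: ", tm, call. = FALSE)
    zt[[tm]] <- (v - mean(v)) / s
  }
  form <- count_formula(response, terms, interaction = FALSE)
  fit <- switch(family,
    negative_binomial = suppressWarnings(MASS::glm.nb(form, data = zt)),
    poisson = stats::glm(form, data = zt,
                         family = stats::poisson(link = "log")),
    gaussian = stats::lm(form, data = zt))
  b <- stats::coef(fit)[terms]
  ratio <- abs(outer(b, b, "/"))
  dimnames(ratio) <- list(terms, terms)
  list(betas = b, influence_ratio = ratio)
}

#' Mechanism regressions (ordinary least squares)
#'
#' Multiple linear regression of a mechanism variable on the experimental
#' factors, with an optional interaction. Standardized betas are taken from
#' the same model without the interaction.
#'
#' @param table data.frame of runs.
#' @param response numeric response column name.
#' @param terms predictor column names.
#' @param interaction include pairwise interactions.
#' @return a `graztox_glm` (Gaussian family) with `adj_r_squared` and
#'   `betas` elements.
#' @export
fit_mechanism_ols <- function(table, response, terms, interaction = FALSE) {
  form <- count_formula(response, terms, interaction)
  fit <- stats::lm(form, data = table)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sb <- standardized_betas(table, response, terms, family = "gaussian")
  as_graztox_glm(fit, "gaussian",
                 extra = list(adj_r_squared = summary(fit)$adj.r.squared,
                              betas = sb$betas))
}

#' Single-factor mechanism screen
#'
#' For each candidate mechanism variable, fits the single-factor
#' negative-binomial GLM of the death count, and reports AICc, the
#' coefficient, the first and third sample quartiles of the mechanism
#' (linear-interpolation quantiles), and the observed percent change in mean
#' deaths between the runs in the bottom quartile group (mechanism <= Q1) and
#' those in the top quartile group (mechanism >= Q3). Rows are sorted by
#' ascending AICc (best-supported mechanism first).
#'
#' @param table data.frame of runs.
#' @param response count response column name.
#' @param mechanisms character vector of mechanism column names.
#' @return data.frame with one row per (non-constant) mechanism.
#' @export
single_factor_scan <- function(table, response, mechanisms) {
  if (nrow(table) < 8) stop("need at least 8 rows", call. = FALSE)
  rows <- lapply(mechanisms, function(mech) {
    v <- table[[mech]]
    if (is.null(v)) stop("mechanism column '", mech, "' not found",
                         call. = FALSE)
    if (pop_sd(v) == 0) {
      warning("mechanism '", mech, "' is constant; skipped", call. = FALSE)
      return(NULL)
    }
    fit <- fit_count_glm(table, response, mech,
                         family = "negative_binomial")
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    m1 <- mean(table[[response]][v <= q[1]])
    m3 <- mean(table[[response]][v >= q[2]])
    pct <- if (m1 > 0) 100 * (m3 - m1) / m1 else NA_real_
    data.frame(mechanism = mech, aicc = fit$aicc,
               coefficient = fit$coefficients$estimate[2],
               q1 = q[1], q3 = q[2], pct_change_deaths = pct,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mechanism = character(0), aicc = numeric(0),
                      coefficient = numeric(0), q1 = numeric(0),
                      q3 = numeric(0), pct_change_deaths = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  out
}
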