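#' Fit a Poisson encoding model for one neuron
#'
#' Maximum-likelihood Poisson regression (log link) of a neuron's window
#' spike counts on word feature regressors, via iteratively reweighted
#' least squares. The returned fit carries everything the downstream
#' statistics need: coefficients and their covariance, fitted means, the
#' maximized log-likelihood, the deviance and the parameter count.
#'
#' @param y Non-negative integer counts, one per word.
#' @param X Design matrix (rows = words) including an intercept column.
#' @return Object of class `poisson_fit`.
#' @export
#' @examples
#' y <- rpois(50, 2)
#' f <- fit_poisson_glm(y, cbind(`(Intercept)` = rep(1, 50)))
#' coef(f)[1] - log(mean(y))  # ~ 0
fit_poisson_glm <- function(y, X) {
  X <- as.matrix(X)
  assert_that(nrow(X) == length(y), "rows(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
                 paste(bad, collapse = ", ")),
          class = "phonopop_rank_deficient")
  }

  fit <- suppressWarnings(glm.fit(X, y, family = poisson()))
  if (!fit$converged) {
    abort("Poisson GLM did not converge", class = "phonopop_no_convergence")
  }
  mu <- fit$fitted.values
  llf <- sum(dpois(y, mu, log = TRUE))
  p <- ncol(X)
  # unscaled covariance of the MLE from the weighted QR decomposition
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  dimnames(covmat) <- list(colnames(X), colnames(X))

  structure(
    list(coefficients = fit$coefficients, vcov = covmat, fitted = mu,
         y = y, llf = llf, k = p, deviance = fit$deviance,
         null_deviance = fit$null.deviance, converged = fit$converged,
         nobs = length(y)),
    class = "poisson_fit"
  )
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("<poisson_fit> k =", x$k, "| llf =", format(x$llf, digits = 6),
      "| deviance =", format(x$deviance, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' @rdname fit_poisson_glm
#' @param x,object A `poisson_fit`.
#' @param ... Unused.
#' @method tidy poisson_fit
#' @export
tidy.poisson_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std.error = unname(se), statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @rdname fit_poisson_glm
#' @method glance poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble(k = x$k, logLik = x$llf, AIC = model_aic(x),
         deviance = x$deviance, nobs = x$nobs, converged = x$converged)
}

#' Akaike information criterion of a fitted encoding model
#'
#' `AIC = 2k - 2 ln(L)` with `k` the number of estimated parameters and
#' `L` the maximized likelihood.
#'
#' @param fit A `poisson_fit`.
#' @return Numeric AIC.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "poisson_fit"))
  2 * fit$k - 2 * fit$llf
}

#' Deviance-based D-squared of a nested model pair
#'
#' Generalisation of R-squared to exponential-family models:
#' `D2 = 1 - K(y, mu_full) / K(y, mu_restricted)` with
#' `K(y, mu) = 2 llf(y; y) - 2 llf(mu; y)` the model deviance. D-squared is
#' the proportional reduction in uncertainty attributable to the regressors
#' of interest, and lies in `[0, 1]` for nested maximum-likelihood fits.
#'
#' @param full,restricted `poisson_fit`s of nested models on the same
#'   counts (the restricted model omits the regressors of interest).
#' @return Numeric in `[0, 1]`, or `NA` (with attribute
#'   `reason = "restricted_saturated"`) when the restricted deviance is 0.
#' @export
d_squared <- function(full, restricted) {
  stopifnot(inherits(full, "poisson_fit"), inherits(restricted, "poisson_fit"))
  assert_that(identical(length(full$y), length(restricted$y)) &&
                all(full$y == restricted$y),
              "fits must share the same outcomes")
  if (restricted$deviance <= .Machine$double.eps^0.5) {
    out <- NA_real_
    attr(out, "reason") <- "restricted_saturated"
    return(out)
  }
  val <- 1 - full$deviance / restricted$deviance
  # numerical floor: nested MLE guarantees the ratio <= 1 up to solver noise
  min(max(val, 0), 1)
}

#' Likelihood-ratio test of nested Poisson fits
#'
#' `stat = 2 (llf_full - llf_restricted)` compared against the chi-squared
#' distribution with `df = k_full - k_restricted`. A neuron is called tuned
#' to a feature family when this test on the family's regressors is
#' significant at `alpha` (default 0.01).
#'
#' @param full,restricted Nested `poisson_fit`s on the same counts.
#' @param alpha Significance level.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `significant`.
#' @export
likelihood_ratio_test <- function(full, restricted, alpha = 0.01) {
  stopifnot(inherits(full, "poisson_fit"), inherits(restricted, "poisson_fit"))
  assert_that(all(full$y == restricted$y), "fits must share the same outcomes")
  df <- full$k - restricted$k
  if (df <= 0) {
    abort("models are not nested (k_full <= k_restricted)",
          class = "phonopop_not_nested")
  }
  stat <- max(0, 2 * (full$llf - restricted$llf))
  p <- pchisq(stat, df, lower.tail = FALSE)
  tibble(statistic = stat, df = df, p.value = p, significant = p < alpha)
}

#' Per-dimension Wald selectivity
#'
#' Two-sided Wald test for each coefficient of a feature family, Bonferroni
#' corrected across the family's categories. Used to call a neuron
#' selectively tuned to individual phoneme groups, syllable templates or
#' morphology flags.
#'
#' @param fit A `poisson_fit`.
#' @param family_terms Names (or indices) of the family's coefficients;
#'   the Bonferroni factor is their number.
#' @param alpha Family-wise level (default 0.01).
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `p.adjusted`, `tuned`.
#' @export
wald_selectivity <- function(fit, family_terms, alpha = 0.01) {
  stopifnot(inherits(fit, "poisson_fit"))
  se2 <- diag(fit$vcov)
  if (any(!is.finite(se2)) || any(se2 <= 0)) {
    abort("singular coefficient covariance", class = "phonopop_singular_vcov")
  }
  if (is.numeric(family_terms)) {
    family_terms <- names(fit$coefficients)[family_terms]
  }
  assert_that(all(family_terms %in% names(fit$coefficients)),
              "unknown family terms")
  est <- fit$coefficients[family_terms]
  se <- sqrt(se2[family_terms])
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  m <- length(family_terms)
  tibble(
    term = family_terms, estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(p),
    p.adjusted = pmin(unname(p) * m, 1),
    tuned = pmin(unname(p) * m, 1) < alpha
  )
}

#' Preferred composition of a tuned neuron
#'
#' The element-wise sign of the family coefficients: the word composition
#' expected to produce the neuron's maximal response carries each
#' positively weighted feature and omits each negatively weighted one. A
#' zero coefficient stays 0 (unconstrained position).
#'
#' @param fit A `poisson_fit`.
#' @param exclude Coefficient names to drop (intercept and nuisance
#'   covariates).
#' @param threshold_insignificant Zero out coefficients whose two-sided
#'   Wald p-value exceeds `alpha` (off by default).
#' @param alpha Level used when thresholding.
#' @return Named integer vector with entries in `{-1, 0, 1}`.
#' @export
preferred_composition <- function(fit, exclude = "(Intercept)",
                                  threshold_insignificant = FALSE,
                                  alpha = 0.01) {
  stopifnot(inherits(fit, "poisson_fit"))
  keep <- setdiff(names(fit$coefficients), exclude)
  b <- fit$coefficients[keep]
  if (threshold_insignificant) {
    se <- sqrt(diag(fit$vcov))[keep]
    p <- 2 * pnorm(-abs(b / se))
    b[p >= alpha] <- 0
  }
  out <- as.integer(sign(b))
  names(out) <- keep
  out
}
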