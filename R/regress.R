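#' Ordinary least squares with explicit coefficient covariance
#'
#' Minimal OLS engine used by all the cost-effectiveness regressions.  The
#' solve goes through a QR (orthogonal) decomposition rather than the normal
#' equations, so rank deficiency is detected reliably and the offending
#' columns can be named.  Classical homoskedastic standard errors and
#' two-sided p-values from the central t distribution with `n - p` degrees
#' of freedom, matching the inferential machinery of a plain `lm()` fit.
#'
#' @param outcome numeric response vector.
#' @param design numeric design matrix with named columns (including the
#'   intercept column if one is wanted).
#' @param outcome_name label carried on the fit.
#' @param robust if `TRUE`, replace the classical covariance with the HC1
#'   sandwich estimator (heteroskedasticity-consistent); off by default.
#' @return An object of class `nb_linear_fit`: coefficients, standard errors,
#'   the full coefficient covariance matrix, residual variance, residual
#'   degrees of freedom, two-sided p-values, residuals and fitted values.
#' @export
fit_ols <- function(outcome, design, outcome_name = "outcome", robust = FALSE) {
  y <- as.numeric(outcome)
  X <- as.matrix(design)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design and outcome sizes differ", call. = FALSE)
  if (n - p < 1)
    stop("insufficient data: ", n, " rows for ", p,
         " coefficients leaves no residual degrees of freedom", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("singular design: column(s) ", paste(dropped, collapse = ", "),
         " are collinear with earlier columns", call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df <- n - p
  rss <- sum(resid^2)
  s2 <- rss / df
  # (X'X)^{-1} from the R factor; unpivot in case qr() permuted columns
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  unpiv <- order(qrx$pivot[seq_len(p)])
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  if (robust) {
    meat <- crossprod(X * resid)            # X' diag(e^2) X
    vc <- xtx_inv %*% meat %*% xtx_inv * n / df
  } else {
    vc <- s2 * xtx_inv
  }
  se <- sqrt(pmax(diag(vc), 0))
  tval <- ifelse(se > 0, coefs / se, ifelse(coefs == 0, 0, Inf * sign(coefs)))
  pval <- ifelse(is.finite(tval), 2 * stats::pt(-abs(tval), df),
                 0)                          # zero residual variance, nonzero coef
  pval[se == 0 & coefs == 0] <- 1
  structure(
    list(outcome_name = outcome_name,
         coefficient_names = colnames(X),
         coefficients = stats::setNames(coefs, colnames(X)),
         standard_errors = stats::setNames(se, colnames(X)),
         coef_covariance = vc,
         residual_variance = s2,
         df_resid = df,
         p_two_sided = stats::setNames(pval, colnames(X)),
         n = n,
         residuals = resid,
         fitted = fitted,
         xtx_inv = xtx_inv,
         robust = robust),
    class = "nb_linear_fit"
  )
}

#' @export
print.nb_linear_fit <- function(x, ...) {
  cat("OLS fit of", x$outcome_name, "(n =", x$n,
      ", df =", x$df_resid, ")\n")
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    p = x$p_two_sided)
  print(round(tab, 6))
  invisible(x)
}

#' @export
coef.nb_linear_fit <- function(object, ...) object$coefficients

#' @export
vcov.nb_linear_fit <- function(object, ...) object$coef_covariance

#' Build the regression design matrix for a dataset
#'
#' Intercept, treatment indicator, then dummy-coded covariates (reference
#' level = first appearance in the data).  Optionally a subgroup dummy plus
#' the treatment-by-subgroup interaction column used by the interaction
#' models.
#'
#' @keywords internal
build_design <- function(ds, covariates = NULL, subgroup = NULL,
                         interaction = FALSE) {
  n <- length(ds$tx)
  cols <- list("(Intercept)" = rep(1, n), tx = ds$tx)
  add_covariate <- function(cols, nm) {
    sch <- ds$covariate_schema[[nm]]
    if (is.null(sch))
      stop("unknown covariate: ", nm, call. = FALSE)
    x <- ds$covariates[[nm]]
    if (sch$type == "numeric") {
      cols[[nm]] <- as.numeric(x)
    } else {
      lev <- sch$levels
      if (length(lev) < 2)
        stop("covariate '", nm, "' has a single level", call. = FALSE)
      for (l in lev[-1]) cols[[paste0(nm, l)]] <- as.numeric(x == l)
    }
    cols
  }
  for (nm in covariates %||% character()) {
    if (!is.null(subgroup) && nm == subgroup) next
    cols <- add_covariate(cols, nm)
  }
  if (!is.null(subgroup)) {
    sch <- ds$covariate_schema[[subgroup]]
    if (is.null(sch)) stop("unknown subgroup covariate: ", subgroup, call. = FALSE)
    if (sch$type != "numeric" && length(sch$levels) < 2)
      stop("subgroup '", subgroup, "' has a single level", call. = FALSE)
    cols <- add_covariate(cols, subgroup)
    if (interaction) {
      if (sch$type == "numeric") {
        cols[[paste0("tx:", subgroup)]] <- ds$tx * as.numeric(ds$covariates[[subgroup]])
      } else {
        for (l in sch$levels[-1]) {
          g <- as.numeric(ds$covariates[[subgroup]] == l)
          cols[[paste0("tx:", subgroup, l)]] <- ds$tx * g
        }
      }
    }
  }
  do.call(cbind, cols)
}

#' Cost regression on the treatment indicator
#'
#' OLS of per-patient cost on the treatment indicator (plus optional
#' covariates).  The `tx` coefficient is the incremental cost estimate
#' \eqn{\Delta C}; with no covariates it equals the difference of arm mean
#' costs exactly.
#'
#' @param ds a [ce_dataset].
#' @param covariates character vector of covariate names to adjust for.
#' @param robust use HC1 sandwich standard errors.
#' @return An `nb_linear_fit`.
#' @export
fit_cost <- function(ds, covariates = NULL, robust = FALSE) {
  stopifnot(inherits(ds, "ce_dataset"))
  fit_ols(ds$cost, build_design(ds, covariates), "cost", robust = robust)
}

#' Effect regression on the treatment indicator
#'
#' As [fit_cost()] with the effect (QALY) outcome; the `tx` coefficient is
#' the incremental effect estimate \eqn{\Delta E}.
#'
#' @inheritParams fit_cost
#' @return An `nb_linear_fit`.
#' @export
fit_effect <- function(ds, covariates = NULL, robust = FALSE) {
  stopifnot(inherits(ds, "ce_dataset"))
  fit_ols(ds$effect, build_design(ds, covariates), "effect", robust = robust)
}

#' Per-patient net benefit at a willingness-to-pay threshold
#'
#' Each patient's net benefit is the monetary value of their health effect at
#' the stated willingness to pay, minus their cost:
#' \eqn{NB_i = \lambda e_i - c_i}.
#'
#' @param ds a [ce_dataset].
#' @param wtp willingness to pay per effect unit (dollars/QALY); must be
#'   non-negative.
#' @return An object of class `nb_vector`: the WTP and the per-patient net
#'   benefits in dataset row order.
#' @export
compute_nb <- function(ds, wtp) {
  stopifnot(inherits(ds, "ce_dataset"))
  if (!is.finite(wtp) || wtp < 0)
    stop("wtp must be a finite non-negative number", call. = FALSE)
  structure(list(wtp = wtp, values = wtp * ds$effect - ds$cost),
            class = "nb_vector")
}

#' Net benefit regression at one willingness-to-pay value
#'
#' Regresses per-patient net benefit on the treatment indicator (and
#' optional covariates).  The `tx` coefficient is the incremental net benefit
#' (INB) at this WTP, and its confidence interval is the INB confidence
#' interval.  The covariate list should match the one used for the cost and
#' effect fits so that the identity
#' \eqn{b_{NB} = \lambda b_E - b_C} holds coefficient-by-coefficient.
#'
#' @inheritParams fit_cost
#' @param wtp willingness to pay (dollars/QALY), non-negative.
#' @return An `nb_linear_fit` with an additional `wtp` element.
#' @export
fit_nb <- function(ds, wtp, covariates = NULL, robust = FALSE) {
  nb <- compute_nb(ds, wtp)
  fit <- fit_ols(nb$values, build_design(ds, covariates),
                 sprintf("net benefit (WTP = %s)", format(wtp, big.mark = ",")),
                 robust = robust)
  fit$wtp <- wtp
  fit
}
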