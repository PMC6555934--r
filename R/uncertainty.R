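#' Probability of cost-effectiveness from a net benefit fit
#'
#' Converts the two-sided p-value of the treatment coefficient in a net
#' benefit regression to the one-sided probability that the new treatment is
#' cost-effective (INB > 0) at that WTP: `1 - p/2` when the INB estimate is
#' positive, `p/2` when negative, and 0.5 at an exact zero.  Plotting this
#' across a WTP grid yields the parametric cost-effectiveness acceptability
#' curve.
#'
#' @param fit an `nb_linear_fit` from [fit_nb()].
#' @return Probability in \[0, 1\].
#' @export
prob_ce_parametric <- function(fit) {
  stopifnot(inherits(fit, "nb_linear_fit"))
  b <- unname(fit$coefficients["tx"])
  p2 <- unname(fit$p_two_sided["tx"])
  if (b > 0) 1 - p2 / 2 else if (b < 0) p2 / 2 else 0.5
}

new_ceac_curve <- function(grid, prob_ce, method, ...) {
  structure(c(list(grid = grid, prob_ce = prob_ce, method = method),
              list(...)),
            class = "ceac_curve")
}

#' @export
as.data.frame.ceac_curve <- function(x, ...) {
  data.frame(wtp = x$grid, prob_ce = x$prob_ce, method = x$method)
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat(sprintf("CEAC (%s, %d WTP points)\n", x$method, length(x$grid)))
  print(utils::head(as.data.frame(x), 12))
  invisible(x)
}

#' @export
plot.ceac_curve <- function(x, ...) {
  graphics::plot(x$grid, x$prob_ce, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Willingness to pay ($/QALY)",
                 ylab = "Probability cost-effective", ...)
  graphics::abline(h = c(0.5, 0.95), lty = 3, col = "grey60")
  invisible(x)
}

#' Parametric cost-effectiveness acceptability curve
#'
#' One net benefit regression per WTP grid point, each converted to a
#' one-sided probability with [prob_ce_parametric()].
#'
#' @param ds a [ce_dataset].
#' @param grid WTP grid (non-negative, increasing).
#' @param covariates covariates shared across fits.
#' @return A `ceac_curve` with `method = "parametric"`.
#' @export
ceac_parametric <- function(ds, grid = default_wtp_grid(), covariates = NULL) {
  prob <- vapply(grid, function(l) prob_ce_parametric(fit_nb(ds, l, covariates)), 0)
  new_ceac_curve(grid, prob, "parametric", covariates_used = covariates %||% character())
}

#' Nonparametric bootstrap of the incremental estimates
#'
#' Resamples patients with replacement within each treatment arm (preserving
#' the randomised arm sizes) and records the incremental cost and effect of
#' every replicate — by arm-mean differences when unadjusted, by refitting
#' the shared-design regressions when covariates are given.  Replicates in
#' which both outcomes are constant within both arms are retained and
#' flagged, never redrawn, so the resampling distribution is untouched.
#'
#' All randomness is scoped to an explicit integer seed under the
#' Mersenne-Twister/Inversion/Rejection generator; the caller's RNG state is
#' left untouched and the same seed reproduces the replicates bit-exactly.
#'
#' @param ds a [ce_dataset].
#' @param B number of replicates (>= 1).
#' @param seed integer seed (required).
#' @param covariates optional covariates; triggers per-replicate refits.
#' @return An object of class `nb_bootstrap`: `B`, `seed`,
#'   `delta_cost_reps`, `delta_effect_reps`, `degenerate` (logical flags),
#'   `stratified = TRUE`, `adjusted`.
#' @export
bootstrap_replicates <- function(ds, B, seed, covariates = NULL) {
  stopifnot(inherits(ds, "ce_dataset"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  idx0 <- which(ds$tx == 0)
  idx1 <- which(ds$tx == 1)
  n0 <- length(idx0); n1 <- length(idx1)
  adjusted <- length(covariates %||% character()) > 0
  res <- withr::with_seed(as.integer(seed), {
    if (!adjusted) {
      # vectorised: B x n index matrices per arm, arm-mean differences
      s0 <- matrix(idx0[sample.int(n0, B * n0, replace = TRUE)], nrow = B)
      s1 <- matrix(idx1[sample.int(n1, B * n1, replace = TRUE)], nrow = B)
      dc <- rowMeans(matrix(ds$cost[s1], nrow = B)) -
        rowMeans(matrix(ds$cost[s0], nrow = B))
      de <- rowMeans(matrix(ds$effect[s1], nrow = B)) -
        rowMeans(matrix(ds$effect[s0], nrow = B))
      deg <- vapply(seq_len(B), function(b) {
        all_const(ds$cost[s0[b, ]]) && all_const(ds$cost[s1[b, ]]) &&
          all_const(ds$effect[s0[b, ]]) && all_const(ds$effect[s1[b, ]])
      }, TRUE)
      list(dc = dc, de = de, deg = deg)
    } else {
      dc <- de <- numeric(B)
      deg <- logical(B)
      for (b in seq_len(B)) {
        keep <- c(idx0[sample.int(n0, n0, replace = TRUE)],
                  idx1[sample.int(n1, n1, replace = TRUE)])
        d <- subset_ce(ds, keep)
        inc <- incremental_summary(d, covariates)
        dc[b] <- inc$delta_cost
        de[b] <- inc$delta_effect
        deg[b] <- inc$s2_cost == 0 && inc$s2_effect == 0
      }
      list(dc = dc, de = de, deg = deg)
    }
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
  structure(
    list(B = B, seed = as.integer(seed),
         delta_cost_reps = res$dc, delta_effect_reps = res$de,
         degenerate = res$deg, stratified = TRUE, adjusted = adjusted),
    class = "nb_bootstrap"
  )
}

all_const <- function(x) length(unique(x)) == 1L

#' @export
print.nb_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap replicates: B = %d, seed = %d (%s, stratified by arm)\n",
              x$B, x$seed, if (x$adjusted) "adjusted refits" else "arm-mean differences"))
  cat(sprintf("  delta_cost:   mean %.2f, sd %.2f\n",
              mean(x$delta_cost_reps), stats::sd(x$delta_cost_reps)))
  cat(sprintf("  delta_effect: mean %.4f, sd %.4f\n",
              mean(x$delta_effect_reps), stats::sd(x$delta_effect_reps)))
  if (any(x$degenerate))
    cat("  ", sum(x$degenerate), "degenerate zero-variance replicate(s) flagged\n")
  invisible(x)
}

#' Bootstrap cost-effectiveness acceptability curve
#'
#' The probability of cost-effectiveness at each WTP is the fraction of
#' bootstrap replicates whose incremental net benefit
#' \eqn{\lambda \Delta E_b - \Delta C_b} is positive, with exact zeros
#' counted one half.
#'
#' @param reps an [bootstrap_replicates()] result.
#' @param grid WTP grid.
#' @return A `ceac_curve` with `method = "bootstrap"` carrying `B` and `seed`.
#' @export
ceac_bootstrap <- function(reps, grid = default_wtp_grid()) {
  stopifnot(inherits(reps, "nb_bootstrap"))
  prob <- vapply(grid, function(l) {
    inb <- l * reps$delta_effect_reps - reps$delta_cost_reps
    mean(inb > 0) + 0.5 * mean(inb == 0)
  }, 0)
  new_ceac_curve(grid, prob, "bootstrap", B = reps$B, seed = reps$seed)
}

#' Percentile bootstrap confidence interval for the INB
#'
#' Percentile interval of the replicate INBs at one WTP.  Percentile rather
#' than BCa: the simplest defensible nonparametric interval, adequate for
#' the near-symmetric INB sampling distributions seen at trial-scale n.
#'
#' @param reps an [bootstrap_replicates()] result (warns below B = 100).
#' @param wtp WTP at which to form the interval.
#' @param level confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci_inb <- function(reps, wtp, level = 0.95) {
  stopifnot(inherits(reps, "nb_bootstrap"))
  if (reps$B < 100)
    warning("percentile intervals are unreliable below B = 100 replicates")
  inb <- wtp * reps$delta_effect_reps - reps$delta_cost_reps
  a <- (1 - level) / 2
  q <- stats::quantile(inb, c(a, 1 - a), names = FALSE, type = 7)
  stats::setNames(q, c("lower", "upper"))
}
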