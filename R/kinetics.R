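#' Predicted organic-matter loss under first-order kinetics
#'
#' OM loss (%) at time `t` under the asymptotic first-order model
#' `a_max * (1 - exp(-k_rate * t))`, where `a_max` is the maximum
#' degradation of OM (%) and `k_rate` the rate constant (per day).
#'
#' @param a_max Asymptotic maximum OM degradation, % (>= 0).
#' @param k_rate First-order rate constant, per day (>= 0).
#' @param t Composting time, days (>= 0); may be a vector.
#' @return Predicted OM loss, %.
#' @examples
#' predict_om_loss(49.6, 0.0131, 105)
#' @export
predict_om_loss <- function(a_max, k_rate, t) {
  if (any(a_max < 0) || any(k_rate < 0) || any(t < 0))
    stop("predict_om_loss: a_max, k_rate and t must be non-negative")
  a_max * (1 - exp(-k_rate * t))
}

#' Fit the first-order OM-degradation model
#'
#' Nonlinear least-squares fit of OM loss (%) = A * (1 - exp(-k t)) to an
#' OM-loss time series by the Levenberg-Marquardt algorithm, with physical
#' bounds A in \[0, 100\] %, k in \[0, 10\] per day. Reported statistics:
#' `residual_mean_square` = SS_res/(n-2), `see` = sqrt(SS_res/(n-2)),
#' `f_value` = ((SS_tot - SS_res)/2) / (SS_res/(n-2)) with SS_tot about the
#' mean, `r_squared` = 1 - SS_res/SS_tot, and parameter standard errors
#' from the Jacobian at the optimum.
#'
#' @param times Sampling times, days; strictly increasing, length >= 4.
#' @param losses Observed OM losses, %, same length, each in \[0, 100\].
#' @param init Optional `c(a0, k0)` starting values. Default: `a0` is 1.1 x
#'   the largest observed loss and `k0 = log(2) / t_half`, `t_half` being
#'   the first time losses exceed half their maximum.
#' @param max_iter Maximum optimiser iterations.
#' @param tol Convergence tolerance (relative offset).
#' @return An object of class `kinetic_fit`: a list with `a_max`, `k_rate`,
#'   `a_se`, `k_se`, `ss_res`, `residual_mean_square`, `f_value`, `see`,
#'   `r_squared`, `n_obs`, `fitted`, `residuals`.
#' @export
fit_first_order <- function(times, losses, init = NULL,
                            max_iter = 200, tol = 1e-10) {
  stopifnot(is.numeric(times), is.numeric(losses),
            length(times) == length(losses))
  if (length(times) < 4)
    stop("fit_first_order: at least 4 observations are needed")
  if (any(diff(times) <= 0))
    stop("fit_first_order: times must be strictly increasing")
  if (any(losses < 0 | losses > 100))
    stop("fit_first_order: losses must lie in [0, 100]")
  if (all(losses == 0)) {
    warning("fit_first_order: all losses are zero; degenerate fit (k = 0)")
    n <- length(times)
    return(new_kinetic_fit(a_max = 0, k_rate = 0, a_se = NA_real_,
                           k_se = NA_real_, ss_res = 0, n = n,
                           fitted = rep(0, n), residuals = rep(0, n),
                           ss_tot = sum((losses - mean(losses))^2)))
  }
  if (is.null(init)) {
    a0 <- min(max(losses) * 1.1, 100)
    half <- max(losses) / 2
    t_half <- times[which(losses > half)[1]]
    if (is.na(t_half) || t_half <= 0) t_half <- stats::median(times[times > 0])
    k0 <- log(2) / t_half
  } else {
    a0 <- init[1]; k0 <- init[2]
  }
  dat <- data.frame(t = times, y = losses)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = dat,
                      start = list(A = a0, k = k0),
                      lower = c(0, 0), upper = c(100, 10),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = tol, ptol = tol)),
    error = function(e) stop("fit_first_order: fit failed to converge (",
                             conditionMessage(e), ")"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, k = NA_real_))
  pred <- stats::fitted(fit)
  res <- losses - pred
  new_kinetic_fit(a_max = unname(cf["A"]), k_rate = unname(cf["k"]),
                  a_se = unname(se["A"]), k_se = unname(se["k"]),
                  ss_res = sum(res^2), n = length(times),
                  fitted = as.numeric(pred), residuals = as.numeric(res),
                  ss_tot = sum((losses - mean(losses))^2))
}

new_kinetic_fit <- function(a_max, k_rate, a_se, k_se, ss_res, n,
                            fitted, residuals, ss_tot) {
  df_res <- n - 2
  rms <- ss_res / df_res
  f_value <- if (ss_tot > 0 && rms > 0) ((ss_tot - ss_res) / 2) / rms else NA_real_
  structure(list(
    a_max = a_max, k_rate = k_rate, a_se = a_se, k_se = k_se,
    ss_res = ss_res, ss_tot = ss_tot,
    residual_mean_square = rms,
    see = sqrt(rms),
    f_value = f_value,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_obs = n, fitted = fitted, residuals = residuals),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("First-order OM-degradation fit (n =", x$n_obs, ")\n")
  cat(sprintf("  A (max degradation)  %.2f %% (se %.2f)\n", x$a_max, x$a_se))
  cat(sprintf("  k (rate constant)    %.4f per day (se %.4f)\n",
              x$k_rate, x$k_se))
  cat(sprintf("  SEE %.3f  RMS %.3f  F %.1f  R2 %.3f\n",
              x$see, x$residual_mean_square, x$f_value, x$r_squared))
  invisible(x)
}

#' Significance summary of a first-order kinetic fit
#'
#' Tests the fitted regression against the intercept-only model with an
#' F(2, n-2) reference distribution.
#'
#' @param fit A `kinetic_fit` object (or a list with `f_value`, `n_obs`).
#' @param alpha Significance level for the verdict.
#' @return List with `f_value`, `df1`, `df2`, `p_value`, `significant`.
#' @export
fit_summary <- function(fit, alpha = 0.001) {
  f <- fit$f_value
  df2 <- fit$n_obs - 2
  p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  list(f_value = f, df1 = 2, df2 = df2, p_value = p,
       significant = is.finite(p) && p < alpha, alpha = alpha)
}

#' Read an OM-loss time series from CSV
#'
#' @param path CSV with columns `day` and `om_loss_pct`.
#' @return List with `times` and `losses`.
#' @export
read_om_loss_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("day", "om_loss_pct") %in% names(df)))
    stop("read_om_loss_series: need columns day, om_loss_pct")
  list(times = df$day, losses = df$om_loss_pct)
}
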