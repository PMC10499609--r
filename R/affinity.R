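#' Normalize therapeutic-antibody MFI
#'
#' Background-subtracted therapeutic signal relative to the
#' background-subtracted control-antibody signal:
#' `(mfi_therapeutic - mfi_background) / (mfi_control - mfi_background)`.
#' A value of 1 means therapeutic binding equal to the surface-expression
#' control; 0 means binding lost to background.
#'
#' @param mfi_therapeutic,mfi_control,mfi_background Median fluorescence
#'   intensities (vectors recycle).
#' @return Normalized response.
#' @export
normalize_mfi <- function(mfi_therapeutic, mfi_control, mfi_background = 0) {
  if (any(mfi_control <= mfi_background))
    stop("control MFI must exceed background MFI")
  (mfi_therapeutic - mfi_background) / (mfi_control - mfi_background)
}

#' Four-parameter log-logistic mean function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log x - log e)))` with Hill slope
#' `b`, lower asymptote `c`, upper asymptote `d` and midpoint (ED50) `e`.
#' At `x = 0` the continuous limit is returned (`d` for `b > 0`, `c` for
#' `b < 0`).
#'
#' @param x Dose vector (>= 0).
#' @param b,c,d,e Parameters; `e > 0`.
#' @return Mean response at each dose.
#' @export
ll4_mean <- function(x, b, c, d, e) {
  out <- numeric(length(x))
  zero <- x <= 0
  out[zero] <- if (b > 0) d else c
  out[!zero] <- c + (d - c) / (1 + exp(b * (log(x[!zero]) - log(e))))
  out
}

# RSS and analytic gradient in theta = (b, c, d, log e), x > 0 rows only;
# zero-dose rows contribute (resp - asymptote)^2 with zero gradient in b,
# log e and unit weight on the anchoring asymptote.
.ll4_rss <- function(theta, x, y) {
  b <- theta[1]; cc <- theta[2]; d <- theta[3]; e <- exp(theta[4])
  r <- y - ll4_mean(x, b, cc, d, e)
  sum(r^2)
}

.ll4_rss_grad <- function(theta, x, y) {
  b <- theta[1]; cc <- theta[2]; d <- theta[3]; loge <- theta[4]
  e <- exp(loge)
  g <- numeric(4)
  zero <- x <= 0
  if (any(zero)) {
    rz <- y[zero] - (if (b > 0) d else cc)
    if (b > 0) g[3] <- g[3] - 2 * sum(rz) else g[2] <- g[2] - 2 * sum(rz)
  }
  xp <- x[!zero]; yp <- y[!zero]
  if (length(xp) > 0) {
    u <- exp(b * (log(xp) - loge))
    s <- 1 / (1 + u)                      # logistic factor
    f <- cc + (d - cc) * s
    r <- yp - f
    ds <- -s^2 * u                        # d s / d(arg), arg = b(logx - loge)
    dfdb <- (d - cc) * ds * (log(xp) - loge)
    dfdc <- 1 - s
    dfdd <- s
    dfdloge <- (d - cc) * ds * (-b)
    g[1] <- g[1] - 2 * sum(r * dfdb)
    g[2] <- g[2] - 2 * sum(r * dfdc)
    g[3] <- g[3] - 2 * sum(r * dfdd)
    g[4] <- g[4] - 2 * sum(r * dfdloge)
  }
  g
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Gaussian-error maximum likelihood (least squares with
#' `sigma^2 = RSS/n`) with deterministic multi-start optimization:
#' Hill-slope starts `{+-0.5, +-1, +-2}`, midpoint starts at the 25/50/75%
#' quantiles of the positive doses, asymptote starts at the response
#' extremes. The best final likelihood wins; ties break to the smallest
#' `|b|`. Zero-dose rows are anchored to the curve's limiting asymptote
#' by default (the log-logistic is undefined at `log 0`) or dropped.
#'
#' @param dose,response Numeric vectors (doses >= 0, at least 4 distinct).
#' @param zero_dose `"anchor"` (default) or `"drop"`.
#' @return An `ll4_fit`: `coefficients` (b, c, d, e), `se`, `sigma`,
#'   `loglik`, `rss`, `n`, `converged`, `fitted`.
#' @export
fit_ll4 <- function(dose, response, zero_dose = c("anchor", "drop")) {
  zero_dose <- match.arg(zero_dose)
  stopifnot(length(dose) == length(response), all(dose >= 0))
  if (zero_dose == "drop") {
    keep <- dose > 0
    dose <- dose[keep]; response <- response[keep]
  }
  if (length(unique(dose)) < 4L)
    stop("need >= 4 distinct doses for a 4-parameter fit")
  pos <- dose[dose > 0]
  e_starts <- unique(stats::quantile(pos, c(0.25, 0.5, 0.75),
                                     names = FALSE, type = 7))
  b_starts <- c(0.5, -0.5, 1, -1, 2, -2)
  c0 <- min(response); d0 <- max(response)
  # parameter box: keeps the optimizer off the degenerate log-linear
  # ridge (b -> 0, e -> 0 or Inf, |c|, |d| -> Inf traces a straight line
  # in log dose with no finite optimum)
  span <- max(d0 - c0, 1e-8)
  lower <- c(-50, c0 - 3 * span, c0 - 3 * span, log(min(pos)) - 7)
  upper <- c(50, d0 + 3 * span, d0 + 3 * span, log(max(pos)) + 7)
  best <- NULL
  for (b0 in b_starts) for (e0 in e_starts) {
    th0 <- c(b0, c0, d0, log(e0))
    opt <- try(stats::optim(th0, .ll4_rss, gr = .ll4_rss_grad,
                            x = dose, y = response, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e3)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    cand <- list(theta = opt$par, rss = opt$value,
                 conv = opt$convergence == 0)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 &&
         abs(cand$theta[1]) < abs(best$theta[1]))) best <- cand
  }
  if (is.null(best)) stop("LL.4 fit failed from every start")
  if (!isTRUE(best$conv)) {
    polish <- try(stats::optim(best$theta, .ll4_rss, gr = .ll4_rss_grad,
                               x = dose, y = response, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = 5000, factr = 1e3)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && is.finite(polish$value) &&
        polish$value <= best$rss)
      best <- list(theta = polish$par, rss = polish$value,
                   conv = polish$convergence == 0)
    grad <- .ll4_rss_grad(best$theta, dose, response)
    if (max(abs(grad)) < 1e-6 * (1 + best$rss)) best$conv <- TRUE
  }
  th <- best$theta
  # canonical orientation: (b, c, d, e) and (-b, d, c, e) trace the same
  # curve, so report the representative with c <= d (b >= 0 when c = d)
  if (th[2] > th[3] || (th[2] == th[3] && th[1] < 0)) {
    th <- c(-th[1], th[3], th[2], th[4])
  }
  n <- length(response)
  rss <- best$rss
  sigma2 <- rss / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  coef <- c(b = th[1], c = th[2], d = th[3], e = exp(th[4]))
  # Gauss-Newton SEs on (b, c, d, e) via the mean-function Jacobian
  se <- rep(NA_real_, 4)
  Jt <- try({
    eps <- 1e-6
    J <- vapply(1:4, function(k) {
      thp <- coef; thm <- coef
      h <- eps * max(1, abs(coef[k]))
      thp[k] <- thp[k] + h; thm[k] <- thm[k] - h
      (ll4_mean(dose, thp[1], thp[2], thp[3], thp[4]) -
         ll4_mean(dose, thm[1], thm[2], thm[3], thm[4])) / (2 * h)
    }, numeric(n))
    V <- sigma2 * solve(crossprod(J))
    sqrt(diag(V))
  }, silent = TRUE)
  if (!inherits(Jt, "try-error")) se <- Jt
  names(se) <- names(coef)
  structure(list(
    coefficients = coef, se = se,
    sigma = sqrt(sigma2), rss = rss, n = n, loglik = loglik,
    converged = isTRUE(best$conv),
    fitted = ll4_mean(dose, coef[1], coef[2], coef[3], coef[4]),
    dose = dose, response = response, zero_dose = zero_dose
  ), class = "ll4_fit")
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat(sprintf(
    "LL.4 fit (n = %d): b = %.4g, c = %.4g, d = %.4g, e = %.4g; sigma = %.4g, logLik = %.4g%s\n",
    x$n, x$coefficients[1], x$coefficients[2], x$coefficients[3],
    x$coefficients[4], x$sigma, x$loglik,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Likelihood-ratio comparison of dose-response curves
#'
#' Tests whether groups (e.g. receptor variants probed with one
#' antibody, or antibodies probed on one variant) share one LL.4 curve.
#' Model 0 fits a single curve to the pooled data; model 1 fits an
#' independent curve per group. Each model uses one shared Gaussian
#' error variance estimated by maximum likelihood, so the degrees of
#' freedom count mean-function parameters only: `df = 4 * (G - 1)`.
#'
#' Because the likelihood is Gaussian, the likelihood ratio is a
#' monotone function of the residual-sum-of-squares ratio, and the exact
#' finite-sample reference for it is the F distribution with
#' `(4(G-1), n - 4G)` degrees of freedom; the asymptotic chi-squared
#' reference on `4(G-1)` df is noticeably liberal at typical
#' curve-comparison sample sizes (a few dozen points), so `reference =
#' "F"` is the default and `"chisq"` is available for the large-sample
#' convention.
#'
#' @param data data.frame with columns `group`, `dose`, `response`.
#' @param zero_dose Passed to [fit_ll4()].
#' @param reference `"F"` (exact Gaussian finite-sample reference,
#'   default) or `"chisq"` (asymptotic).
#' @return An `ll4_lrt`: `statistic` (`2 * (ll1 - ll0)`), `df`,
#'   `p_value`, `loglik_model0`, `loglik_model1`, per-group fits and the
#'   pooled fit.
#' @export
lr_test <- function(data, zero_dose = c("anchor", "drop"),
                    reference = c("F", "chisq")) {
  zero_dose <- match.arg(zero_dose)
  reference <- match.arg(reference)
  stopifnot(all(c("group", "dose", "response") %in% names(data)))
  groups <- split(data, data$group)
  G <- length(groups)
  if (G < 2L) stop("need >= 2 groups")
  fit0 <- fit_ll4(data$dose, data$response, zero_dose)
  fits1 <- lapply(groups, function(g) fit_ll4(g$dose, g$response, zero_dose))
  if (!fit0$converged || !all(vapply(fits1, `[[`, logical(1), "converged")))
    stop("a component LL.4 fit did not converge")
  n <- nrow(data)
  rss1 <- sum(vapply(fits1, `[[`, numeric(1), "rss"))
  sigma2_1 <- rss1 / n
  ll1 <- -n / 2 * (log(2 * pi * sigma2_1) + 1)
  ll0 <- fit0$loglik
  stat <- max(0, 2 * (ll1 - ll0))
  df <- 4L * (G - 1L)
  rss0 <- fit0$rss
  df2 <- n - 4L * G
  p_value <- if (reference == "chisq" || df2 <= 0) {
    stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    Fstat <- ((rss0 - rss1) / df) / (rss1 / df2)
    stats::pf(Fstat, df, df2, lower.tail = FALSE)
  }
  structure(list(
    statistic = stat, df = df,
    p_value = p_value, reference = reference,
    loglik_model0 = ll0, loglik_model1 = ll1,
    fit_pooled = fit0, fits = fits1
  ), class = "ll4_lrt")
}

#' @export
print.ll4_lrt <- function(x, ...) {
  cat(sprintf("LL.4 likelihood-ratio test: LR = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
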