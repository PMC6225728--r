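## Diffusion model fits on time-averaged MSD curves.  Fitting is nonlinear
## least squares on the linear MSD scale (unweighted); log-log regression is
## used only for initialization, and as a fallback when the optimizer fails.

select_fit_lags <- function(curve, fit_fraction, min_lags, max_lags) {
  k <- nrow(curve)
  n_use <- min(max(ceiling(fit_fraction * k), min_lags), max_lags, k)
  curve[seq_len(n_use), , drop = FALSE]
}

#' Fit the anomalous diffusion model MSD = 4 D_a t^a
#'
#' Nonlinear least squares over the first `fit_fraction` of available lags
#' (at least `min_lags`, at most `max_lags`), with bounds `D_alpha >= 0`
#' and `alpha` in (0, 2].  Initialization comes from a log-log linear
#' regression; if the optimizer fails the log-log estimates are returned
#' with `flag = "loglog_fallback"`.
#'
#' @param curve an `msd_curve` from [compute_msd()].
#' @param fit_fraction fraction of available lags to fit (default 0.25).
#' @param min_lags,max_lags bounds on the number of fitted lags.
#' @return an `anomalous_fit`: list with D_alpha (um^2/s^alpha), alpha,
#'   rss, n_points, flag.
#' @export
fit_anomalous <- function(curve, fit_fraction = 0.25, min_lags = 5L,
                          max_lags = 60L) {
  cv <- select_fit_lags(curve, fit_fraction, min_lags, max_lags)
  if (nrow(cv) < 5) stopf("need at least 5 lags to fit; have %d", nrow(cv))
  t <- cv$lag_s; y <- cv$msd_um2
  if (all(y <= 0)) stopf("MSD is identically zero; alpha is undefined")
  pos <- y > 0
  ll <- stats::lm(log(y[pos]) ~ log(t[pos]))
  a0 <- min(max(unname(stats::coef(ll)[2]), 0.01), 2)
  D0 <- max(exp(unname(stats::coef(ll)[1])) / 4, 1e-12)
  flag <- "ok"
  fit <- tryCatch({
    nf <- stats::nls(y ~ 4 * D * t^a,
                     start = list(D = D0, a = a0),
                     lower = c(D = 0, a = 1e-6), upper = c(D = Inf, a = 2),
                     algorithm = "port",
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))
    p <- stats::coef(nf)
    list(D = unname(p["D"]), a = unname(p["a"]),
         rss = sum(stats::resid(nf)^2))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((y - 4 * exp(p[1]) * t^p[2])^2)
    op <- tryCatch(stats::optim(c(log(D0), a0), obj, method = "L-BFGS-B",
                                lower = c(-60, 1e-6), upper = c(60, 2)),
                   error = function(e) NULL)
    if (!is.null(op)) {
      fit <- list(D = exp(op$par[1]), a = op$par[2], rss = op$value)
      flag <- "optim_fallback"
    } else {
      fit <- list(D = D0, a = a0, rss = sum((y - 4 * D0 * t^a0)^2))
      flag <- "loglog_fallback"
    }
  }
  if (fit$a >= 2 - 1e-9 || fit$a <= 1e-5) flag <- paste(flag, "at_bound")
  structure(list(D_alpha = fit$D, alpha = fit$a, rss = fit$rss,
                 n_points = nrow(cv), flag = flag),
            class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf("<anomalous_fit> alpha=%.4f, D_alpha=%.4g um^2/s^a (rss %.3g, %d lags, %s)\n",
              x$alpha, x$D_alpha, x$rss, x$n_points, x$flag))
  invisible(x)
}

#' Fit the confined + macroscopic model MSD = A(1-exp(-t/tau)) + 4 D_macro t
#'
#' Multi-start bounded nonlinear least squares: tau initialized from the
#' curve half-rise, A from the late plateau, D_macro from the tail slope,
#' with additional starts at tau/5 and 5 tau and a near-pure-diffusion
#' start.  The derived microscopic coefficient `D_micro = A/(4 tau)` and
#' confinement size `L = sqrt(A/2)` are computed from the fitted values.
#' All fitted lags are used by default: the plateau is a late-lag feature.
#'
#' @param curve an `msd_curve`.
#' @param fit_fraction fraction of available lags to fit (default 1).
#' @param min_lags,max_lags bounds on the number of fitted lags.
#' @return a `confined_fit`: A (um^2), tau (s), D_macro (um^2/s),
#'   D_micro (um^2/s), L (um), rss, n_points, flag.
#' @export
fit_confined <- function(curve, fit_fraction = 1, min_lags = 6L,
                         max_lags = Inf) {
  cv <- select_fit_lags(curve, fit_fraction, min_lags, max_lags)
  if (nrow(cv) < 6) stopf("need at least 6 lags to fit; have %d", nrow(cv))
  t <- cv$lag_s; y <- cv$msd_um2
  n <- length(t)
  tail_idx <- seq.int(max(1, floor(2 * n / 3)), n)
  slope <- if (length(tail_idx) >= 2)
    max(unname(stats::coef(stats::lm(y[tail_idx] ~ t[tail_idx]))[2]), 0) else 0
  D0 <- slope / 4
  A0 <- max(mean(y[tail_idx]) - 4 * D0 * mean(t[tail_idx]), max(y) * 0.05,
            1e-12)
  half <- t[which(y - 4 * D0 * t >= A0 / 2)[1]]
  tau0 <- if (is.na(half)) max(t) / 4 else max(half / log(2), t[1] / 2)
  starts <- list(c(A0, tau0, D0), c(A0, tau0 / 5, D0), c(A0, 5 * tau0, D0),
                 c(max(y) * 0.01, tau0, max(slope, y[1] / t[1] / 8) / 4))
  obj <- function(p) sum((y - (p[1] * (1 - exp(-t / p[2])) + 4 * p[3] * t))^2)
  best <- NULL
  for (s in starts) {
    op <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                lower = c(0, 1e-6, 0),
                                control = list(maxit = 500, factr = 1e4)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stopf("confined fit failed from every start")
  ## Gauss-Newton polish: tightens the multi-start solution to machine
  ## precision on clean curves
  dat <- data.frame(t = t, y = y)
  nf <- tryCatch(suppressWarnings(stats::nls(
    y ~ A * (1 - exp(-t / tau)) + 4 * Dm * t, data = dat,
    start = list(A = max(best$par[1], 1e-10), tau = max(best$par[2], 1e-6),
                 Dm = best$par[3]),
    lower = c(0, 1e-6, 0), algorithm = "port",
    control = stats::nls.control(maxiter = 500, tol = 1e-12,
                                 warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(nf)) {
    rss_nf <- sum(stats::resid(nf)^2)
    if (rss_nf <= best$value) {
      p <- stats::coef(nf)
      best <- list(par = c(p[["A"]], p[["tau"]], p[["Dm"]]), value = rss_nf)
    }
  }
  A <- best$par[1]; tau <- best$par[2]; Dm <- best$par[3]
  flag <- "ok"
  if (A < 1e-6 * max(y)) {
    warnf("confined fit is degenerate (A ~ 0): curve is effectively linear; D_macro carries the slope")
    flag <- "degenerate_linear"
  }
  structure(list(A = A, tau = tau, D_macro = Dm, D_micro = A / (4 * tau),
                 L = sqrt(A / 2), rss = best$value, n_points = n,
                 flag = flag),
            class = "confined_fit")
}

#' @export
print.confined_fit <- function(x, ...) {
  cat(sprintf("<confined_fit> A=%.4g um^2, tau=%.3g s, D_macro=%.3g, D_micro=%.3g um^2/s, L=%.4g um (%s)\n",
              x$A, x$tau, x$D_macro, x$D_micro, x$L, x$flag))
  invisible(x)
}

#' Summarize anomalous exponents by group
#'
#' @param alphas numeric vector of fitted exponents.
#' @param group_labels grouping factor, same length.
#' @param bin_width histogram bin width on [0, 2].
#' @return named list per group: values, n, mean, sd, se (NA for n = 1),
#'   and hist (counts over the fixed bins).  Empty groups are dropped with
#'   a warning.
#' @export
alpha_distribution <- function(alphas, group_labels, bin_width = 0.1) {
  group_labels <- as.character(group_labels)
  breaks <- seq(0, 2, by = bin_width)
  out <- list()
  for (g in unique(group_labels)) {
    v <- alphas[group_labels == g & !is.na(alphas)]
    if (length(v) == 0) { warnf("group '%s' is empty; omitted", g); next }
    h <- graphics::hist(pmin(pmax(v, 0), 2), breaks = breaks, plot = FALSE)
    out[[g]] <- list(values = v, n = length(v), mean = mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                     se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                          else NA_real_,
                     hist = h$counts, breaks = breaks)
  }
  out
}

#' Welch two-sided t test between two groups
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom.  When both groups have zero variance: p = 1 for equal means
#' (t = 0), p = 0 otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with t, df, p_value, mean_a, mean_b.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs at least 2 values")
  m1 <- mean(values_a); m2 <- mean(values_b)
  v1 <- stats::var(values_a); v2 <- stats::var(values_b)
  n1 <- length(values_a); n2 <- length(values_b)
  if (v1 == 0 && v2 == 0) {
    tstat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(t = tstat, df = n1 + n2 - 2,
                p_value = if (m1 == m2) 1 else 0, mean_a = m1, mean_b = m2))
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p_value = 2 * stats::pt(-abs(tstat), df),
       mean_a = m1, mean_b = m2)
}
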