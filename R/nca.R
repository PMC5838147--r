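#' Area under a concentration-time curve
#'
#' Trapezoidal integration.  `"linear"` uses the linear trapezoid on
#' every segment; `"linear_up_log_down"` (standard NCA practice)
#' switches to the log trapezoid `(C1 - C2) / ln(C1/C2) * dt` on
#' segments where the concentration declines between two positive
#' values, which is exact for mono-exponential decay.
#'
#' @param profile A [pk_profile()] (or anything with `times`/`conc`);
#'   at least 2 points.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @return AUC to the last point, in concentration-unit * h.
#' @export
auc <- function(profile, method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  auc_aumc(profile$times, profile$conc, method)["auc"]
}

auc_aumc <- function(t, c, method) {
  if (length(t) < 2L) stop("AUC needs at least 2 points", call. = FALSE)
  a <- 0
  m <- 0
  for (k in seq_len(length(t) - 1L)) {
    t1 <- t[k]; t2 <- t[k + 1L]; c1 <- c[k]; c2 <- c[k + 1L]
    dt <- t2 - t1
    logdown <- method == "linear_up_log_down" && c2 < c1 && c2 > 0
    if (logdown) {
      lam <- log(c1 / c2) / dt
      a <- a + (c1 - c2) / lam
      m <- m + (t1 * c1 - t2 * c2) / lam + (c1 - c2) / lam^2
    } else {
      a <- a + dt * (c1 + c2) / 2
      m <- m + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  c(auc = a, aumc = m)
}

#' Terminal elimination rate by log-linear regression
#'
#' Fits `log(C)` against `t` by least squares over candidate terminal
#' windows (all suffixes with at least `min_points` quantifiable points,
#' excluding Tmax and earlier points for extravascular profiles) and
#' keeps the window with the best adjusted r-squared.  `lambda_z` is the
#' negative slope.
#'
#' @param profile A [pk_profile()].
#' @param min_points Minimum points in the terminal window (default 3).
#' @return List: `lambda_z` (1/h), `t_half` (h), `n_points`, `r2`,
#'   `adj_r2`, `points_used` (indices), `reliable` (FALSE when the
#'   fitted slope is non-negative or the fit is degenerate).
#' @export
fit_lambda_z <- function(profile, min_points = 3L) {
  t <- profile$times
  c <- profile$conc
  pos <- c > 0
  imax <- which.max(c)
  candidates <- which(pos & seq_along(c) > imax)
  if (profile$route == "iv_bolus" && imax == 1L) {
    candidates <- which(pos & seq_along(c) >= 2L)
  }
  if (length(candidates) < min_points) {
    stop("need at least ", min_points,
         " quantifiable terminal points after Tmax", call. = FALSE)
  }
  starts <- candidates[seq_len(length(candidates) - min_points + 1L)]
  best <- NULL
  for (s in starts) {
    idx <- candidates[candidates >= s]
    fit <- stats::lm(log(c[idx]) ~ t[idx])
    sm <- suppressWarnings(summary(fit))   # exact fits trip summary.lm
    adj <- sm$adj.r.squared
    if (is.null(best) || (is.finite(adj) && adj > best$adj_r2 + 1e-10)) {
      best <- list(slope = unname(stats::coef(fit)[2]),
                   r2 = sm$r.squared, adj_r2 = adj, idx = idx)
    }
  }
  lambda <- -best$slope
  list(lambda_z = lambda, t_half = log(2) / lambda,
       n_points = length(best$idx), r2 = best$r2, adj_r2 = best$adj_r2,
       points_used = best$idx,
       reliable = is.finite(lambda) && lambda > 0 &&
         is.finite(best$r2) && best$r2 >= 0.8)
}

#' Non-compartmental analysis of one profile
#'
#' Computes the standard model-free parameters: Cmax/Tmax from the
#' observed points, AUC to the last quantifiable point and extrapolated
#' to infinity (`auc_inf = auc_last + C_last / lambda_z`), terminal
#' half-life, mean residence time (`AUMC_inf / AUC_inf`), and for i.v.
#' bolus dosing the blood clearance `CL = dose / AUC_inf` (mL/min/kg)
#' and steady-state volume `Vss = CL * MRT` (L/kg).  Dose-normalized
#' AUC is `auc_inf / dose`.  Unit conversion between nM and ng/mL uses
#' the declared molecular weight and is never guessed.
#'
#' @param profile A [pk_profile()].
#' @param method AUC method, see [auc()].
#' @param blq_rule Censoring rule, see [preprocess_blq()].
#' @param min_points Terminal-fit minimum, see [fit_lambda_z()].
#' @return Object of class `"nca_result"`.
#' @export
nca <- function(profile, method = c("linear_up_log_down", "linear"),
                blq_rule = "leading_zero", min_points = 3L) {
  stopifnot(inherits(profile, "pk_profile"))
  method <- match.arg(method)
  p <- preprocess_blq(profile, blq_rule)
  t <- p$times
  c <- p$conc
  cmax <- max(c)         # Cmax/Tmax from observed points only
  tmax <- t[which.max(c)]
  lam <- fit_lambda_z(p, min_points)
  if (p$route == "iv_bolus" && t[1] > 0) {
    # standard bolus C0: log-linear back-extrapolation through the
    # first two declining points; falls back to C(t1) otherwise
    c0 <- if (length(c) >= 2 && c[1] > c[2] && c[2] > 0) {
      exp(log(c[1]) - t[1] * (log(c[2]) - log(c[1])) / (t[2] - t[1]))
    } else {
      c[1]
    }
    t <- c(0, t)
    c <- c(c0, c)
  }
  both <- auc_aumc(t, c, method)
  last_q <- max(which(c > 0))
  c_last <- c[last_q]
  t_last <- t[last_q]
  auc_last <- unname(both["auc"])
  aumc_last <- unname(both["aumc"])
  auc_inf <- auc_last + c_last / lam$lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lam$lambda_z +
    c_last / lam$lambda_z^2
  mrt <- aumc_inf / auc_inf
  cl <- vss <- NA_real_
  if (p$route == "iv_bolus") {
    auc_ngml <- conc_as_ng_ml(auc_inf, p$conc_unit, p$molecular_weight)
    cl <- p$dose * 1e6 / auc_ngml / 60        # mL/min/kg
    vss <- cl * mrt * 60 / 1000               # L/kg
  }
  structure(list(
    subject_id = p$subject_id, site = p$site, route = p$route,
    dose = p$dose, conc_unit = p$conc_unit,
    auc_last = auc_last, auc_inf = unname(auc_inf),
    cmax = cmax, tmax = tmax,
    lambda_z = lam$lambda_z, t_half = lam$t_half,
    n_lambda_points = lam$n_points, lambda_r2 = lam$r2,
    lambda_reliable = lam$reliable,
    mrt = unname(mrt), cl = cl, vss = vss,
    auc_dose_normalized = unname(auc_inf) / p$dose,
    blq_note = p$blq_note
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("nca_result %s [%s, %s], dose %g mg/kg:\n", x$subject_id,
              x$site, x$route, x$dose))
  cat(sprintf("  Cmax %.4g %s at %.3g h; AUC_last %.4g, AUC_inf %.4g %s*h\n",
              x$cmax, x$conc_unit, x$tmax, x$auc_last, x$auc_inf,
              x$conc_unit))
  cat(sprintf("  lambda_z %.4g 1/h (t1/2 %.3g h, %d pts, r2 %.3f); MRT %.3g h\n",
              x$lambda_z, x$t_half, x$n_lambda_points, x$lambda_r2, x$mrt))
  if (x$route == "iv_bolus") {
    cat(sprintf("  CL %.4g mL/min/kg; Vss %.3g L/kg\n", x$cl, x$vss))
  }
  invisible(x)
}

#' Absolute oral bioavailability from dose-normalized AUCs
#'
#' `%BAV = 100 * AUC_dn(oral) / AUC_dn(iv)`.  Arguments may be
#' `nca_result` objects or bare dose-normalized AUC numbers (so printed
#' table values can be checked directly).
#'
#' @param oral,iv `nca_result` or numeric dose-normalized AUC.
#' @return Bioavailability in percent.
#' @examples
#' oral_bioavailability(214, 544)  # 39.3
#' @export
oral_bioavailability <- function(oral, iv) {
  dn <- function(x) {
    if (inherits(x, "nca_result")) x$auc_dose_normalized else as.numeric(x)
  }
  o <- dn(oral)
  i <- dn(iv)
  if (!is.finite(i) || i <= 0) stop("iv dose-normalized AUC must be > 0",
                                    call. = FALSE)
  100 * o / i
}
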