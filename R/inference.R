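#' Invert DW-SSFP attenuation to an apparent diffusion coefficient
#'
#' Finds the single diffusivity D for which the chosen Gaussian DW-SSFP model
#' predicts the measured attenuation S(q, D)/S(q, 0). The model ratio is
#' strictly decreasing in D, so the root is unique; it is located by bracketed
#' search on [0, d_max].
#'
#' @param attenuation Measured attenuation(s) in (0, 1].
#' @param flip_deg Flip angle(s) in degrees, recycled against `attenuation`.
#' @param p An [ssfp_protocol()].
#' @param tis A [tissue()] supplying T1, T2 (its `d` is ignored).
#' @param model DW-SSFP signal model used for the inversion.
#' @param pulse Gradient treatment for the coherence-order models.
#' @param d_max Upper bracket for D, mm^2/s.
#' @return ADC estimate(s) in mm^2/s.
#' @export
#' @examples
#' p <- ssfp_protocol(60, tr_ms = 28.2, tau_ms = 13.56, q_per_cm = 300)
#' tis <- tissue(568, 19.8)
#' a <- ssfp_attenuation(p, tissue(568, 19.8, d = 3e-4), model = "buxton")
#' adc_from_attenuation(a, 60, p, tis)  # recovers 3e-4
adc_from_attenuation <- function(attenuation, flip_deg, p, tis,
                                 model = c("buxton", "two_period", "freed"),
                                 pulse = c("pulsed", "narrow"),
                                 d_max = 0.01) {
  stopifnot(inherits(p, "ssfp_protocol"), inherits(tis, "tissue"))
  model <- match.arg(model)
  pulse <- match.arg(pulse)
  n <- max(length(attenuation), length(flip_deg))
  attenuation <- rep_len(attenuation, n)
  flip_deg <- rep_len(flip_deg, n)
  if (any(attenuation <= 0 | attenuation > 1)) {
    stop_dwssfp("attenuation must lie in (0, 1]", class = "dwssfp_error_data")
  }
  vapply(seq_len(n), function(i) {
    a <- attenuation[i]
    if (a == 1) return(0)
    # model ratio S(q, d) / S(q, 0), strictly decreasing in d
    alpha <- flip_deg[i] * pi / 180
    s_ref <- ssfp_signal_core(model, alpha, p, tis$t1, tis$t2, 0,
                              pulse = pulse)
    f <- function(d) {
      ssfp_signal_core(model, alpha, p, tis$t1, tis$t2, d,
                       pulse = pulse) / s_ref - a
    }
    if (f(d_max) > 0) {
      stop_dwssfp(
        sprintf("attenuation %.6g below model ratio at d_max = %g: widen d_max",
                a, d_max),
        class = "dwssfp_error_bracket")
    }
    stats::uniroot(f, c(0, d_max), tol = 1e-14)$root
  }, numeric(1))
}

#' ADC of a DW-SE measurement under a gamma diffusivity distribution
#'
#' The ADC obtained by fitting the Stejskal-Tanner mono-exponential to the
#' gamma-mixture DW-SE signal at b-value b:
#' ADC(b) = (Dm^2 / (b Ds^2)) log(1 + b Ds^2 / Dm), with ADC(0) = Dm by
#' continuous extension. Strictly decreasing and convex in b when Ds > 0.
#'
#' @param b b-value(s), s/mm^2.
#' @param g A [gamma_diffusivity()].
#' @return ADC(s) in mm^2/s.
#' @export
#' @examples
#' adc_se_gamma(1000, gamma_diffusivity(1.5e-4, 2.1e-4))  # ~1.315e-4
adc_se_gamma <- function(b, g) {
  stopifnot(inherits(g, "gamma_diffusivity"))
  if (any(b < 0)) stop_dwssfp("b must be >= 0", class = "dwssfp_error_data")
  x <- b * g$ds^2 / g$dm
  ifelse(x < .Machine$double.eps, g$dm, g$dm * log1p(x) / x)
}

#' Equivalent DW-SE b-value for a given ADC
#'
#' Solves adc_se_gamma(b) = adc for b on [0, b_max]: the DW-SE b-value at
#' which a Stejskal-Tanner fit to the shared gamma-mixture signal would give
#' the same ADC as measured (e.g. with DW-SSFP at some flip angle).
#'
#' @param adc ADC value(s), mm^2/s; each must lie in
#'   (adc_se_gamma(b_max), Dm].
#' @param g A [gamma_diffusivity()].
#' @param b_max Upper bracket, s/mm^2.
#' @return Effective b-value(s), s/mm^2.
#' @export
effective_bvalue <- function(adc, g, b_max = 20000) {
  stopifnot(inherits(g, "gamma_diffusivity"))
  if (g$ds / g$dm < 1e-8) {
    stop_dwssfp(
      "degenerate distribution (Ds = 0): the ADC is b-independent, any b matches",
      class = "dwssfp_error_degenerate")
  }
  vapply(adc, function(a) {
    if (a > g$dm * (1 + 1e-12)) {
      stop_dwssfp(sprintf("adc %.6g exceeds Dm %.6g: no b-value solves it",
                          a, g$dm),
                  class = "dwssfp_error_nosolution")
    }
    if (a >= g$dm) return(0)
    lo <- adc_se_gamma(b_max, g)
    if (a < lo) {
      stop_dwssfp(
        sprintf("adc %.6g below adc_se_gamma(b_max) = %.6g: raise b_max",
                a, lo),
        class = "dwssfp_error_bracket")
    }
    stats::uniroot(function(b) adc_se_gamma(b, g) - a, c(0, b_max),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Predicted ADC-versus-flip-angle curve under a gamma distribution
#'
#' Forward-evaluates the gamma-mixture DW-SSFP attenuation at each flip angle
#' and inverts it with the single-D (Gaussian) model, reproducing the
#' flip-angle dependence of the ADC that non-Gaussian diffusion induces.
#'
#' @param g A [gamma_diffusivity()].
#' @param p An [ssfp_protocol()].
#' @param tis A [tissue()] (T1, T2).
#' @param model DW-SSFP signal model.
#' @param pulse Gradient treatment for the coherence-order models.
#' @param flip_deg Optional flip-angle override (degrees).
#' @return A tibble with columns `flip_deg`, `adc`.
#' @export
predicted_adc_curve <- function(g, p, tis,
                                model = c("buxton", "two_period", "freed"),
                                pulse = c("pulsed", "narrow"),
                                flip_deg = NULL) {
  model <- match.arg(model)
  pulse <- match.arg(pulse)
  flips <- if (is.null(flip_deg)) p$flip_deg else flip_deg
  att <- ssfp_attenuation(p, tis, g = g, model = model, flip_deg = flips,
                          pulse = pulse)
  tibble::tibble(flip_deg = flips,
                 adc = adc_from_attenuation(att, flips, p, tis, model = model,
                                            pulse = pulse))
}

#' Fit a gamma diffusivity distribution across flip angles
#'
#' Least-squares fit of the two-parameter gamma diffusivity distribution
#' (Dm, Ds) to multi-flip DW-SSFP data, using the Levenberg-Marquardt
#' algorithm with positivity enforced by a log-parameterization. Two fit
#' targets are supported: `"adc"` fits the predicted ADC-versus-flip curve to
#' measured ADCs (the route used for experimental data); `"signal"` fits the
#' gamma-model attenuation directly to measured attenuations (the route used
#' against Monte-Carlo signals).
#'
#' @param data For `fit_target = "adc"`: a data frame with columns `flip_deg`,
#'   `adc` (optionally `stderr`). For `"signal"`: columns `flip_deg`,
#'   `attenuation` (optionally `stderr`).
#' @param p An [ssfp_protocol()].
#' @param tis A [tissue()] (T1, T2).
#' @param model DW-SSFP signal model.
#' @param fit_target `"adc"` or `"signal"`.
#' @param weights `"none"` (default) for unweighted least squares, or
#'   `"stderr"` for inverse-variance weighting by the `stderr` column.
#' @param pulse Gradient treatment for the coherence-order models; use
#'   `"narrow"` when fitting Monte-Carlo data (the simulator's impulse
#'   gradients).
#' @param start Optional named vector `c(dm = , ds = )` of starting values;
#'   defaults to Dm0 = ADC at the largest flip angle (or the attenuation-
#'   implied ADC) and Ds0 = Dm0.
#' @return An object of class `dwssfp_gamma_fit`: a list with elements `dm`,
#'   `ds`, `cov` (2x2 covariance of (Dm, Ds) from the LM fit, delta-method
#'   transformed from the log scale), `convergence`, `degenerate` (TRUE when
#'   Ds is pinned near zero, i.e. the data are consistent with Gaussian
#'   diffusion), `fitted`, `data`, `model`, `fit_target`.
#' @export
fit_gamma <- function(data, p, tis,
                      model = c("buxton", "two_period", "freed"),
                      fit_target = c("adc", "signal"),
                      weights = c("none", "stderr"),
                      pulse = c("pulsed", "narrow"),
                      start = NULL) {
  stopifnot(inherits(p, "ssfp_protocol"), inherits(tis, "tissue"))
  model <- match.arg(model)
  pulse <- match.arg(pulse)
  fit_target <- match.arg(fit_target)
  weights <- match.arg(weights)
  data <- tibble::as_tibble(data)
  if (!("flip_deg" %in% names(data))) {
    stop_dwssfp("data must have a flip_deg column", class = "dwssfp_error_data")
  }
  if (anyDuplicated(data$flip_deg)) {
    stop_dwssfp("duplicate flip angles: degenerate design",
                class = "dwssfp_error_data")
  }
  if (nrow(data) < 3 || diff(range(data$flip_deg)) < 30) {
    stop_dwssfp("need >= 3 flip angles spanning >= 30 degrees",
                class = "dwssfp_error_data")
  }
  ycol <- if (fit_target == "adc") "adc" else "attenuation"
  if (!(ycol %in% names(data))) {
    stop_dwssfp(sprintf("data must have a '%s' column for fit_target '%s'",
                        ycol, fit_target), class = "dwssfp_error_data")
  }
  y <- data[[ycol]]
  w <- rep(1, nrow(data))
  if (weights == "stderr") {
    if (!("stderr" %in% names(data)) || any(!is.finite(data$stderr)) ||
        any(data$stderr <= 0)) {
      stop_dwssfp("inverse-variance weighting needs a positive stderr column",
                  class = "dwssfp_error_data")
    }
    w <- 1 / data$stderr
  }

  predict_y <- function(dm, ds) {
    g <- gamma_diffusivity(dm, ds)
    if (fit_target == "adc") {
      predicted_adc_curve(g, p, tis, model = model, pulse = pulse,
                          flip_deg = data$flip_deg)$adc
    } else {
      ssfp_attenuation(p, tis, g = g, model = model, pulse = pulse,
                       flip_deg = data$flip_deg)
    }
  }

  if (is.null(start)) {
    dm0 <- if (fit_target == "adc") {
      data$adc[which.max(data$flip_deg)]
    } else {
      tryCatch(
        adc_from_attenuation(min(1, data$attenuation[which.max(data$flip_deg)]),
                             max(data$flip_deg), p, tis, model = model,
                             pulse = pulse),
        dwssfp_error = function(e) NA_real_)
    }
    if (!is.finite(dm0) || dm0 <= 0) {
      # fall back to a robust location when the top-flip point is unusable
      dm0 <- if (fit_target == "adc") {
        stats::median(data$adc[is.finite(data$adc) & data$adc > 0])
      } else {
        NA_real_
      }
    }
    if (!is.finite(dm0) || dm0 <= 0) dm0 <- 1e-4
    start <- c(dm = dm0, ds = dm0)
  }

  resid_fn <- function(par) {
    dm <- exp(par[1])
    ds <- exp(par[2])
    # keep the Levenberg-Marquardt trajectory inside the physically
    # meaningful region; outside it (or on model failure) return a flat
    # penalty so the step is rejected
    if (!is.finite(dm) || !is.finite(ds) || dm < 1e-9 || dm > 0.05 ||
        ds < 1e-12 || ds > 0.05) {
      return(rep(1e6, length(y)))
    }
    pred <- tryCatch(predict_y(dm, ds), dwssfp_error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, length(y)))
    w * (pred - y)
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(start[["dm"]], start[["ds"]])),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  if (fit$info %in% c(0, 5)) {
    rlang::abort(
      sprintf("gamma fit did not converge (LM info %d)", fit$info),
      class = c("dwssfp_error_convergence", "dwssfp_error"),
      residuals = fit$fvec)
  }
  dm <- exp(fit$par[1])
  ds <- exp(fit$par[2])
  # degenerate when the Gaussian limit (Ds -> 0) explains the data equally
  # well: the curve is flat and Ds is unidentified
  dev_fit <- sum(fit$fvec^2)
  dev_gauss <- sum((w * (predict_y(dm, dm * 1e-8) - y))^2)
  degenerate <- ds < 1e-6 * dm || ds < 1e-9 ||
    dev_gauss <= dev_fit * (1 + 1e-4) + 1e-30
  # covariance on the log scale, delta method to the linear scale
  cov_log <- tryCatch({
    dof <- max(1, nrow(data) - 2)
    s2 <- sum(fit$fvec^2) / dof
    s2 * solve(fit$hessian)
  }, error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(dm, ds))
  cov_lin <- J %*% cov_log %*% J
  dimnames(cov_lin) <- list(c("dm", "ds"), c("dm", "ds"))

  structure(
    list(dm = dm, ds = ds, cov = cov_lin,
         convergence = list(info = fit$info, message = fit$message,
                            niter = fit$niter,
                            deviance = sum(fit$fvec^2)),
         degenerate = degenerate,
         fitted = tibble::tibble(flip_deg = data$flip_deg, observed = y,
                                 fitted = predict_y(dm, ds)),
         data = data, model = model, fit_target = fit_target,
         weights = weights, pulse = pulse),
    class = "dwssfp_gamma_fit")
}

#' Run the DW-SSFP to DW-SE translation pipeline
#'
#' Chains the full inference: normalize the diffusion-weighted signal by the
#' reference signal, invert each flip angle's attenuation to an ADC with the
#' Gaussian model, fit the gamma diffusivity distribution (Dm, Ds) across
#' flip angles, and assign each flip angle the equivalent DW-SE b-value that
#' yields the same ADC under the shared distribution.
#'
#' @param signal_table A data frame with columns `flip_deg`, `s_dw`, `s_ref`
#'   (optionally `stderr`), e.g. from [generate_multiflip_dataset()] or
#'   [read_signal_table()].
#' @param p An [ssfp_protocol()].
#' @param tis A [tissue()] (T1, T2).
#' @param model DW-SSFP signal model.
#' @param fit_target Passed to [fit_gamma()]; `"adc"` by default.
#' @param b_max Bracket for the effective b-value search, s/mm^2.
#' @param weights Passed to [fit_gamma()].
#' @param pulse Gradient treatment for the coherence-order models.
#' @return An object of class `dwssfp_beff`: list with `per_flip` (tibble:
#'   `flip_deg`, `attenuation`, `adc`, `b_eff`), `fit` (the
#'   `dwssfp_gamma_fit`), and `provenance` (model, tolerances, package
#'   version).
#' @export
#' @examples
#' p <- ssfp_protocol(seq(10, 170, 10), 28.2, 13.56, q_per_cm = 300)
#' tis <- tissue(568, 19.8)
#' tbl <- generate_multiflip_dataset(gamma_diffusivity(1.5e-4, 2.1e-4), p, tis)
#' res <- run_translation_pipeline(tbl, p, tis)
#' glance(res)
run_translation_pipeline <- function(signal_table, p, tis,
                                     model = c("buxton", "two_period",
                                               "freed"),
                                     fit_target = c("adc", "signal"),
                                     b_max = 20000,
                                     weights = c("none", "stderr"),
                                     pulse = c("pulsed", "narrow")) {
  model <- match.arg(model)
  fit_target <- match.arg(fit_target)
  weights <- match.arg(weights)
  pulse <- match.arg(pulse)
  tbl <- validate_signal_table(signal_table)

  stage <- function(name, expr) {
    tryCatch(expr, dwssfp_error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s': %s", name,
                           conditionMessage(e)),
                   class = class(e), parent = e)
    })
  }

  n_clipped <- 0L
  att <- stage("attenuation", {
    a <- tbl$s_dw / tbl$s_ref
    if (any(a <= 0)) {
      stop_dwssfp("non-positive attenuations; apply noise handling first",
                  class = "dwssfp_error_data")
    }
    # noise can push near-unity attenuations above 1; clip and record
    n_clipped <- sum(a > 1)
    pmin(a, 1)
  })
  adc <- stage("adc_inversion", {
    vapply(seq_along(att), function(i) {
      tryCatch(
        adc_from_attenuation(att[i], tbl$flip_deg[i], p, tis, model = model,
                             pulse = pulse),
        # flips whose noisy attenuation no single diffusivity can explain
        # (typically dim high-flip signals) are dropped, not fatal
        dwssfp_error_bracket = function(e) NA_real_)
    }, numeric(1))
  })
  fit_data <- tibble::tibble(flip_deg = tbl$flip_deg, adc = adc,
                             attenuation = att)
  if ("stderr" %in% names(tbl)) fit_data$stderr <- tbl$stderr
  usable <- if (fit_target == "adc") !is.na(adc) else rep(TRUE, length(att))
  fit <- stage("gamma_fit",
               fit_gamma(fit_data[usable, ], p, tis, model = model,
                         pulse = pulse, fit_target = fit_target,
                         weights = weights))
  g <- gamma_diffusivity(fit$dm, fit$ds)
  b_eff <- stage("effective_bvalue", {
    # noisy per-flip ADCs can stray outside the invertible range
    # (adc_se_gamma(b_max), Dm]; those flips get NA rather than failing the
    # whole run, and the count is recorded
    lo <- adc_se_gamma(b_max, g)
    adc_c <- pmin(adc, fit$dm)          # numerical excess above Dm -> b = 0
    ok <- !is.na(adc_c) & adc_c >= lo
    out <- rep(NA_real_, length(adc_c))
    out[ok] <- effective_bvalue(adc_c[ok], g, b_max = b_max)
    out
  })

  structure(
    list(per_flip = tibble::tibble(flip_deg = tbl$flip_deg, attenuation = att,
                                   adc = adc, b_eff = b_eff),
         fit = fit,
         provenance = list(model = model, fit_target = fit_target,
                           b_max = b_max, weights = weights, pulse = pulse,
                           n_clipped = n_clipped,
                           n_adc_na = sum(is.na(adc)),
                           n_beff_na = sum(is.na(b_eff)),
                           package_version =
                             as.character(utils::packageVersion("dwssfp")))),
    class = "dwssfp_beff")
}

#' @export
print.dwssfp_gamma_fit <- function(x, ...) {
  cat("<gamma diffusivity fit>\n")
  cat(sprintf("  Dm = %.4g mm^2/s, Ds = %.4g mm^2/s (model: %s, target: %s)\n",
              x$dm, x$ds, x$model, x$fit_target))
  if (x$degenerate) {
    cat("  note: Ds pinned near zero - data consistent with Gaussian diffusion\n")
  }
  invisible(x)
}

#' @export
print.dwssfp_beff <- function(x, ...) {
  cat("<DW-SSFP effective b-value result>\n")
  cat(sprintf("  Dm = %.4g, Ds = %.4g mm^2/s; %d flip angles, b_eff %.0f-%.0f s/mm^2\n",
              x$fit$dm, x$fit$ds, nrow(x$per_flip),
              min(x$per_flip$b_eff), max(x$per_flip$b_eff)))
  print(x$per_flip)
  invisible(x)
}
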