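# Proton gyromagnetic ratio over 2*pi, in 1/(s*mT).
# q = gamma_bar * G * tau is then in cycles/mm, the convention in which
# b = q^2 * (Delta - tau/3) and A1 = exp(-q^2 * TR * D).
GAMMA_BAR <- 42577.478518

#' DW-SSFP acquisition protocol
#'
#' Describes one diffusion-weighted steady-state free precession (DW-SSFP)
#' acquisition: flip angle(s), repetition time, diffusion-gradient duration and
#' strength. Interface units follow the acquisition console (degrees,
#' milliseconds, cm^-1 or mT/m); values are converted once, here, to the
#' internal unit system (seconds, mm^-1).
#'
#' Either `q_per_cm` or `grad_mT_per_m` must be supplied; if the gradient
#' amplitude is given, q = (gamma/2pi) G tau is derived.
#'
#' @param flip_deg Flip angle(s) in degrees, each in (0, 180).
#' @param tr_ms Repetition time in ms.
#' @param tau_ms Diffusion-gradient duration in ms, 0 < tau < TR.
#' @param q_per_cm Diffusion-encoding wavenumber q in cm^-1 (cycles).
#' @param grad_mT_per_m Diffusion-gradient amplitude in mT/m.
#'
#' @return An object of class `ssfp_protocol` with fields `alpha` (radians),
#'   `flip_deg`, `tr`, `tau` (seconds), `q` (mm^-1), `grad` (mT/m or NA).
#' @export
#' @examples
#' ssfp_protocol(flip_deg = seq(10, 170, 10), tr_ms = 28.2, tau_ms = 13.56,
#'               q_per_cm = 300)
ssfp_protocol <- function(flip_deg, tr_ms, tau_ms, q_per_cm = NULL,
                          grad_mT_per_m = NULL) {
  stopifnot(is.numeric(flip_deg), length(flip_deg) >= 1)
  if (any(flip_deg <= 0 | flip_deg >= 180)) {
    stop_dwssfp("flip_deg must lie strictly within (0, 180) degrees",
                class = "dwssfp_error_protocol")
  }
  if (!is.numeric(tr_ms) || length(tr_ms) != 1 || tr_ms <= 0) {
    stop_dwssfp("tr_ms must be a single positive number (milliseconds)",
                class = "dwssfp_error_protocol")
  }
  if (!is.numeric(tau_ms) || length(tau_ms) != 1 || tau_ms <= 0 ||
      tau_ms >= tr_ms) {
    stop_dwssfp("tau_ms must satisfy 0 < tau < TR (milliseconds)",
                class = "dwssfp_error_protocol")
  }
  grad <- NA_real_
  if (!is.null(q_per_cm)) {
    if (q_per_cm < 0) {
      stop_dwssfp("q_per_cm must be >= 0", class = "dwssfp_error_protocol")
    }
    q <- q_per_cm * 0.1 # cm^-1 -> mm^-1
    if (!is.null(grad_mT_per_m)) grad <- grad_mT_per_m
  } else if (!is.null(grad_mT_per_m)) {
    if (grad_mT_per_m < 0) {
      stop_dwssfp("grad_mT_per_m must be >= 0",
                  class = "dwssfp_error_protocol")
    }
    grad <- grad_mT_per_m
    q <- GAMMA_BAR * (grad_mT_per_m / 1000) * (tau_ms / 1000) # mm^-1
  } else {
    stop_dwssfp("supply one of q_per_cm or grad_mT_per_m",
                class = "dwssfp_error_protocol")
  }
  structure(
    list(flip_deg = as.numeric(flip_deg),
         alpha = as.numeric(flip_deg) * pi / 180,
         tr = tr_ms / 1000, tau = tau_ms / 1000,
         q = q, grad = grad),
    class = "ssfp_protocol"
  )
}

#' DW-SE (pulsed-gradient spin-echo) protocol
#'
#' @param tau_ms Gradient-lobe duration in ms.
#' @param delta_ms Diffusion time Delta (lobe onset-to-onset) in ms;
#'   must satisfy Delta >= tau.
#' @param q_per_cm Encoding wavenumber in cm^-1 (cycles). May be omitted when
#'   the protocol is only used as a timing template (e.g. a b-value grid is
#'   supplied separately to the simulator).
#'
#' @return Object of class `se_protocol` with `tau`, `delta` (seconds),
#'   `q` (mm^-1) and the derived `b` (s/mm^2).
#' @export
se_protocol <- function(tau_ms, delta_ms, q_per_cm = 0) {
  if (tau_ms <= 0) {
    stop_dwssfp("tau_ms must be > 0", class = "dwssfp_error_protocol")
  }
  if (delta_ms < tau_ms) {
    stop_dwssfp("delta_ms must be >= tau_ms (gradient lobes cannot overlap)",
                class = "dwssfp_error_protocol")
  }
  if (q_per_cm < 0) {
    stop_dwssfp("q_per_cm must be >= 0", class = "dwssfp_error_protocol")
  }
  q <- q_per_cm * 0.1
  tau <- tau_ms / 1000
  delta <- delta_ms / 1000
  structure(
    list(tau = tau, delta = delta, q = q, b = q^2 * (delta - tau / 3)),
    class = "se_protocol"
  )
}

#' Tissue / sample properties
#'
#' @param t1_ms Longitudinal relaxation time in ms.
#' @param t2_ms Transverse relaxation time in ms, T2 <= T1.
#' @param d Diffusion coefficient in mm^2/s.
#' @param s0 Equilibrium magnetization (arbitrary signal units).
#'
#' @return Object of class `tissue` with `t1`, `t2` in seconds.
#' @export
tissue <- function(t1_ms, t2_ms, d = 0, s0 = 1) {
  if (t2_ms <= 0 || t1_ms < t2_ms) {
    stop_dwssfp("require T1 >= T2 > 0", class = "dwssfp_error_tissue")
  }
  if (d < 0) stop_dwssfp("d must be >= 0", class = "dwssfp_error_tissue")
  if (s0 <= 0) stop_dwssfp("s0 must be > 0", class = "dwssfp_error_tissue")
  structure(list(t1 = t1_ms / 1000, t2 = t2_ms / 1000, d = d, s0 = s0),
            class = "tissue")
}

#' Gamma distribution of diffusivities
#'
#' Two-parameter description of non-Gaussian diffusion: a continuous mixture
#' of Gaussian compartments whose diffusivities follow a gamma distribution
#' with mean `dm` and standard deviation `ds`. The shape is k = dm^2/ds^2 and
#' the scale theta = ds^2/dm; note that k < 1 whenever ds > dm, in which case
#' the density diverges (integrably) as D -> 0+.
#'
#' @param dm Mean diffusivity in mm^2/s.
#' @param ds Standard deviation of the diffusivity in mm^2/s.
#'
#' @return Object of class `gamma_diffusivity` with fields `dm`, `ds`,
#'   `shape`, `scale`.
#' @export
#' @examples
#' gamma_diffusivity(dm = 1.5e-4, ds = 2.1e-4)
gamma_diffusivity <- function(dm, ds) {
  if (!is.numeric(dm) || !is.numeric(ds) || dm <= 0 || ds <= 0) {
    stop_dwssfp("dm and ds must both be positive",
                class = "dwssfp_error_distribution")
  }
  structure(list(dm = dm, ds = ds, shape = dm^2 / ds^2, scale = ds^2 / dm),
            class = "gamma_diffusivity")
}

#' Steady-state relaxation and diffusion factors
#'
#' E1 = exp(-TR/T1), E2 = exp(-TR/T2), A1 = exp(-q^2 TR D),
#' A2 = exp(-q^2 tau D). A1 = A2^(TR/tau) by construction.
#'
#' @param p An [ssfp_protocol()].
#' @param t1,t2 Relaxation times in seconds.
#' @param d Diffusion coefficient in mm^2/s (scalar or vector).
#' @return List with numeric fields E1, E2, A1, A2.
#' @keywords internal
ss_factors <- function(p, t1, t2, d) {
  list(E1 = exp(-p$tr / t1), E2 = exp(-p$tr / t2),
       A1 = exp(-p$q^2 * p$tr * d), A2 = exp(-p$q^2 * p$tau * d))
}

stop_dwssfp <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dwssfp_error"))
}

#' @export
print.ssfp_protocol <- function(x, ...) {
  cat("<DW-SSFP protocol>\n")
  cat(sprintf("  flip angles: %s deg\n",
              paste(signif(x$flip_deg, 4), collapse = ", ")))
  cat(sprintf("  TR = %.4g ms, tau = %.4g ms, q = %.4g mm^-1 (%.4g cm^-1)\n",
              x$tr * 1000, x$tau * 1000, x$q, x$q * 10))
  invisible(x)
}

#' @export
print.gamma_diffusivity <- function(x, ...) {
  cat(sprintf(
    "<gamma diffusivity> Dm = %.4g mm^2/s, Ds = %.4g mm^2/s (k = %.4g, theta = %.4g)\n",
    x$dm, x$ds, x$shape, x$scale))
  invisible(x)
}
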