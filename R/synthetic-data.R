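#' Generate a multi-flip DW-SSFP dataset with known ground truth
#'
#' Forward-simulates diffusion-weighted and non-diffusion-weighted DW-SSFP
#' signals at every flip angle of the protocol, under either a gamma
#' distribution of diffusivities or a single diffusivity, optionally
#' corrupted with Rician noise. The default engine evaluates the analytic
#' signal models; `engine = "mc"` uses the Monte-Carlo simulator.
#'
#' @param truth A [gamma_diffusivity()] or a single diffusivity (mm^2/s).
#' @param p An [ssfp_protocol()] (paper-style default: 17 flips 10-170 deg,
#'   TR 28.2 ms, tau 13.56 ms, q 300 cm^-1).
#' @param tis A [tissue()].
#' @param snr Signal-to-noise ratio S0/sigma; `Inf` (default) for noise-free.
#' @param seed Seed for noise (and the MC engine).
#' @param engine `"analytic"` or `"mc"`.
#' @param model Signal model for the analytic engine.
#' @param n_spins,n_tr Monte-Carlo engine size parameters.
#' @return A signal table: tibble with columns `flip_deg`, `s_dw`, `s_ref`.
#' @export
#' @examples
#' p <- ssfp_protocol(seq(10, 170, 10), 28.2, 13.56, q_per_cm = 300)
#' generate_multiflip_dataset(gamma_diffusivity(1.5e-4, 2.1e-4), p,
#'                            tissue(568, 19.8))
generate_multiflip_dataset <- function(truth, p, tis, snr = Inf, seed = 1,
                                       engine = c("analytic", "mc"),
                                       model = c("buxton", "two_period",
                                                 "freed"),
                                       n_spins = 1e5, n_tr = 250) {
  stopifnot(inherits(p, "ssfp_protocol"), inherits(tis, "tissue"))
  engine <- match.arg(engine)
  model <- match.arg(model)
  if (snr <= 0) {
    stop_dwssfp("snr must be positive", class = "dwssfp_error_data")
  }
  g <- if (inherits(truth, "gamma_diffusivity")) truth else NULL
  d <- if (is.null(g)) {
    if (!is.numeric(truth) || truth < 0) {
      stop_dwssfp("truth must be a gamma_diffusivity or a diffusivity >= 0",
                  class = "dwssfp_error_data")
    }
    truth
  } else {
    NULL
  }

  if (engine == "analytic") {
    s_ref <- if (model == "freed") {
      ssfp_freed_signal(p, tis, d = 0)
    } else {
      tis$s0 * ssfp_signal_core(model, p$alpha, p, tis$t1, tis$t2, 0)
    }
    s_dw <- if (is.null(g)) {
      switch(model,
        two_period = ssfp_two_period_signal(p, tis, d = d),
        buxton = ssfp_buxton_signal(p, tis, d = d),
        freed = ssfp_freed_signal(p, tis, d = d))
    } else {
      ssfp_gamma_signal(p, tis, g, model = model)
    }
  } else {
    ens <- make_ensemble(n_spins, d = d, g = g, seed = seed)
    mc <- simulate_dwssfp_mc(ens, p, tis, n_tr = n_tr, seed = seed + 1L)
    s_dw <- mc$signal
    s_ref <- mc$signal_ref
  }

  tbl <- tibble::tibble(flip_deg = p$flip_deg, s_dw = s_dw, s_ref = s_ref)
  if (is.finite(snr)) {
    # noise scale anchored to the brightest reference signal: the steady-state
    # DW-SSFP signal is a small fraction of the equilibrium magnetization, so
    # anchoring sigma to S0 itself would leave no usable signal at any
    # conventional SNR
    s_scale <- max(tbl$s_ref)
    tbl$s_dw <- add_rician_noise(tbl$s_dw, snr, seed = seed, s0 = s_scale)
    tbl$s_ref <- add_rician_noise(tbl$s_ref, snr, seed = seed + 1L,
                                  s0 = s_scale)
  }
  tbl
}

#' Generate a multi-b DW-SE dataset with known ground truth
#'
#' Closed-form DW-SE signals over a b-value grid under a gamma distribution
#' of diffusivities (or a single D), with optional Rician noise.
#'
#' @param truth A [gamma_diffusivity()] or single diffusivity.
#' @param b_values b-value grid, s/mm^2.
#' @param s0 Equilibrium signal.
#' @param snr,seed As in [generate_multiflip_dataset()].
#' @return Tibble with columns `b`, `s_dw`, `s_ref` (`s_ref` = S at b = 0).
#' @export
generate_multib_dataset <- function(truth, b_values = seq(0, 14000, 1000),
                                    s0 = 1, snr = Inf, seed = 1) {
  s_dw <- if (inherits(truth, "gamma_diffusivity")) {
    dwse_signal_gamma(b_values, truth, s0 = s0)
  } else {
    s0 * exp(-b_values * truth)
  }
  tbl <- tibble::tibble(b = b_values, s_dw = s_dw, s_ref = s0)
  if (is.finite(snr)) {
    tbl$s_dw <- add_rician_noise(tbl$s_dw, snr, seed = seed, s0 = s0)
    tbl$s_ref <- add_rician_noise(tbl$s_ref, snr, seed = seed + 1L, s0 = s0)
  }
  tbl
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MR noise model: the noisy signal is |(S + n1) + i n2| with n1,
#' n2 independent zero-mean Gaussians of standard deviation sigma = s0/snr.
#' At S = 0 the result is Rayleigh with mean sigma sqrt(pi/2); at high SNR it
#' approaches S + Gaussian noise of SD sigma.
#'
#' @param signal Noise-free magnitude signal(s).
#' @param snr Signal-to-noise ratio defining sigma = s0/snr.
#' @param seed Integer seed.
#' @param s0 Reference signal defining the noise scale (default 1).
#' @return Noisy magnitudes, same length as `signal`.
#' @export
add_rician_noise <- function(signal, snr, seed = 1, s0 = 1) {
  if (snr <= 0) stop_dwssfp("snr must be > 0", class = "dwssfp_error_data")
  if (!is.finite(snr)) return(signal)
  sigma <- s0 / snr
  set.seed(seed)
  n1 <- stats::rnorm(length(signal), 0, sigma)
  n2 <- stats::rnorm(length(signal), 0, sigma)
  sqrt((signal + n1)^2 + n2^2)
}

#' Subtract the mean background signal
#'
#' Estimates the noise floor as the mean of magnitude values from a
#' signal-free region and removes it from every signal column, flooring at a
#' small positive epsilon (flagged in the `floored` attribute). This is the
#' standard first-order correction for the Rician noise floor of magnitude
#' data: the mean background of pure noise is sigma sqrt(pi/2).
#'
#' @param signal_table Tibble with signal columns `s_dw` and `s_ref` (others
#'   pass through).
#' @param background Numeric vector of background magnitudes.
#' @param floor_eps Lower floor applied after subtraction.
#' @return The corrected table; attribute `floored` counts floored entries.
#' @export
subtract_background <- function(signal_table, background,
                                floor_eps = 1e-9) {
  if (length(background) == 0 || all(!is.finite(background))) {
    stop_dwssfp("background set is empty", class = "dwssfp_error_data")
  }
  bg <- mean(background)
  tbl <- tibble::as_tibble(signal_table)
  floored <- 0L
  for (col in intersect(c("s_dw", "s_ref"), names(tbl))) {
    v <- tbl[[col]] - bg
    floored <- floored + sum(v < floor_eps)
    tbl[[col]] <- pmax(v, floor_eps)
  }
  attr(tbl, "floored") <- floored
  tbl
}

# Validate the signal-table contract shared by inference and I/O.
validate_signal_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("flip_deg", "s_dw", "s_ref")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_dwssfp(sprintf("signal table lacks column(s): %s",
                        paste(missing, collapse = ", ")),
                class = "dwssfp_error_data")
  }
  if (any(tbl$flip_deg <= 0 | tbl$flip_deg >= 180)) {
    stop_dwssfp("flip_deg must lie in (0, 180)", class = "dwssfp_error_data")
  }
  if (is.unsorted(tbl$flip_deg, strictly = TRUE)) {
    stop_dwssfp("flip_deg must be strictly increasing",
                class = "dwssfp_error_data")
  }
  if (any(tbl$s_dw <= 0 | tbl$s_ref <= 0)) {
    stop_dwssfp("signals must be positive", class = "dwssfp_error_data")
  }
  tbl
}
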