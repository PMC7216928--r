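#' Create a spin ensemble for Monte-Carlo simulation
#'
#' Spins occupy a 1-D voxel along the diffusion-gradient axis; each spin
#' carries its own diffusivity, either a shared constant or a draw from a
#' gamma distribution (the mechanism by which a gamma ensemble is built: free
#' Gaussian walks whose step variance is scaled per spin). Positions are
#' stratified uniformly over the voxel, which makes the reference (frozen)
#' run's dephasing sums exact.
#'
#' With `phase_groups = m > 1` the ensemble is built from `n_spins / m`
#' independent walkers, each replicated at m initial positions rotated by a
#' 1/m fraction of the voxel. Replicas share their displacement stream during
#' simulation, so the average over initial phase cancels all coherence orders
#' not divisible by m exactly -- a variance-reduction scheme that leaves the
#' estimator unbiased (the positions remain uniform and the per-spin
#' diffusivities remain gamma draws) while suppressing dephasing noise.
#'
#' @param n_spins Number of spins (must be divisible by `phase_groups`).
#' @param d Constant diffusivity (mm^2/s); ignored when `g` is given.
#' @param g Optional [gamma_diffusivity()]; per-walker D is drawn from it.
#' @param seed Integer seed; the ensemble is fully reproducible.
#' @param phase_groups Number of phase-rotated replicas per walker (1 = plain
#'   independent spins).
#' @param d_sampling `"quantile"` (default) assigns diffusivities from a
#'   stratified grid of gamma quantiles in random order, so the ensemble's
#'   empirical distribution matches the target essentially exactly;
#'   `"random"` uses independent draws.
#' @return Object of class `spin_ensemble`: list with `u` (positions on the
#'   unit interval, scaled to the voxel width at simulation time), `d`
#'   (per-spin diffusivity), `walker` (index of the shared displacement
#'   stream), `n_walkers`, `n_spins`, `phase_groups`, `seed`, `gamma`.
#' @export
#' @examples
#' ens <- make_ensemble(1e4, g = gamma_diffusivity(1.5e-4, 2.1e-4), seed = 1)
#' mean(ens$d)
make_ensemble <- function(n_spins, d = NULL, g = NULL, seed = 1,
                          phase_groups = 1L,
                          d_sampling = c("quantile", "random")) {
  stopifnot(n_spins >= 1, phase_groups >= 1)
  d_sampling <- match.arg(d_sampling)
  if (is.null(d) && is.null(g)) {
    stop_dwssfp("supply a constant d or a gamma_diffusivity g",
                class = "dwssfp_error_data")
  }
  if (!is.null(g)) stopifnot(inherits(g, "gamma_diffusivity"))
  m <- as.integer(phase_groups)
  if (n_spins %% m != 0) {
    stop_dwssfp("n_spins must be divisible by phase_groups",
                class = "dwssfp_error_data")
  }
  n_w <- as.integer(n_spins / m)
  set.seed(seed)
  d_w <- if (!is.null(g)) {
    if (d_sampling == "quantile") {
      sample(stats::qgamma((seq_len(n_w) - 0.5) / n_w, shape = g$shape,
                           scale = g$scale))
    } else {
      stats::rgamma(n_w, shape = g$shape, scale = g$scale)
    }
  } else {
    if (d < 0) stop_dwssfp("d must be >= 0", class = "dwssfp_error_data")
    rep(d, n_w)
  }
  # walker j sits at stratified offsets within its 1/m slice, replicated at
  # the m rotations; the union is a stratified uniform grid over the voxel
  u_w <- (seq_len(n_w) - 0.5) / n_w / m
  u <- rep(u_w, m) + rep((seq_len(m) - 1) / m, each = n_w)
  structure(list(u = u, d = rep(d_w, m), walker = rep(seq_len(n_w), m),
                 d_walker = d_w, n_walkers = n_w,
                 n_spins = as.integer(n_spins), phase_groups = m,
                 seed = as.integer(seed), gamma = g),
            class = "spin_ensemble")
}

# One steady-state DW-SSFP run for a single flip angle. Narrow-pulse
# treatment: per TR the spin takes one Gaussian step of variance 2 D TR and
# the gradient imparts transverse phase q*x as an impulse; relaxation is
# lumped per TR; the echo is read after the gradient, before the next RF.
# `diffuse = FALSE` freezes the spins (the D = 0 reference run), in which
# case the per-TR phase rotation is hoisted out of the loop.
# Returns the final-TR complex transverse magnetization per spin.
mc_ssfp_run <- function(x, ens, alpha, tr, q, t1, t2, n_tr, diffuse = TRUE) {
  n <- length(x)
  E1 <- exp(-tr / t1)
  E2 <- exp(-tr / t2)
  sa <- sin(alpha)
  ca <- cos(alpha)
  sd_w <- sqrt(2 * ens$d_walker * tr)
  wk <- ens$walker
  mx <- numeric(n)
  my <- numeric(n)
  mz <- rep(1, n)
  if (!diffuse) {
    ph <- q * x
    cp <- cos(ph)
    sp <- sin(ph)
  }
  for (k in seq_len(n_tr)) {
    my_new <- my * ca + mz * sa          # RF about the x-axis
    mz <- -my * sa + mz * ca
    my <- my_new
    if (diffuse) {
      x <- x + stats::rnorm(ens$n_walkers, 0, sd_w)[wk]
      ph <- q * x                        # impulse gradient
      cp <- cos(ph)
      sp <- sin(ph)
    }
    mx_new <- mx * cp - my * sp
    my <- mx * sp + my * cp
    mx <- mx_new
    mx <- mx * E2
    my <- my * E2
    mz <- mz * E1 + (1 - E1)
  }
  complex(real = mx, imaginary = my)
}

# Standard error of a ratio of coherent amplitudes from walker binning:
# complete replica sets stay in one bin, bin means are projected on the
# overall phase, and the spread of per-bin ratios gives the SE.
mc_ratio_se <- function(m_dw, m_ref, ens, n_bins = 50) {
  n_bins <- min(n_bins, ens$n_walkers)
  bin <- ((ens$walker - 1L) %% n_bins) + 1L
  p_dw <- exp(-1i * Arg(mean(m_dw)))
  p_ref <- exp(-1i * Arg(mean(m_ref)))
  a_b <- Re(vapply(split(m_dw, bin), mean, complex(1)) * p_dw) /
         Re(vapply(split(m_ref, bin), mean, complex(1)) * p_ref)
  stats::sd(a_b) / sqrt(n_bins)
}

#' Monte-Carlo simulation of the DW-SSFP sequence
#'
#' Vectorized spin-walk simulation: per TR one RF rotation, one Gaussian
#' displacement step of variance 2 D TR, one impulse diffusion gradient
#' imparting phase q x, and lumped E1/E2 relaxation; the echo is sampled
#' after the gradient at the final TR (250 TRs by default, enough for the
#' steady state). The voxel spans one full phase wrap (width 2 pi / q) so the
#' gradient fully dephases unrefocused magnetization. Each flip angle is
#' paired with a reference run of the same ensemble with diffusion frozen
#' (D = 0), reproducing how non-diffusion-weighted data are simulated; the
#' attenuation is their ratio.
#'
#' @param ens A [make_ensemble()] ensemble.
#' @param p An [ssfp_protocol()] (its flip angles are simulated).
#' @param tis A [tissue()] (T1, T2; its `d` is ignored in favour of the
#'   ensemble's).
#' @param n_tr Number of TRs simulated before the echo is read. Values < 100
#'   trigger a transient warning recorded in the result.
#' @param seed Seed for the displacement stream (distinct from the ensemble
#'   seed so repeated simulations of one ensemble are reproducible).
#' @return Object of class `mc_result`: tibble with columns `flip_deg`,
#'   `signal`, `signal_ref`, `attenuation`, `stderr` (standard error of the
#'   attenuation from walker binning), plus attributes `n_spins`, `n_steps`,
#'   `seed`, `warnings`.
#' @export
simulate_dwssfp_mc <- function(ens, p, tis, n_tr = 250, seed = 1) {
  stopifnot(inherits(ens, "spin_ensemble"), inherits(p, "ssfp_protocol"),
            inherits(tis, "tissue"))
  if (n_tr < 1) stop_dwssfp("n_tr must be >= 1", class = "dwssfp_error_data")
  warn <- character(0)
  if (n_tr < 100) {
    warn <- c(warn, sprintf(
      "n_tr = %d may not reach steady state; 250 is the reference choice",
      n_tr))
  }
  if (p$q <= 0) {
    stop_dwssfp(
      paste0("q = 0 leaves unrefocused magnetization undephased (banding ",
             "regime); simulate the reference by freezing diffusion instead"),
      class = "dwssfp_error_data")
  }
  L <- 2 * pi / p$q
  x0 <- ens$u * L

  rows <- purrr::map_dfr(seq_along(p$alpha), function(i) {
    a <- p$alpha[i]
    set.seed(seed + 1000L * i)
    m_dw <- mc_ssfp_run(x0, ens, a, p$tr, p$q, tis$t1, tis$t2, n_tr,
                        diffuse = TRUE)
    m_ref <- mc_ssfp_run(x0, ens, a, p$tr, p$q, tis$t1, tis$t2, n_tr,
                         diffuse = FALSE)
    s_dw <- abs(mean(m_dw))
    s_ref <- abs(mean(m_ref))
    tibble::tibble(flip_deg = p$flip_deg[i],
                   signal = s_dw, signal_ref = s_ref,
                   attenuation = s_dw / s_ref,
                   stderr = mc_ratio_se(m_dw, m_ref, ens))
  })
  structure(rows, class = c("mc_result", class(rows)),
            n_spins = ens$n_spins, n_steps = n_tr, seed = seed,
            warnings = warn)
}

#' Monte-Carlo simulation of the DW-SE sequence
#'
#' Simulates pulsed-gradient spin-echo attenuation with continuous phase
#' accrual: Gaussian steps of variance 2 D dt; during each gradient lobe the
#' phase advances by (q/tau) x dt, with the sign flipped after the refocusing
#' pulse. The b-value grid is realized by changing the gradient amplitude at
#' fixed timing, and b is computed with [stejskal_tanner_b()]. Relaxation
#' cancels in the attenuation and is not simulated.
#'
#' @param ens A [make_ensemble()] ensemble (phase replicas are ignored here:
#'   balanced lobes already cancel the initial-position phase).
#' @param p An [se_protocol()] providing tau and Delta.
#' @param b_values b-value grid in s/mm^2.
#' @param dt Time step in seconds (0.4 ms by default); must divide tau and
#'   Delta to within 1%, and dt > tau/10 triggers an accuracy warning.
#' @param seed Seed for the displacement stream.
#' @return Object of class `mc_result`: tibble with columns `b`, `signal`
#'   (attenuation), `stderr`.
#' @export
simulate_dwse_mc <- function(ens, p, b_values, dt = 4e-4, seed = 1) {
  stopifnot(inherits(ens, "spin_ensemble"), inherits(p, "se_protocol"))
  if (any(b_values < 0)) {
    stop_dwssfp("b_values must be >= 0", class = "dwssfp_error_data")
  }
  n_tau <- p$tau / dt
  n_gap <- (p$delta - p$tau) / dt
  if (abs(n_tau - round(n_tau)) > 0.01 * max(1, round(n_tau)) ||
      abs(n_gap - round(n_gap)) > 0.01 * max(1, round(n_gap))) {
    stop_dwssfp("dt must divide tau and Delta - tau (within 1%)",
                class = "dwssfp_error_data")
  }
  if (dt > p$tau / 10) {
    warning("dt > tau/10: gradient-lobe discretization may bias attenuation")
  }
  n_tau <- as.integer(round(n_tau))
  n_gap <- as.integer(round(n_gap))
  n <- ens$n_spins
  sdstep <- sqrt(2 * ens$d * dt)
  n_bins <- min(100L, n)
  grp <- rep(seq_len(n_bins), length.out = n)

  rows <- purrr::map_dfr(seq_along(b_values), function(j) {
    b <- b_values[j]
    q_b <- sqrt(b / (p$delta - p$tau / 3)) # wavenumber realizing this b
    gmom <- q_b / p$tau * dt               # phase increment rate * dt
    set.seed(seed + 1000L * j)
    # balanced lobes cancel any constant position offset, so the origin is
    # immaterial: start all spins at 0 and track displacements only
    x <- numeric(n)
    phi <- numeric(n)
    for (k in seq_len(n_tau)) {            # first lobe
      x <- x + stats::rnorm(n, 0, sdstep)
      phi <- phi + gmom * x
    }
    for (k in seq_len(n_gap)) {            # free interval + refocusing
      x <- x + stats::rnorm(n, 0, sdstep)
    }
    for (k in seq_len(n_tau)) {            # second lobe (sign flipped)
      x <- x + stats::rnorm(n, 0, sdstep)
      phi <- phi - gmom * x
    }
    m <- exp(1i * phi)
    s_g <- vapply(split(m, grp), mean, complex(1))
    s <- abs(mean(m))
    proj <- Re(s_g * exp(-1i * Arg(mean(m))))
    tibble::tibble(b = b, signal = s,
                   stderr = stats::sd(proj) / sqrt(n_bins))
  })
  structure(rows, class = c("mc_result", class(rows)),
            n_spins = ens$n_spins, n_steps = 2L * n_tau + n_gap, seed = seed,
            warnings = character(0))
}

#' One Gaussian diffusion step between two reflecting barriers
#'
#' Takes a Gaussian step of variance 2 D dt for every spin and applies
#' specular reflection at the walls x = 0 and x = a (any number of
#' reflections, via folding of the triangle map), so the uniform stationary
#' distribution on (0, a) is preserved and no spin is lost.
#'
#' @param ens A [make_ensemble()] ensemble whose positions `u` must already
#'   lie within (0, a).
#' @param a Barrier spacing in mm.
#' @param dt Time step in seconds.
#' @return The ensemble with updated positions.
#' @export
reflecting_barrier_step <- function(ens, a, dt) {
  stopifnot(inherits(ens, "spin_ensemble"))
  if (a <= 0) stop_dwssfp("a must be > 0", class = "dwssfp_error_data")
  if (any(ens$u < 0 | ens$u > a)) {
    stop_dwssfp("positions must lie within [0, a]; rescale ens$u first",
                class = "dwssfp_error_data")
  }
  step <- stats::rnorm(ens$n_spins, 0, sqrt(2 * ens$d * dt))
  if (sqrt(2 * max(ens$d) * dt) > a) {
    warning("step length comparable to barrier spacing; reflections still conserve spins")
  }
  x <- ens$u + step
  x <- x %% (2 * a)                       # fold onto the reflected tiling
  x <- ifelse(x > a, 2 * a - x, x)
  ens$u <- x
  ens
}
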