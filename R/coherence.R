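# Exact steady state of the DW-SSFP sequence by coherence-order expansion.
#
# States just before each RF pulse: transverse amplitudes f_p (coherence order
# p in gradient-moment units, p in -P..P) and longitudinal amplitudes z_p
# (p in 0..P; z_{-p} = z_p with the real phase convention used here).
# One TR consists of: RF(alpha) about a fixed axis, then relaxation and free
# diffusion while the gradient lobe (duration tau, at the end of the TR)
# shifts every transverse order by +1. The echo is the order-0 transverse
# amplitude just before the next RF, i.e. sampled after the gradient.
#
# Free diffusion in the (piecewise-constant) gradient attenuates a transverse
# state entering a TR at order p by A1^(p^2) * A2^(p + 1/3) and a stored
# longitudinal state of order p by A1^(p^2), with A1 = exp(-q^2 TR D),
# A2 = exp(-q^2 tau D). Setting `pulse = "narrow"` drops the intra-gradient
# term A2^(p + 1/3) (impulse gradient, one diffusion step per TR), which is
# the model realized exactly by the Monte-Carlo engine.
#
# Truncating at order P and solving the resulting linear system is the
# backward-elimination (continued-fraction) evaluation of the steady-state
# recursion at depth P; P is increased until the echo amplitude converges.

ssfp_steady_state_exact <- function(alpha, tr, tau, q, t1, t2, d,
                                    order = 60, pulse = c("pulsed", "narrow"),
                                    clamp_order = NULL) {
  pulse <- match.arg(pulse)
  E1 <- exp(-tr / t1)
  E2 <- exp(-tr / t2)
  P <- as.integer(order)
  c2 <- cos(alpha / 2)^2
  s2 <- sin(alpha / 2)^2
  t  <- sin(alpha)
  ca <- cos(alpha)

  sig <- q^2 * d
  # transverse interval entering at order p (then shifted to p + 1); with
  # clamp_order = m the diffusion attenuation of orders beyond m is frozen at
  # its order-m value (the geometric-tail closure of the Buxton-type closed
  # form: low orders exact, deep pathways attenuated geometrically)
  eps <- function(p) {
    if (!is.null(clamp_order)) p <- pmax(pmin(p, clamp_order),
                                         -clamp_order - 1L)
    att <- exp(-sig * tr * p^2)
    if (pulse == "pulsed") att <- att * exp(-sig * tau * (p + 1 / 3))
    E2 * att
  }
  eta <- function(p) {
    if (!is.null(clamp_order)) p <- pmin(p, clamp_order)
    E1 * exp(-sig * tr * p^2)
  }

  nf <- 2L * P + 1L           # f_{-P}..f_{P}
  nz <- P + 1L                # z_0..z_P
  n  <- nf + nz
  fi <- function(p) p + P + 1L      # index of f_p
  zi <- function(p) nf + p + 1L     # index of z_p (p >= 0)

  A <- matrix(0, n, n)
  b <- numeric(n)

  # f_p = eps(p-1) * [c2 f_{p-1} - s2 f_{-(p-1)} + t z_{|p-1|}]
  for (p in (-P):P) {
    i <- fi(p)
    A[i, i] <- 1
    pm <- p - 1L
    if (abs(pm) <= P) {
      e <- eps(pm)
      A[i, fi(pm)]  <- A[i, fi(pm)]  - e * c2
      A[i, fi(-pm)] <- A[i, fi(-pm)] + e * s2
      A[i, zi(abs(pm))] <- A[i, zi(abs(pm))] - e * t
    }
  }
  # z_p = eta(p) * [ca z_p - (t/2)(f_p + f_{-p})] + (1 - E1) delta_{p0}
  for (p in 0:P) {
    i <- zi(p)
    h <- eta(p)
    A[i, i] <- 1 - h * ca
    A[i, fi(p)]  <- A[i, fi(p)]  + h * t / 2
    A[i, fi(-p)] <- A[i, fi(-p)] + h * t / 2
    if (p == 0L) b[i] <- 1 - E1
  }

  x <- solve(A, b)
  list(echo = x[fi(0L)], f = x[seq_len(nf)], z = x[nf + seq_len(nz)])
}

# Echo magnitude (M0 = 1) with automatic order refinement: the truncation
# order is doubled until successive depths agree to `rtol` relative.
ssfp_exact_echo <- function(alpha, tr, tau, q, t1, t2, d,
                            order = NULL, pulse = "pulsed",
                            rtol = 1e-10, max_order = 800,
                            clamp_order = NULL) {
  if (!is.null(order)) {
    return(abs(ssfp_steady_state_exact(alpha, tr, tau, q, t1, t2, d,
                                       order = order, pulse = pulse,
                                       clamp_order = clamp_order)$echo))
  }
  P <- 24L
  prev <- abs(ssfp_steady_state_exact(alpha, tr, tau, q, t1, t2, d,
                                      order = P, pulse = pulse,
                                      clamp_order = clamp_order)$echo)
  repeat {
    P <- 2L * P
    cur <- abs(ssfp_steady_state_exact(alpha, tr, tau, q, t1, t2, d,
                                       order = P, pulse = pulse,
                                       clamp_order = clamp_order)$echo)
    if (abs(cur - prev) <= rtol * max(abs(cur), .Machine$double.xmin)) {
      return(cur)
    }
    if (P > max_order) {
      stop_dwssfp(
        sprintf("coherence-order expansion did not converge by order %d", P),
        class = "dwssfp_error_convergence")
    }
    prev <- cur
  }
}

# Buxton-type closed evaluation: coherence orders |p| <= p_star treated
# exactly, the infinite tail summed under frozen (geometric) attenuation
# factors via the decaying invariant subspace of the constant transfer
# matrix. Equivalent to the clamped-factor steady-state solve, but O(1):
# an 8x8 system plus a 3x3 eigenproblem for p_star = 2. Near alpha = 180 deg
# the transfer-matrix elimination becomes ill-conditioned (c^2 - t g -> 0)
# and the clamped large-order solve is used instead.
ssfp_buxton_echo <- function(alpha, tr, tau, q, t1, t2, d,
                             p_star = 2L, pulse = "pulsed") {
  E1 <- exp(-tr / t1)
  E2 <- exp(-tr / t2)
  sig <- q^2 * d
  eps <- function(p) {
    att <- exp(-sig * tr * p^2)
    if (pulse == "pulsed") att <- att * exp(-sig * tau * (p + 1 / 3))
    E2 * att
  }
  eta <- function(p) E1 * exp(-sig * tr * p^2)
  c2 <- cos(alpha / 2)^2
  s2 <- sin(alpha / 2)^2
  t  <- sin(alpha)
  ca <- cos(alpha)
  P <- as.integer(p_star)

  hP <- eta(P)
  g <- hP * (t / 2) / (1 - hP * ca)
  if (abs(c2 - t * g) < 1e-6) {
    # fall back to the clamped-factor large-order solve
    return(ssfp_exact_echo(alpha, tr, tau, q, t1, t2, d, pulse = pulse,
                           clamp_order = P))
  }

  nf <- 2L * P + 1L
  nz <- P + 1L
  n  <- nf + nz
  fi <- function(p) p + P + 1L
  zi <- function(p) nf + p + 1L
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (p in (-P + 1L):P) {
    i <- fi(p)
    pm <- p - 1L
    A[i, i] <- A[i, i] + 1
    e <- eps(pm)
    A[i, fi(pm)]  <- A[i, fi(pm)]  - e * c2
    A[i, fi(-pm)] <- A[i, fi(-pm)] + e * s2
    A[i, zi(abs(pm))] <- A[i, zi(abs(pm))] - e * t
  }
  for (p in 0:P) {
    i <- zi(p)
    h <- eta(p)
    A[i, i] <- 1 - h * ca
    A[i, fi(p)]  <- A[i, fi(p)]  + h * t / 2
    A[i, fi(-p)] <- A[i, fi(-p)] + h * t / 2
    if (p == 0L) b[i] <- 1 - E1
  }
  # constant tail transfer matrix for v_p = (f_p, f_{-p}, z_p), p >= P
  epP <- eps(P)
  emP <- eps(-(P + 1L))
  M <- matrix(0, 3, 3)
  M[1, ] <- epP * c(c2, -s2, t)
  M[2, ] <- (c(0, 1 / emP, 0) + (s2 + t * g) * M[1, ]) / (c2 - t * g)
  M[3, ] <- -g * (M[1, ] + M[2, ])
  ev <- eigen(t(M))
  grow <- which(abs(ev$values) >= 1 - 1e-12)
  if (length(grow) != 1L) {
    return(ssfp_exact_echo(alpha, tr, tau, q, t1, t2, d, pulse = pulse,
                           clamp_order = P))
  }
  l <- Re(ev$vectors[, grow])
  closure <- numeric(n)
  closure[fi(P)] <- l[1]
  closure[fi(-P)] <- l[2]
  closure[zi(P)] <- l[3]
  Afull <- rbind(A[-fi(-P), , drop = FALSE], closure)
  bfull <- c(b[-fi(-P)], 0)
  x <- tryCatch(solve(Afull, bfull), error = function(e) NULL)
  if (is.null(x)) {
    return(ssfp_exact_echo(alpha, tr, tau, q, t1, t2, d, pulse = pulse,
                           clamp_order = P))
  }
  abs(x[fi(0L)])
}
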