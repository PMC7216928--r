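# Shared fixtures: the acquisition and tissue parameters used throughout
# (whole-protocol multi-flip DW-SSFP at 7T-postmortem-like conditions).

paper_protocol <- function(flips = seq(10, 170, 10)) {
  ssfp_protocol(flip_deg = flips, tr_ms = 28.2, tau_ms = 13.56,
                q_per_cm = 300)
}

fig1_protocol <- function(flips = 60) {
  ssfp_protocol(flip_deg = flips, tr_ms = 28.2, tau_ms = 13.56,
                q_per_cm = 300)
}

cc_tissue <- function(d = 0) tissue(t1_ms = 568, t2_ms = 19.8, d = d)

fig1_tissue <- function(d = 3.5e-4) tissue(t1_ms = 600, t2_ms = 20, d = d)

cc_gamma <- function() gamma_diffusivity(dm = 1.5e-4, ds = 2.1e-4)

# Independent brute-force oracle for the two-transverse-period model:
# term-by-term pathway summation, truncated when terms drop below 1e-15.
two_period_bruteforce <- function(flip_deg, tr_ms, q_per_mm, t1_ms, t2_ms, d,
                                  s0 = 1) {
  a <- flip_deg * pi / 180
  tr <- tr_ms / 1000
  E1 <- exp(-tr / (t1_ms / 1000))
  E2 <- exp(-tr / (t2_ms / 1000))
  A1 <- exp(-q_per_mm^2 * tr * d)
  mz <- s0 * (1 - E1) / (1 - E1 * cos(a))
  total <- mz * E2^2 * sin(a) * (1 - cos(a)) / 2 * A1   # spin-echo pathway
  n <- 1
  repeat {
    term <- mz * E2^2 * sin(a)^3 / 2 * E1^n * cos(a)^(n - 1) * A1^(n + 1)
    total <- total + term
    if (abs(term) < 1e-15 || n > 10000) break
    n <- n + 1
  }
  abs(total)
}
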