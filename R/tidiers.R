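#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gamma diffusivity fit
#'
#' @param x A `dwssfp_gamma_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy dwssfp_gamma_fit
#' @export
tidy.dwssfp_gamma_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tibble::tibble(term = c("dm", "ds"),
                 estimate = c(x$dm, x$ds),
                 std.error = as.numeric(se))
}

#' Fit-level summary of a gamma diffusivity fit
#'
#' @param x A `dwssfp_gamma_fit`.
#' @param ... Unused.
#' @return One-row tibble: `dm`, `ds`, `deviance`, `n`, `degenerate`,
#'   `converged`.
#' @method glance dwssfp_gamma_fit
#' @export
glance.dwssfp_gamma_fit <- function(x, ...) {
  tibble::tibble(dm = x$dm, ds = x$ds,
                 deviance = x$convergence$deviance,
                 n = nrow(x$data),
                 degenerate = x$degenerate,
                 converged = !x$convergence$info %in% c(0, 5))
}

#' Per-flip-angle view of a translation result
#'
#' @param x A `dwssfp_beff`.
#' @param ... Unused.
#' @return Tibble with `flip_deg`, `attenuation`, `adc`, `b_eff`.
#' @method tidy dwssfp_beff
#' @export
tidy.dwssfp_beff <- function(x, ...) x$per_flip

#' Summary of a translation result
#'
#' @param x A `dwssfp_beff`.
#' @param ... Unused.
#' @return One-row tibble: fitted `dm`, `ds`, b-value range covered, model.
#' @method glance dwssfp_beff
#' @export
glance.dwssfp_beff <- function(x, ...) {
  tibble::tibble(dm = x$fit$dm, ds = x$fit$ds,
                 b_eff_min = min(x$per_flip$b_eff),
                 b_eff_max = max(x$per_flip$b_eff),
                 n_flips = nrow(x$per_flip),
                 model = x$provenance$model)
}
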