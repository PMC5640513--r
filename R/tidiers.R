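#' Turn a fitted object into a tidy tibble
#'
#' Broom-style generics for this package's fitted objects ([tidy()] for
#' per-component rows, [glance()] for a one-row model summary).
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(term = "Ea", estimate = x$Ea, unit = "MPa")
}

#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(Ea = x$Ea, delta_max = x$delta_max, rms = x$rms,
                 n = x$n, flag = x$flag)
}

#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p_value, method = x$method,
                 n_a = x$n[1], n_b = x$n[2])
}

#' @export
glance.mw_test <- tidy.mw_test

#' @export
tidy.gc_solution <- function(x, ...) {
  aperture_curve(x)
}

#' @export
glance.gc_solution <- function(x, ...) {
  cv <- aperture_curve(x)
  tibble::tibble(
    variant = if (x$fixed_poles) "fixed_poles" else "baseline_bc",
    cross_section = x$mesh$params$cross_section_kind,
    steps = nrow(x$steps),
    P_gc_max = x$protocol$P_gc_max,
    converged = all(x$steps$converged),
    max_residual_nN = max(x$steps$residual_nN),
    opening_threshold = opening_threshold(cv),
    plateau_onset = plateau_onset(cv),
    max_aperture = max(cv$aperture)
  )
}

#' @export
tidy.gc_gradient <- function(x, ...) {
  if (x$flag != "ok") {
    return(tibble::tibble(cell = integer(0), gradient = numeric(0)))
  }
  tibble::tibble(cell = c(1L, 2L), gradient = x$per_cell)
}

#' @export
glance.gc_gradient <- function(x, ...) {
  tibble::tibble(gradient = x$gradient, n_peaks = x$n_peaks, flag = x$flag)
}

#' @export
tidy.gc_afm_study <- function(x, ...) x$gradients

#' @export
glance.gc_afm_study <- function(x, ...) {
  tibble::tibble(median_mature = x$median_mature,
                 median_young = x$median_young,
                 U = x$test$U, p_value = x$test$p_value,
                 n_excluded = x$n_excluded)
}
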