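# broom-style tidy()/glance() methods for fitted and comparison objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DCS coherence calibration
#'
#' @param x A `dcs_calibration` from [calibrate_beta()].
#' @param ... Ignored.
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.dcs_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "bfi"),
    estimate = c(x$beta, x$bfi)
  )
}

#' @rdname tidy.dcs_calibration
#' @export
glance.dcs_calibration <- function(x, ...) {
  tibble::tibble(beta = x$beta, bfi = x$bfi, residual = x$residual,
                 n_curves = x$n_curves)
}

#' Tidy a nonparametric Bland-Altman result
#'
#' @param x A `bland_altman` from [bland_altman_nonparametric()].
#' @param ... Ignored.
#' @return A one-row tibble with `bias`, `loa_low`, `loa_high`, `rpc`,
#'   `n`, `n_dropped`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 rpc = x$rpc, n = x$n, n_dropped = x$n_dropped)
}

#' Tidy a paired modality comparison
#'
#' @param x A `modality_comparison` from [paired_group_tests()].
#' @param ... Ignored.
#' @return The pairwise table (Wilcoxon p, Pearson r, linear fit) as a
#'   tibble.
#' @export
tidy.modality_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.modality_comparison
#' @export
glance.modality_comparison <- function(x, ...) {
  tibble::tibble(friedman_p = x$friedman_p, n_runs = x$n_runs,
                 n_excluded = x$n_excluded)
}
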