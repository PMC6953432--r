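#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a robust test result
#'
#' @param x a `robust_htest` from [yuen_boot()], [yuen_paired()] or
#'   [t1way_boot()].
#' @param ... unused.
#' @return One-row tibble with `statistic`, `p.value`, `estimate`,
#'   `conf.low`, `conf.high`, `method`.
#' @method tidy robust_htest
#' @export
tidy.robust_htest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value, estimate = x$estimate,
    conf.low = x$conf_int[1], conf.high = x$conf_int[2], method = x$method)
}

#' Glance at a robust test result
#'
#' @inheritParams tidy.robust_htest
#' @return One-row tibble with `p.value`, `trim`, `n.boot`, `seed`.
#' @method glance robust_htest
#' @export
glance.robust_htest <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, trim = x$trim, n.boot = x$n_boot,
                 seed = x$seed)
}

#' Tidy a repeated-CV classification result
#'
#' @param x a `knn_cv` from [tune_and_score()].
#' @param ... unused.
#' @return Tibble with one row per iteration: `iteration`, `accuracy` and
#'   the chosen hyper-parameters.
#' @method tidy knn_cv
#' @export
tidy.knn_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(iteration = seq_len(x$n_iter), accuracy = x$accuracies),
    x$params)
}

#' Glance at a repeated-CV classification result
#'
#' @inheritParams tidy.knn_cv
#' @return One-row tibble with `median.accuracy`, `n.iter`, `seed`.
#' @method glance knn_cv
#' @export
glance.knn_cv <- function(x, ...) {
  tibble::tibble(median.accuracy = x$median_accuracy, n.iter = x$n_iter,
                 seed = x$seed)
}

#' Band powers of a spectrum as a tibble
#'
#' @param x a `power_spectrum` from [concatenated_welch()].
#' @param ... unused.
#' @return One-row tibble with theta/beta/gamma powers (uV^2).
#' @method glance power_spectrum
#' @export
glance.power_spectrum <- function(x, ...) {
  bp <- attr(x, "band_powers")
  tibble::as_tibble(as.list(bp))
}

#' Band summary of a spike-triggered power result
#'
#' @param x a `coupling_result` from [spike_triggered_relative_power()].
#' @param ... unused.
#' @return One-row tibble with `beta`, `gamma` mean relative power,
#'   `n.spikes`, `n.skipped`.
#' @method glance coupling_result
#' @export
glance.coupling_result <- function(x, ...) {
  s <- attr(x, "band_summary")
  tibble::tibble(beta = s[["beta"]], gamma = s[["gamma"]],
                 n.spikes = attr(x, "n_spikes"),
                 n.skipped = attr(x, "n_skipped"))
}
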