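.COHORT_FEATURES <- c("beta_power", "gamma_power", "log10_firing_rate",
                      "st_beta_power", "st_gamma_power")

#' Generate a two-class feature cohort
#'
#' Per-animal feature vectors (by default the five superficial-layer
#' electrophysiological features used for phenotype classification: LFP beta
#' and gamma band power, log10 firing rate, spike-triggered relative LFP
#' power in beta and gamma) drawn from group-specific Gaussians with unit
#' within-group SD. `effect_scale` multiplies the between-group mean
#' difference, in pooled-SD units per feature: 0 gives identical group
#' distributions, 5 gives essentially separable classes.
#'
#' @param spec a [cohort_spec()] (supplies `n_per_group` and the seed).
#' @param effect_scale non-negative between-group separation multiplier.
#' @param feature_names feature column names.
#' @param loadings per-feature loading of the group effect (default 1 for
#'   every feature).
#' @param group_names labels for the two groups.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return Tibble with `animal_id`, `group` and one column per feature.
#' @export
gen_feature_cohort <- function(spec = cohort_spec(), effect_scale = 1,
                               feature_names = .COHORT_FEATURES,
                               loadings = rep(1, length(feature_names)),
                               group_names = c("control", "GE"),
                               seed = spec$seed) {
  stopifnot(effect_scale >= 0, length(loadings) == length(feature_names))
  n <- spec$n_per_group
  if (n < 2) stop("n_per_group must be >= 2 for cross-validation to be possible")
  set.seed(seed)
  p <- length(feature_names)
  mk <- function(g, shift) {
    m <- matrix(stats::rnorm(n * p), n, p) +
      matrix(shift * loadings, n, p, byrow = TRUE)
    colnames(m) <- feature_names
    tibble::as_tibble(m) |>
      dplyr::mutate(group = g, .before = 1)
  }
  out <- dplyr::bind_rows(mk(group_names[1], 0),
                          mk(group_names[2], effect_scale))
  out$animal_id <- sprintf("m%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "animal_id", .before = 1)
}

#' Generate an object-recognition interaction-time table
#'
#' Per-animal novel/familiar interaction times constructed so the expected
#' discrimination ratio equals the requested group mean: each animal's ratio
#' is `mean_dr + N(0, noise_sd)` (clipped to the valid (-1, 1) range), and
#' times are `total/2 * (1 +/- ratio)`, guaranteeing non-negative times and
#' an exact deterministic inversion when `noise_sd = 0`.
#'
#' @param n_per_group animals per group.
#' @param mean_dr named numeric vector of group mean discrimination ratios,
#'   each inside (-1, 1).
#' @param noise_sd SD of per-animal ratio noise.
#' @param total_time_s total interaction time per animal, seconds.
#' @param seed integer seed.
#' @return Tibble with `animal_id`, `group`, `t_novel_s`, `t_familiar_s` and
#'   the realized `discrimination_ratio`.
#' @export
gen_behavior <- function(n_per_group,
                         mean_dr = c(control = 0.45, GE = 0.05, GE_mino = 0.35),
                         noise_sd = 0.15, total_time_s = 40, seed = 1) {
  if (any(mean_dr <= -1 | mean_dr >= 1)) {
    stop("mean_dr must lie strictly inside (-1, 1)")
  }
  stopifnot(n_per_group >= 1, noise_sd >= 0, total_time_s > 0)
  set.seed(seed)
  out <- purrr::map_dfr(names(mean_dr) %||% as.character(seq_along(mean_dr)),
                        function(g) {
    dr <- mean_dr[[g]] + stats::rnorm(n_per_group, 0, noise_sd)
    dr <- pmin(pmax(dr, -0.999), 0.999)
    tibble::tibble(
      group = g,
      t_novel_s = total_time_s / 2 * (1 + dr),
      t_familiar_s = total_time_s / 2 * (1 - dr))
  })
  out$animal_id <- sprintf("b%03d", seq_len(nrow(out)))
  out$discrimination_ratio <- discrimination_ratio(out$t_novel_s,
                                                   out$t_familiar_s)
  dplyr::relocate(out, "animal_id", .before = 1)
}
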