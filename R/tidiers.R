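#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0),
         unit = c("nm", "a.u."))
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, q_min = x$q_range[1], q_max = x$q_range[2],
         qrg_low = x$qrg_window[1], qrg_high = x$qrg_window[2],
         fit_points = x$fit_points, residual_rms = x$residual_rms,
         valid = x$valid)
}

#' @export
tidy.cross_section_fit <- function(x, ...) {
  tibble(term = tolower(x$which), estimate = x$rxs, unit = "nm")
}

#' @export
glance.cross_section_fit <- function(x, ...) {
  tibble(which = x$which, rxs = x$rxs, intercept = x$intercept,
         q_min = x$q_range[1], q_max = x$q_range[2],
         fit_points = x$fit_points)
}

#' @export
tidy.distance_distribution <- function(x, ...) {
  tibble(r = x$r, p = x$p)
}

#' @export
glance.distance_distribution <- function(x, ...) {
  tibble(dmax = x$dmax, rg = x$rg, m1 = x$m1, m2 = x$m2)
}

#' @export
tidy.pca_result <- function(x, ...) x$projections

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_frames = nrow(x$projections),
         n_groups = length(x$centroid_ids),
         pc1_fraction = x$variance_fractions[1],
         pc2_fraction = x$variance_fractions[2],
         pc3_fraction = if (length(x$variance_fractions) >= 3) {
           x$variance_fractions[3]
         } else {
           NA_real_
         },
         silhouette = x$silhouette)
}

#' @export
glance.sedimentation_estimate <- function(x, ...) {
  tibble(s20w = x$s20w, stokes_radius = x$stokes_radius,
         hull_volume = x$hull_volume, mass = x$mass, vbar = x$vbar)
}

#' @export
tidy.conformer_ensemble <- function(x, ...) {
  tibble(frame = seq_along(x$frames),
         rg = vapply(x$frames, model_rg, numeric(1)))
}

#' @export
glance.conformer_ensemble <- function(x, ...) {
  tibble(attempted = x$attempted, accepted = x$accepted,
         acceptance_rate = if (x$attempted > 0) {
           x$accepted / x$attempted
         } else {
           NA_real_
         },
         frames_stored = length(x$frames), seed = x$seed,
         step = x$step, cutoff = x$cutoff)
}
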