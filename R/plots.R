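#' @export
autoplot.scattering_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (nm^-1)), y = "I(Q) (a.u.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distance_distribution <- function(object, ...) {
  df <- tibble(r = object$r, p = object$p)
  pk <- tibble(r = c(object$m1, object$m2)) |> dplyr::filter(!is.na(r))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = pk, ggplot2::aes(xintercept = .data$r),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "r (nm)", y = "P(r)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kratky_curve <- function(object, ...) {
  pk <- kratky_peaks(object)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "firebrick") +
    ggplot2::labs(x = expression(Q %.% R[G]),
                  y = expression((Q %.% R[G])^2 %.% I(Q) / I(0))) +
    ggplot2::theme_minimal()
}

#' Chevron plot: R-factor vs model R_G
#'
#' The classic diagnostic of ensemble fitting: every scored model as a
#' point, the best-n set highlighted, with optional vertical lines at an
#' experimental R_G and its +/- 2% boundaries.
#'
#' @param scores A `fit_scores` tibble from [score_ensemble()].
#' @param best Optional integer ids of the selected best models.
#' @param rg_expt Optional experimental R_G, nm (draws the +/- 2% band).
#' @return A ggplot object.
#' @export
plot_chevron <- function(scores, best = NULL, rg_expt = NULL) {
  scores <- dplyr::mutate(scores,
                          selected = .data$model_id %in% (best %||% integer()))
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$rg, .data$r_factor)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                        alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = expression(R[G] ~ (nm)), y = "R-factor (%)") +
    ggplot2::theme_minimal()
  if (!is.null(rg_expt)) {
    p <- p +
      ggplot2::geom_vline(xintercept = rg_expt) +
      ggplot2::geom_vline(xintercept = rg_expt * c(0.98, 1.02),
                          linetype = "dashed")
  }
  p
}

#' @export
autoplot.fit_scores <- function(object, ...) plot_chevron(object, ...)

#' @export
autoplot.pca_result <- function(object, ...) {
  proj <- object$projections
  cent <- proj[object$centroid_ids, ]
  ggplot2::ggplot(proj, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = cent, shape = 8, size = 3,
                        colour = "black") +
    ggplot2::labs(colour = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.guinier_fit <- function(object, curve, ...) {
  stopifnot(!missing(curve))
  df <- tibble(q2 = curve$q^2, lni = log(pmax(curve$intensity, 1e-300)),
               in_window = curve$q >= object$q_range[1] &
                 curve$q <= object$q_range[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$q2, .data$lni)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window), size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$i0),
                         slope = -object$rg^2 / 3, colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Q^2 ~ (nm^-2)), y = "ln I(Q)") +
    ggplot2::theme_minimal()
}
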