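# shared pair-distance histogram (Rcpp kernel); nbins from the bounding box
.pair_hist <- function(xyz, b, bin_width) {
  rng <- apply(xyz, 2, range)
  diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  nbins <- max(1L, as.integer(ceiling(diag_len / bin_width)) + 1L)
  ph <- pair_hist_cpp(xyz, b, bin_width, nbins)
  ph$r <- (seq_len(nbins) - 0.5) * bin_width
  ph$bin_width <- bin_width
  ph
}

.debye_from_hist <- function(ph, q_grid) {
  qr <- outer(ph$r, q_grid)         # nbins x nq
  sinc <- ifelse(qr < 1e-12, 1, sin(qr) / qr)
  as.numeric(ph$self + 2 * crossprod(ph$hist, sinc))
}

#' Theoretical scattering curve by the Debye equation
#'
#' Evaluates `I(Q) = sum_i sum_j b_i b_j sin(Q r_ij)/(Q r_ij)` through a
#' weighted pair-distance histogram (exact orientational average, in vacuo,
#' no hydration shell). `I(0) = (sum b)^2` exactly.
#'
#' @param model An [atomic_model()] with scattering lengths assigned.
#' @param q_grid Q values, nm^-1.
#' @param bin_width Histogram bin width, nm (default 0.01).
#' @param contrast `"xray"` or `"neutron"`.
#' @return A [scattering_curve()].
#' @export
debye_intensity <- function(model, q_grid, bin_width = 0.01,
                            contrast = c("xray", "neutron")) {
  contrast <- match.arg(contrast)
  b <- .model_b(model, contrast)
  xyz <- coords(model)
  if (nrow(xyz) == 1) {
    return(scattering_curve(q_grid, rep(b^2, length(q_grid)),
                            contrast = contrast))
  }
  ph <- .pair_hist(xyz, b, bin_width)
  scattering_curve(q_grid, .debye_from_hist(ph, q_grid),
                   contrast = contrast)
}

#' Theoretical scattering curve on a golden-ratio spherical grid
#'
#' Averages `|sum_i b_i exp(i Q u . r_i)|^2` over quasi-uniform directions
#' `u` placed by a golden-ratio (Fibonacci) spherical spiral. Converges to
#' the Debye result as `n_directions` grows; the two evaluators serve as
#' mutual cross-checks.
#'
#' @inheritParams debye_intensity
#' @param n_directions Number of quadrature directions (default 300).
#' @return A [scattering_curve()].
#' @export
golden_grid_intensity <- function(model, q_grid, n_directions = 300,
                                  contrast = c("xray", "neutron")) {
  contrast <- match.arg(contrast)
  stopifnot(n_directions >= 1)
  b <- .model_b(model, contrast)
  xyz <- coords(model)
  k <- seq_len(n_directions)
  z <- 1 - (2 * k - 1) / n_directions
  phi <- 2 * pi * k / ((1 + sqrt(5)) / 2)
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(phi), s * sin(phi), z)
  ur <- u %*% t(xyz)                 # ndir x natoms
  intensity <- vapply(q_grid, function(q) {
    qur <- q * ur
    re <- cos(qur) %*% b
    im <- sin(qur) %*% b
    mean(re^2 + im^2)
  }, numeric(1))
  scattering_curve(q_grid, intensity, contrast = contrast)
}

#' Distance distribution container
#'
#' @param r Distances, nm.
#' @param p Probability density (unit area).
#' @param dmax Maximum dimension, nm.
#' @param rg P(r)-derived radius of gyration, nm.
#' @param m1,m2 Modal distances, nm (`m2` may be NA).
#' @return An object of class `distance_distribution`.
#' @export
distance_distribution <- function(r, p, dmax, rg, m1 = NA_real_,
                                  m2 = NA_real_) {
  if (any(p < -1e-12)) abort("P(r) must be non-negative")
  p <- pmax(p, 0)
  structure(list(r = r, p = p, dmax = dmax, rg = rg, m1 = m1, m2 = m2),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution> dmax %.2f nm, rg %.3f nm, M1 %.2f nm, M2 %s\n",
    x$dmax, x$rg, x$m1,
    if (is.na(x$m2)) "absent" else sprintf("%.2f nm", x$m2)))
  invisible(x)
}

#' Exact pair-distance distribution of a model
#'
#' `P(r)` as the scattering-length-weighted histogram of all pair
#' distances, normalised to unit area; `D_max` is the exact largest pair
#' distance; `R_G` from the second moment,
#' `R_G^2 = sum P r^2 / (2 sum P)`. Peaks M1/M2 are located with
#' [find_pr_peaks()].
#'
#' @inheritParams debye_intensity
#' @param bin_width Histogram bin width, nm.
#' @return A [distance_distribution()].
#' @export
theoretical_pr <- function(model, bin_width = 0.01,
                           contrast = c("xray", "neutron")) {
  contrast <- match.arg(contrast)
  if (n_atoms(model) < 2) abort("P(r) needs at least two atoms")
  b <- .model_b(model, contrast)
  ph <- .pair_hist(coords(model), b, bin_width)
  p <- ph$hist / (sum(ph$hist) * bin_width)
  rg <- sqrt(sum(p * ph$r^2) / (2 * sum(p)))
  d <- distance_distribution(ph$r, p, dmax = ph$dmax, rg = rg)
  pk <- find_pr_peaks(d)
  d$m1 <- pk[["m1"]]
  d$m2 <- pk[["m2"]]
  d
}
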