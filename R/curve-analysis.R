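#' Guinier fit: R_G and I(0) from the low-Q slope
#'
#' Least-squares line of `ln I(Q)` vs `Q^2` over the window
#' `[q_min, q_max]`: `ln I(Q) = ln I(0) - R_G^2 Q^2 / 3`, so
#' `R_G = sqrt(-3 slope)` and `I(0) = exp(intercept)`. For antibodies the
#' approximation holds out to `Q R_G <= 1.5`; the fit is flagged invalid
#' (never silently truncated) beyond that.
#'
#' @param curve A [scattering_curve()].
#' @param q_min,q_max Fit window, nm^-1 (defaults: the X-ray R_G preset of
#'   [q_windows]).
#' @return An object of class `guinier_fit` with elements `rg`, `i0`,
#'   `q_range`, `qrg_window`, `fit_points`, `residual_rms`, `valid`.
#' @export
guinier_fit <- function(curve, q_min = q_windows$rg_xray[1],
                        q_max = q_windows$rg_xray[2]) {
  sel <- curve$q >= q_min & curve$q <= q_max
  if (sum(sel) < 4) abort("Fewer than 4 points in the Guinier window")
  q <- curve$q[sel]
  i <- curve$intensity[sel]
  if (any(i <= 0)) abort("Non-positive intensities in the Guinier window")
  fit <- lm(log(i) ~ I(q^2))
  slope <- coef(fit)[[2]]
  if (slope > 0) abort("non-physical Guinier slope (positive)")
  rg <- sqrt(-3 * slope)
  i0 <- exp(coef(fit)[[1]])
  structure(list(
    rg = rg, i0 = i0, q_range = c(q_min, q_max),
    qrg_window = c(q_min * rg, q_max * rg), fit_points = sum(sel),
    residual_rms = sqrt(mean(fit$residuals^2)),
    valid = q_max * rg <= 1.5, contrast = attr(curve, "contrast")),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> R_G = %.3f nm, I(0) = %.4g (%d pts, Q.R_G %.2f-%.2f%s)\n",
    x$rg, x$i0, x$fit_points, x$qrg_window[1], x$qrg_window[2],
    if (x$valid) "" else ", outside Q.R_G <= 1.5"))
  invisible(x)
}

#' Cross-sectional Guinier fit: R_XS from intermediate Q
#'
#' Least-squares line of `ln(I(Q) Q)` vs `Q^2`:
#' `ln(I Q) = [I Q]_{Q->0} - R_XS^2 Q^2 / 2`, so `R_XS = sqrt(-2 slope)`.
#' For antibodies, R_XS-1 (default window 0.29-0.52 nm^-1) tracks the
#' Fab-Fc separation; R_XS-2 (0.66-1.05 nm^-1) the subunit cross-section.
#'
#' @param curve A [scattering_curve()].
#' @param q_min,q_max Fit window, nm^-1; defaults from `which`.
#' @param which `"RXS1"` or `"RXS2"` (sets the default window).
#' @return An object of class `cross_section_fit` with `rxs`, `intercept`,
#'   `q_range`, `which`.
#' @export
cross_section_fit <- function(curve, q_min = NULL, q_max = NULL,
                              which = c("RXS1", "RXS2")) {
  which <- match.arg(which)
  win <- if (which == "RXS1") q_windows$rxs1 else q_windows$rxs2
  q_min <- q_min %||% win[1]
  q_max <- q_max %||% win[2]
  sel <- curve$q >= q_min & curve$q <= q_max & curve$q > 0
  if (sum(sel) < 4) abort("Fewer than 4 points in the cross-section window")
  q <- curve$q[sel]
  iq <- curve$intensity[sel] * q
  if (any(iq <= 0)) abort("Non-positive I*Q in the cross-section window")
  fit <- lm(log(iq) ~ I(q^2))
  slope <- coef(fit)[[2]]
  if (slope > 1e-12) abort("non-physical cross-sectional Guinier slope")
  structure(list(rxs = sqrt(max(0, -2 * slope)),
                 intercept = exp(coef(fit)[[1]]),
                 q_range = c(q_min, q_max), which = which,
                 fit_points = sum(sel)),
            class = "cross_section_fit")
}

#' @export
print.cross_section_fit <- function(x, ...) {
  cat(sprintf("<cross_section_fit> %s = %.3f nm (Q %.2f-%.2f nm^-1)\n",
              x$which, x$rxs, x$q_range[1], x$q_range[2]))
  invisible(x)
}

#' Locate the M1 and M2 peaks of a P(r) distribution
#'
#' M1 is the global maximum. M2 is the next local maximum at r > M1 of a
#' smoothing-spline fit; when no second maximum exists, a shoulder is
#' sought as a zero crossing of the second derivative of the smoothed
#' P(r) beyond M1 (NA if neither exists). Ties between equal maxima break
#' toward smaller r.
#'
#' @param dist A [distance_distribution()].
#' @param spar Smoothing parameter for [stats::smooth.spline()].
#' @return Named numeric vector `c(m1 = , m2 = )` (m2 possibly NA).
#' @export
find_pr_peaks <- function(dist, spar = 0.5) {
  r <- dist$r
  p <- dist$p
  keep <- r <= max(r[p > 0], dist$dmax)
  r <- r[keep]; p <- p[keep]
  m1 <- r[which.max(p)]
  if (length(r) < 10) return(c(m1 = m1, m2 = NA_real_))
  ss <- smooth.spline(r, p, spar = spar)
  rf <- seq(min(r), max(r), length.out = 512)
  ps <- predict(ss, rf)$y
  dp <- diff(ps)
  locmax <- which(dp[-1] < 0 & dp[-length(dp)] >= 0) + 1
  locmax <- locmax[ps[locmax] > 0.02 * max(ps)]   # ignore tail wiggles
  m1s <- rf[locmax[which.max(ps[locmax])]]
  if (length(m1s) == 0) m1s <- m1
  cand <- rf[locmax]
  cand <- cand[cand > m1s + 0.2]
  if (length(cand) > 0) {
    return(c(m1 = m1, m2 = cand[1]))
  }
  # shoulder: a concave dip (negative excursion of the second derivative
  # of the smoothed curve) beyond M1, at radii where the distribution is
  # still appreciable; amplitude thresholds reject smoothing wiggles
  d2 <- predict(ss, rf, deriv = 2)$y
  mask <- rf > m1s + 0.2 & ps > 0.02 * max(ps)
  sgn <- diff(sign(d2))
  neg <- which(sgn < 0 & mask[-length(mask)])
  for (nstart in neg) {
    pos_after <- which(sgn > 0 & seq_along(sgn) > nstart &
                         mask[-length(mask)])
    if (length(pos_after) == 0) next
    iv <- nstart:pos_after[1]
    depth <- -min(d2[iv])
    if (depth > 0.02 * max(abs(d2))) {
      # centre of the concave interval = shoulder position
      return(c(m1 = m1, m2 = (rf[nstart] + rf[pos_after[1]]) / 2))
    }
  }
  c(m1 = m1, m2 = NA_real_)
}

#' Normalised Kratky transform
#'
#' `y = (Q R_G)^2 I(Q)/I(0)` against `x = Q R_G`; the peak structure
#' diagnoses compactness vs disorder (a globular body peaks at
#' `x = sqrt(3)`, `y = 3/e`). Peaks are local maxima of a spline-smoothed
#' transform.
#'
#' @param curve A [scattering_curve()].
#' @param fit A [guinier_fit()] supplying R_G and I(0).
#' @return A tibble of class `kratky_curve` with columns `x`, `y` and a
#'   `peaks` attribute (tibble of peak x/y).
#' @export
kratky_normalized <- function(curve, fit) {
  stopifnot(fit$rg > 0, fit$i0 > 0)
  x <- curve$q * fit$rg
  y <- x^2 * curve$intensity / fit$i0
  out <- tibble(x = x, y = y)
  ss <- smooth.spline(x, y, spar = 0.4)
  xf <- seq(min(x), max(x), length.out = 1024)
  ys <- predict(ss, xf)$y
  dp <- diff(ys)
  locmax <- which(dp[-1] < 0 & dp[-length(dp)] >= 0) + 1
  peaks <- tibble(x = xf[locmax], y = ys[locmax])
  structure(out, class = c("kratky_curve", class(out)), peaks = peaks,
            rg = fit$rg)
}

#' Kratky peak positions
#' @param kratky A `kratky_curve` from [kratky_normalized()].
#' @return Tibble of peak `x` (Q R_G) and `y` values.
#' @export
kratky_peaks <- function(kratky) attr(kratky, "peaks")

#' Regularise a measured curve onto a uniform grid including Q = 0
#'
#' Interpolation makes the Q spacing uniform; extrapolation extends the
#' curve to zero Q with the Guinier model `I(0) exp(-Q^2 R_G^2 / 3)` below
#' the first measured point. The standard grids are 680 points (X-ray) and
#' 72 points (neutron) on 0-1.5 nm^-1.
#'
#' @param curve A [scattering_curve()].
#' @param n_points Grid size.
#' @param q_max Grid maximum, nm^-1.
#' @param fit A [guinier_fit()] of the same curve (supplies I(0), R_G).
#' @return A [scattering_curve()] on the uniform grid.
#' @export
regularize_curve <- function(curve, n_points = 680, q_max = 1.5, fit) {
  if (q_max > max(curve$q) + 1e-9) {
    abort(sprintf("q_max = %g beyond the measured range (max %g)",
                  q_max, max(curve$q)))
  }
  grid <- seq(0, q_max, length.out = n_points)
  q1 <- min(curve$q)
  f <- splinefun(curve$q, curve$intensity, method = "monoH.FC")
  out <- ifelse(grid < q1,
                fit$i0 * exp(-grid^2 * fit$rg^2 / 3),
                f(grid))
  scattering_curve(grid, out, contrast = attr(curve, "contrast"))
}
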