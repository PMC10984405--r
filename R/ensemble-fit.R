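#' Crystallography-style R-factor between two curves
#'
#' `R = 100 * sum |I_expt - eta I_model| / sum |I_expt|`, with the scale
#' factor `eta` fixed by matching the experimental forward scattering:
#' `eta = I_expt(0) / I_model(0)` (first grid point). Both curves must be
#' on the identical Q grid (see [regularize_curve()]). With
#' `eta = "lsq"`, eta instead minimises the sum of squared differences
#' (not the reference convention; provided as an option).
#'
#' @param expt,model [scattering_curve()]s on the same Q grid.
#' @param eta `"i0"` (match I(0); the reference behaviour) or `"lsq"`.
#' @return A list with `r_factor` (percent) and `eta`.
#' @export
r_factor <- function(expt, model, eta = c("i0", "lsq")) {
  eta <- match.arg(eta)
  if (nrow(expt) != nrow(model) ||
      max(abs(expt$q - model$q)) > 1e-9) {
    abort("Curves are on different Q grids; regularize_curve() both first")
  }
  ie <- expt$intensity
  im <- model$intensity
  sc <- if (eta == "i0") {
    ie[1] / im[1]
  } else {
    sum(ie * im) / sum(im^2)
  }
  if (!is.finite(sc) || sc <= 0) abort("Non-positive scale factor eta")
  list(r_factor = 100 * sum(abs(ie - sc * im)) / sum(abs(ie)),
       eta = sc)
}

#' Score every frame of an ensemble against an experimental curve
#'
#' Computes each frame's theoretical Debye curve on the experimental grid
#' and its R-factor/eta, plus the frame's coordinate R_G (for chevron
#' plots of R-factor vs R_G).
#'
#' @param ensemble A `conformer_ensemble` from [tamc_sample()].
#' @param expt A regularised [scattering_curve()].
#' @param contrast `"xray"` or `"neutron"`.
#' @param bin_width Pair-histogram bin width, nm.
#' @return A tibble of class `fit_scores`: `model_id`, `r_factor`, `eta`,
#'   `rg`.
#' @export
score_ensemble <- function(ensemble, expt, contrast = c("xray", "neutron"),
                           bin_width = 0.01) {
  contrast <- match.arg(contrast)
  if (length(ensemble$frames) == 0) abort("Ensemble has no frames")
  b <- .model_b(ensemble$topology, contrast)
  q <- expt$q
  ie <- expt$intensity
  sum_ie <- sum(abs(ie))
  # all pair histograms first, then one shared sinc kernel and a single
  # matrix product: much cheaper than per-frame Debye evaluation
  hists <- lapply(ensemble$frames, .pair_hist, b = b, bin_width = bin_width)
  nb <- max(vapply(hists, function(h) length(h$hist), integer(1)))
  H <- matrix(0, length(hists), nb)
  for (i in seq_along(hists)) {
    H[i, seq_along(hists[[i]]$hist)] <- hists[[i]]$hist
  }
  r_ctr <- (seq_len(nb) - 0.5) * bin_width
  qr <- outer(r_ctr, q)
  sinc <- ifelse(qr < 1e-12, 1, sin(qr) / qr)
  self <- hists[[1]]$self
  I_model <- self + 2 * H %*% sinc          # frames x nq
  sc <- ie[1] / I_model[, 1]
  resid <- abs(matrix(ie, nrow(I_model), length(q), byrow = TRUE) -
                 sc * I_model)
  out <- tibble(
    model_id = seq_along(ensemble$frames),
    r_factor = 100 * rowSums(resid) / sum_ie,
    eta = sc,
    rg = vapply(ensemble$frames, model_rg, numeric(1), weights = b))
  class(out) <- c("fit_scores", class(out))
  out
}

#' Select the n best-fitting models
#'
#' Indices of the `n` smallest R-factors (ties break toward the smaller
#' model id).
#'
#' @param scores A `fit_scores` tibble from [score_ensemble()].
#' @param n How many models to keep (default 100).
#' @return Integer vector of model ids.
#' @export
select_best <- function(scores, n = 100) {
  if (n > nrow(scores)) {
    abort(sprintf("Requested %d models but only %d scored", n, nrow(scores)))
  }
  ord <- order(scores$r_factor, scores$model_id)
  scores$model_id[ord[seq_len(n)]]
}

#' Chevron table: best R-factor as a function of model R_G
#'
#' Bins the scored ensemble by R_G and reports the minimum R-factor per
#' bin; the location of the overall minimum estimates the true R_G.
#'
#' @param scores A `fit_scores` tibble.
#' @param bin_width R_G bin width, nm.
#' @return A tibble `rg_mid`, `min_r_factor`, `n_models`, with attribute
#'   `rg_at_min`.
#' @export
chevron_table <- function(scores, bin_width = 0.05) {
  br <- seq(floor(min(scores$rg) / bin_width) * bin_width,
            max(scores$rg) + bin_width, by = bin_width)
  bin <- cut(scores$rg, br, include.lowest = TRUE)
  tab <- scores |>
    dplyr::mutate(rg_mid = (br[as.integer(bin)] +
                              br[as.integer(bin) + 1]) / 2) |>
    dplyr::group_by(.data$rg_mid) |>
    dplyr::summarise(min_r_factor = min(.data$r_factor),
                     n_models = dplyr::n(), .groups = "drop")
  attr(tab, "rg_at_min") <- tab$rg_mid[which.min(tab$min_r_factor)]
  tab
}

#' Superpose coordinate frames onto a reference (Kabsch)
#'
#' Least-squares rigid superposition of the selected atoms of each frame
#' onto the reference; the fitted transform is applied to the whole frame.
#'
#' @param frames List of n x 3 coordinate matrices.
#' @param reference An n x 3 reference coordinate matrix.
#' @param selection Integer atom indices used for the fit (default: all).
#' @return List of aligned coordinate matrices.
#' @export
superpose_set <- function(frames, reference, selection = NULL) {
  selection <- selection %||% seq_len(nrow(reference))
  if (length(selection) == 0) abort("Empty selection")
  ref <- reference[selection, , drop = FALSE]
  if (any(selection > nrow(reference))) abort("Selection out of range")
  ref_ctr <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_ctr)
  lapply(frames, function(fr) {
    if (nrow(fr) != nrow(reference)) abort("Frame/reference atom mismatch")
    mob <- fr[selection, , drop = FALSE]
    mob_ctr <- colMeans(mob)
    H <- crossprod(sweep(mob, 2, mob_ctr), ref0)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sweep(sweep(fr, 2, mob_ctr) %*% t(R), 2, ref_ctr, "+")
  })
}

#' Occupied-space summary for a subunit across aligned frames
#'
#' Per-atom positional standard deviation over frames (root mean squared
#' deviation from the per-atom mean position), averaged over the selected
#' atoms: a single spread statistic (nm) quantifying how much space the
#' subunit explores, e.g. the Fc across a best-fit set.
#'
#' @param frames List of aligned n x 3 coordinate matrices.
#' @param selection Integer atom indices of the subunit.
#' @return Spread, nm.
#' @export
fc_occupancy_summary <- function(frames, selection) {
  if (length(selection) == 0) abort("Empty selection")
  arr <- vapply(frames, function(f) f[selection, , drop = FALSE],
                matrix(0, length(selection), 3))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  per_atom <- sqrt(apply(dev2, 1, mean) * 3)  # sum over x,y,z of variances
  mean(per_atom)
}
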