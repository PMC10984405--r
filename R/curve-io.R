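#' Construct a scattering curve
#'
#' A tibble subclass with columns `q` (nm^-1, strictly increasing),
#' `intensity`, and optionally `sigma`, tagged with the contrast
#' (X-ray/neutron) and whether it is normalised to I(0) = 1.
#'
#' @param q Momentum transfer, nm^-1, strictly increasing, >= 0.
#' @param intensity Intensities (arbitrary units).
#' @param sigma Optional per-point errors.
#' @param contrast `"xray"` or `"neutron"`.
#' @param normalized Logical: I(0) = 1?
#' @return A tibble of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             contrast = c("xray", "neutron"),
                             normalized = FALSE) {
  contrast <- match.arg(contrast)
  if (length(q) != length(intensity)) abort("q and intensity lengths differ")
  if (any(q < 0)) abort("q must be non-negative")
  if (any(diff(q) <= 0)) abort("q must be strictly increasing")
  if (!all(is.finite(intensity))) abort("intensity must be finite")
  df <- tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) abort("sigma length differs from q")
    df$sigma <- as.numeric(sigma)
  }
  structure(df, class = c("scattering_curve", class(df)),
            contrast = contrast, normalized = normalized)
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %s, %d points, Q in [%.3g, %.3g] nm^-1%s\n",
              attr(x, "contrast"), nrow(x), min(x$q), max(x$q),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  NextMethod()
}

#' Normalise a curve to I(0) = 1
#'
#' Divides intensity (and sigma) by the first-point intensity; intended for
#' curves whose grid starts at Q = 0 (see [regularize_curve()]).
#'
#' @param curve A [scattering_curve()].
#' @return A normalised [scattering_curve()].
#' @export
normalize_curve <- function(curve) {
  i0 <- curve$intensity[1]
  if (i0 <= 0) abort("Cannot normalize: I at first grid point is not positive")
  curve$intensity <- curve$intensity / i0
  if (!is.null(curve[["sigma"]])) curve$sigma <- curve[["sigma"]] / i0
  attr(curve, "normalized") <- TRUE
  curve
}

#' Read a scattering curve from 3-column text
#'
#' Expects whitespace-separated columns Q (nm^-1), I(Q), and optionally
#' sigma; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param contrast `"xray"` or `"neutron"`.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, contrast = "xray") {
  if (!file.exists(path)) abort(paste("No such file:", path))
  df <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 2) abort("Curve file needs at least 2 columns (Q, I)")
  scattering_curve(df[[1]], df[[2]],
                   sigma = if (ncol(df) >= 3) df[[3]] else NULL,
                   contrast = contrast)
}

#' Write a scattering curve as 3-column text
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  if (is.null(df[["sigma"]])) df$sigma <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Q(nm^-1)  I(Q)  sigma   contrast=%s",
                     attr(curve, "contrast")), con)
  write.table(format(df, digits = 10), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
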