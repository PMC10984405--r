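#' PCA of a conformer set with k-means grouping and centroid models
#'
#' Eigen-decomposition of the covariance matrix of the (flattened) atomic
#' coordinates over frames (coordinates only, no mass weighting), followed
#' by k-means clustering of the projections on the top principal
#' components (fixed seed, 50 restarts). The centroid model of each group
#' is the member frame closest, in PC space, to the group mean. Glycan
#' atoms can be stripped first so glycosylated and deglycosylated sets are
#' compared on the same protein atoms.
#'
#' @param frames List of aligned n x 3 coordinate matrices (superpose
#'   first; see [superpose_set()]).
#' @param n_components Number of principal components kept (default 3).
#' @param n_groups Number of k-means groups (default 4).
#' @param topology Optional [atomic_model()]; needed when
#'   `strip_glycans_first` is TRUE.
#' @param strip_glycans_first Drop glycan atoms before the PCA.
#' @param seed Integer seed for the k-means restarts.
#' @return An object of class `pca_result`: `eigenvalues`,
#'   `variance_fractions`, `projections` (tibble, one row per frame),
#'   `group_labels`, `centroid_ids`, `silhouette` (mean silhouette width).
#' @export
pca_cluster <- function(frames, n_components = 3, n_groups = 4,
                        topology = NULL, strip_glycans_first = TRUE,
                        seed = 1) {
  if (length(frames) < n_groups) {
    abort(sprintf("Need at least %d frames for %d groups",
                  n_groups, n_groups))
  }
  keep <- seq_len(nrow(frames[[1]]))
  if (strip_glycans_first && !is.null(topology)) {
    keep <- which(!topology$atoms$is_glycan)
  }
  X <- t(vapply(frames, function(f) as.numeric(f[keep, , drop = FALSE]),
                numeric(3 * length(keep))))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (max(abs(Xc)) < 1e-9) {
    abort("Degenerate input: all frames are identical (zero covariance)")
  }
  sv <- svd(Xc, nu = 0, nv = min(nrow(X) - 1, 20))
  nf <- nrow(X)
  eig <- sv$d^2 / (nf - 1)
  eig <- eig[seq_len(min(length(eig), nf - 1))]
  vf <- eig / sum(eig)
  k <- min(n_components, ncol(sv$v))
  proj <- Xc %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  km <- withr::with_seed(seed,
                         kmeans(proj, centers = n_groups, nstart = 50))
  labels <- km$cluster
  centroid_ids <- vapply(seq_len(n_groups), function(g) {
    ids <- which(labels == g)
    d2 <- rowSums((proj[ids, , drop = FALSE] -
                     matrix(km$centers[g, ], length(ids), k,
                            byrow = TRUE))^2)
    ids[which.min(d2)]
  }, integer(1))
  sil <- .mean_silhouette(proj, labels)
  structure(list(
    eigenvalues = eig, variance_fractions = vf,
    projections = as_tibble(as.data.frame(proj)) |>
      dplyr::mutate(model_id = dplyr::row_number(),
                    group = labels),
    group_labels = labels, centroid_ids = centroid_ids,
    silhouette = sil, n_components = k),
    class = "pca_result")
}

# mean silhouette width over all points (reported so users can judge the
# choice of n_groups, which is a convention, not an optimum)
.mean_silhouette <- function(proj, labels) {
  n <- nrow(proj)
  if (length(unique(labels)) < 2 || n > 2000) return(NA_real_)
  D <- as.matrix(stats::dist(proj))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    bvals <- vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1))
    b <- min(bvals)
    if (is.nan(a)) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d frames, %d groups; PC variance fractions: %s\n",
    nrow(x$projections), length(x$centroid_ids),
    paste(sprintf("%.3f", x$variance_fractions[seq_len(x$n_components)]),
          collapse = ", ")))
  if (!is.na(x$silhouette)) {
    cat(sprintf("  mean silhouette width %.3f\n", x$silhouette))
  }
  invisible(x)
}
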