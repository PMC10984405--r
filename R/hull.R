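#' Volume of the 3-D convex hull of a point set
#'
#' Incremental (beneath-beyond) convex hull: starting from an extreme
#' tetrahedron, each point outside the current hull removes its visible
#' faces and is reconnected across the horizon edges. The volume is the
#' sum of tetrahedra from an interior point to each face. Written in
#' vectorised R; exact up to floating-point tolerance and validated
#' against closed forms (cube, tetrahedron, dense sphere clouds).
#'
#' @param xyz An n x 3 coordinate matrix.
#' @param tol Plane-distance tolerance (points closer are treated as on
#'   the face).
#' @return Hull volume (same cubed units as the coordinates).
#' @export
convex_hull_volume <- function(xyz, tol = 1e-9) {
  xyz <- unique(as.matrix(xyz))
  n <- nrow(xyz)
  if (n < 4) abort("Degenerate geometry: need at least 4 distinct points")
  # initial tetrahedron from extremes
  i1 <- which.min(xyz[, 1])
  i2 <- which.max(xyz[, 1])
  if (i1 == i2) abort("Degenerate geometry: zero extent")
  d12 <- xyz[i2, ] - xyz[i1, ]
  # farthest from the line i1-i2
  w <- sweep(xyz, 2, xyz[i1, ])
  crossp <- cbind(w[, 2] * d12[3] - w[, 3] * d12[2],
                  w[, 3] * d12[1] - w[, 1] * d12[3],
                  w[, 1] * d12[2] - w[, 2] * d12[1])
  i3 <- which.max(rowSums(crossp^2))
  nrm <- crossp[i3, ]
  if (sqrt(sum(nrm^2)) < tol) abort("Degenerate geometry: collinear points")
  # farthest from the plane (i1,i2,i3)
  nrm <- nrm / sqrt(sum(nrm^2))
  dist_pl <- w %*% nrm
  i4 <- which.max(abs(dist_pl))
  if (abs(dist_pl[i4]) < tol) abort("Degenerate geometry: coplanar points")
  interior <- colMeans(xyz[c(i1, i2, i3, i4), ])

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  face_data <- function(f) {
    a <- xyz[f[1], ]; bb <- xyz[f[2], ]; cc <- xyz[f[3], ]
    nr <- pracma::cross(bb - a, cc - a)
    nn <- sqrt(sum(nr^2))
    if (nn < tol) return(NULL)
    nr <- nr / nn
    if (sum(nr * (a - interior)) < 0) nr <- -nr  # outward
    c(nr, sum(nr * a))
  }
  fd <- t(apply(faces, 1, face_data))
  todo <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in todo) {
    d <- fd[, 1:3, drop = FALSE] %*% xyz[p, ] - fd[, 4]
    vis <- which(d > tol)
    if (length(vis) == 0) next
    # horizon = edges used by exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(k) {
      f <- faces[k, ]
      rbind(sort(f[c(1, 2)]), sort(f[c(1, 3)]), sort(f[c(2, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    fd <- fd[-vis, , drop = FALSE]
    new_faces <- cbind(horizon, p)
    new_fd <- lapply(seq_len(nrow(new_faces)),
                     function(k) face_data(new_faces[k, ]))
    ok <- !vapply(new_fd, is.null, logical(1))
    faces <- rbind(faces, new_faces[ok, , drop = FALSE])
    fd <- rbind(fd, do.call(rbind, new_fd[ok]))
  }
  vol <- 0
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    vol <- vol + abs(det(rbind(xyz[f[1], ] - interior,
                               xyz[f[2], ] - interior,
                               xyz[f[3], ] - interior))) / 6
  }
  vol
}
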