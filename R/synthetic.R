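#' Specification for the mock antibody generator
#'
#' Defaults emulate a ~148 kDa antibody: two Fab lobes and one Fc lobe
#' (ellipsoidal pseudo-atomic point clouds) in a Y arrangement, joined by
#' two flexible tripeptide linkers, scaled so the default radius of
#' gyration is ~4.9 nm and the maximum dimension ~15 nm.
#'
#' @param subunit_semiaxes List of three numeric triples (nm): semiaxes of
#'   Fab1, Fab2, Fc.
#' @param pseudo_atoms_per_subunit Pseudo-atoms per lobe.
#' @param linker_residues Residues per flexible linker (tripeptide default).
#' @param target_rg Target radius of gyration, nm (lobe spacing is scaled
#'   once, deterministically, to meet it).
#' @param mass_kda Nominal molecular mass recorded on the model.
#' @param seed Integer seed; same seed gives a bitwise-identical model.
#' @return A list of class `mock_antibody_spec`.
#' @export
mock_antibody_spec <- function(subunit_semiaxes = list(
                                 fab1 = c(2.75, 1.9, 1.5),
                                 fab2 = c(2.75, 1.9, 1.5),
                                 fc   = c(2.40, 1.9, 1.6)),
                               pseudo_atoms_per_subunit = 150,
                               linker_residues = 3,
                               target_rg = 4.9,
                               mass_kda = 148.1,
                               seed = 1) {
  stopifnot(pseudo_atoms_per_subunit > 0, linker_residues > 0,
            target_rg > 0,
            all(vapply(subunit_semiaxes, function(s) all(s > 0), logical(1))))
  structure(list(subunit_semiaxes = subunit_semiaxes,
                 pseudo_atoms_per_subunit = pseudo_atoms_per_subunit,
                 linker_residues = linker_residues,
                 target_rg = target_rg, mass_kda = mass_kda, seed = seed),
            class = "mock_antibody_spec")
}

# uniform points inside an ellipsoid (rejection from the bounding box)
.ellipsoid_cloud <- function(n, semi) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(runif(3 * 2 * n, -1, 1), ncol = 3)
    keep <- rowSums(cand^2) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  sweep(out, 2, semi, "*")
}

#' Generate an antibody-like mock model
#'
#' Three rigid ellipsoidal pseudo-atom lobes (Fab1, Fab2, Fc) joined by two
#' flexible linkers whose residues carry N/CA/C pseudo-backbone atoms on a
#' zig-zag path, with phi/psi dihedrals declared variable so the
#' torsion-angle Monte Carlo sampler operates on them exactly as on a real
#' hinge. All pseudo-atoms are unit scatterers for both contrasts.
#'
#' @param spec A [mock_antibody_spec()].
#' @return An [atomic_model()] with `rigid_body` membership (1 = Fab1,
#'   2 = Fc, 3 = Fab2, 0 = linkers) and `flexible_regions` filled.
#' @export
make_mock_antibody <- function(spec = mock_antibody_spec()) {
  withr::with_seed(spec$seed, .build_mock_antibody(spec))
}

.build_mock_antibody <- function(spec) {
  semi <- spec$subunit_semiaxes
  npa <- spec$pseudo_atoms_per_subunit
  # base lobe centres (Y arrangement, nm); spacing rescaled to target_rg
  centers <- list(fab1 = c(-4.1, 2.66, 0), fc = c(0, -3.8, 0),
                  fab2 = c(4.1, 2.66, 0))
  clouds <- list(
    fab1 = .ellipsoid_cloud(npa, semi$fab1),
    fc   = .ellipsoid_cloud(npa, semi$fc),
    fab2 = .ellipsoid_cloud(npa, semi$fab2))
  # internal (lobe) second moment about the common centroid decomposes as
  # rg^2 = <lobe rg^2> + spread(centres)^2; scale centres to hit target_rg
  lobe_rg2 <- mean(vapply(clouds, function(p) mean(rowSums(
    sweep(p, 2, colMeans(p))^2)), numeric(1)))
  ctr_mat <- do.call(rbind, centers)
  ctr0 <- colMeans(ctr_mat)
  c2 <- mean(rowSums(sweep(ctr_mat, 2, ctr0)^2))
  if (spec$target_rg^2 <= lobe_rg2) {
    abort("target_rg too small for the given subunit semiaxes")
  }
  sc <- sqrt((spec$target_rg^2 - lobe_rg2) / c2)
  centers <- lapply(centers, function(x) ctr0 + sc * (x - ctr0))
  lobes <- purrr::imap(clouds, function(p, nm) {
    sweep(p, 2, centers[[nm]], "+")
  })
  # refuse lobes that already interpenetrate
  gap12 <- .min_cross_dist(lobes$fab1, lobes$fc)
  gap23 <- .min_cross_dist(lobes$fc, lobes$fab2)
  gap13 <- .min_cross_dist(lobes$fab1, lobes$fab2)
  if (min(gap12, gap23, gap13) < 0.25) {
    abort("Infeasible geometry: lobes overlap at build")
  }

  surface_point <- function(from, to, semi_from) {
    d <- to - from
    d <- d / sqrt(sum(d^2))
    # exit point of the ray on the ellipsoid surface, nudged outward so
    # linker atoms start clear of the lobe point cloud
    t <- 1 / sqrt(sum((d / semi_from)^2))
    from + (t + 0.15) * d
  }
  linker_atoms <- function(seg, p_start, p_end, n_res) {
    n_at <- 3 * n_res
    tfrac <- seq(0, 1, length.out = n_at + 2)[2:(n_at + 1)]
    path <- outer(tfrac, p_end - p_start) +
      matrix(p_start, n_at, 3, byrow = TRUE)
    # zig-zag offset perpendicular to the path so dihedral axes have lever
    d <- (p_end - p_start) / sqrt(sum((p_end - p_start)^2))
    perp <- pracma::cross(d, if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
    perp <- perp / sqrt(sum(perp^2))
    perp2 <- pracma::cross(d, perp)
    off <- 0.12 * (rep_len(c(1, -1), n_at))
    off2 <- 0.06 * (rep_len(c(1, 0, -1), n_at))
    path <- path + outer(off, perp) + outer(off2, perp2)
    tibble(element = "X",
           atom_name = rep(c("N", "CA", "C"), n_res),
           residue_name = "LNK",
           residue_number = rep(seq_len(n_res), each = 3),
           segment_id = seg,
           x = path[, 1], y = path[, 2], z = path[, 3])
  }
  lnk1 <- linker_atoms("LNK1",
                       surface_point(centers$fab1, centers$fc, semi$fab1),
                       surface_point(centers$fc, centers$fab1, semi$fc),
                       spec$linker_residues)
  lnk2 <- linker_atoms("LNK2",
                       surface_point(centers$fc, centers$fab2, semi$fc),
                       surface_point(centers$fab2, centers$fc, semi$fab2),
                       spec$linker_residues)
  lobe_tib <- function(p, seg, resname) {
    tibble(element = "X", atom_name = "PS", residue_name = resname,
           residue_number = 1L, segment_id = seg,
           x = p[, 1], y = p[, 2], z = p[, 3])
  }
  atoms <- dplyr::bind_rows(
    lobe_tib(lobes$fab1, "FAB1", "FB1"),
    lnk1,
    lobe_tib(lobes$fc, "FC", "FCC"),
    lnk2,
    lobe_tib(lobes$fab2, "FAB2", "FB2"))
  n1 <- nrow(lnk1)
  i_fab1 <- seq_len(npa)
  i_lnk1 <- npa + seq_len(n1)
  i_fc <- npa + n1 + seq_len(npa)
  i_lnk2 <- 2 * npa + n1 + seq_len(nrow(lnk2))
  i_fab2 <- 2 * npa + n1 + nrow(lnk2) + seq_len(npa)
  rigid <- integer(nrow(atoms))
  rigid[i_fab1] <- 1L; rigid[i_fc] <- 2L; rigid[i_fab2] <- 3L
  atoms$rigid_body <- rigid
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  nearest <- function(p, idx) idx[which.min(colSums((t(xyz[idx, ]) - p)^2))]
  chain_bonds <- function(idx) cbind(idx[-length(idx)], idx[-1])
  bonds <- rbind(
    c(nearest(xyz[i_lnk1[1], ], i_fab1), i_lnk1[1]),
    chain_bonds(i_lnk1),
    c(i_lnk1[length(i_lnk1)], nearest(xyz[i_lnk1[length(i_lnk1)], ], i_fc)),
    c(nearest(xyz[i_lnk2[1], ], i_fc), i_lnk2[1]),
    chain_bonds(i_lnk2),
    c(i_lnk2[length(i_lnk2)], nearest(xyz[i_lnk2[length(i_lnk2)], ], i_fab2)))
  flex <- tidyr::expand_grid(
    segment_id = c("LNK1", "LNK2"),
    residue_number = seq_len(spec$linker_residues),
    dihedral = c("phi", "psi"))
  m <- atomic_model(atoms, bonds = bonds, mass = spec$mass_kda,
                    vbar = 0.730, flexible_regions = flex)
  m$atoms$xray_b <- 1
  m$atoms$neutron_b <- 1
  m
}

#' Uniform solid-sphere point model
#'
#' Pseudo-atoms uniformly distributed in a solid sphere, unit scattering
#' length each; the coordinate radius of gyration converges to
#' `sqrt(3/5) * radius` as `n_points` grows.
#'
#' @param radius Sphere radius, nm.
#' @param n_points Number of points.
#' @param seed Integer seed.
#' @return An [atomic_model()].
#' @export
make_sphere_model <- function(radius, n_points, seed = 1) {
  stopifnot(radius > 0, n_points >= 1)
  withr::with_seed(seed, {
    if (n_points == 1) {
      xyz <- matrix(0, 1, 3)
    } else {
      u <- matrix(rnorm(3 * n_points), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- radius * runif(n_points)^(1 / 3)
      xyz <- u * r
    }
    atoms <- tibble(element = "X", atom_name = "PS", residue_name = "SPH",
                    residue_number = 1L, segment_id = "SPH",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    m <- atomic_model(atoms)
    m$atoms$xray_b <- 1
    m$atoms$neutron_b <- 1
    m
  })
}

#' Closed-form scattering curve of a homogeneous sphere
#'
#' `I(Q) = [3 (sin x - x cos x) / x^3]^2` with `x = Q R`, normalised to
#' `I(0) = 1`. Used as an analytic oracle throughout the test suite.
#'
#' @param radius Sphere radius, nm.
#' @param q_grid Q values, nm^-1.
#' @return A [scattering_curve()].
#' @export
analytic_sphere_curve <- function(radius, q_grid) {
  stopifnot(radius > 0)
  x <- q_grid * radius
  amp <- ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  scattering_curve(q = q_grid, intensity = amp^2, contrast = "xray",
                   normalized = TRUE)
}

#' Closed-form P(r) of a homogeneous sphere
#'
#' Density of the distance between two uniform points in a ball of radius
#' R: `p(r) = 3 r^2 / R^3 * (1 - 3 r / (4 R) + r^3 / (16 R^3))` on
#' `[0, 2R]`.
#'
#' @param radius Sphere radius, nm.
#' @param r Distances, nm.
#' @return Probability density values.
#' @export
analytic_sphere_pr <- function(radius, r) {
  p <- 3 * r^2 / radius^3 *
    (1 - 3 * r / (4 * radius) + r^3 / (16 * radius^3))
  p[r < 0 | r > 2 * radius] <- 0
  p
}

#' Noise specification for simulated experiments
#'
#' Gaussian counting-statistics-like noise with standard deviation
#' `sigma(Q) = relative_sigma_at_zero * I(Q) * (1 + sigma_growth * Q)`.
#'
#' @param relative_sigma_at_zero Relative error at Q = 0.
#' @param sigma_growth Per-nm^-1 growth rate of the relative error.
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(relative_sigma_at_zero = 0.01, sigma_growth = 1,
                       seed = 1) {
  stopifnot(relative_sigma_at_zero >= 0, sigma_growth >= 0)
  structure(list(relative_sigma_at_zero = relative_sigma_at_zero,
                 sigma_growth = sigma_growth, seed = seed),
            class = "noise_spec")
}

#' Simulate a noisy scattering experiment from a model
#'
#' Computes the theoretical Debye curve of the model on a uniform Q grid
#' and adds mean-zero Gaussian noise per [noise_spec()]; the error column
#' carries sigma(Q).
#'
#' @param model An [atomic_model()] with scattering lengths assigned.
#' @param contrast `"xray"` or `"neutron"`.
#' @param noise A [noise_spec()].
#' @param n_q Number of grid points (>= 4).
#' @param q_max Maximum Q, nm^-1.
#' @return A [scattering_curve()] with a `sigma` column.
#' @export
simulate_experiment <- function(model, contrast = "xray",
                                noise = noise_spec(), n_q = 680,
                                q_max = 1.5) {
  if (n_q < 4) abort("n_q must be at least 4")
  q <- seq(0, q_max, length.out = n_q)
  theo <- debye_intensity(model, q, contrast = contrast)
  sig <- noise$relative_sigma_at_zero * theo$intensity *
    (1 + noise$sigma_growth * q)
  i_obs <- withr::with_seed(noise$seed,
                            theo$intensity + rnorm(n_q, sd = sig))
  scattering_curve(q = q, intensity = i_obs, sigma = sig,
                   contrast = contrast)
}
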