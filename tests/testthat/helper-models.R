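# fixtures built in code, shared across test files

# two unit scatterers separated by d (nm), along x
two_point_model <- function(d = 1) {
  m <- atomic_model(tibble::tibble(
    element = "X", atom_name = c("P1", "P2"), residue_name = "PTS",
    residue_number = 1L, segment_id = "T",
    x = c(0, d), y = 0, z = 0))
  m$atoms$xray_b <- 1
  m$atoms$neutron_b <- 1
  m
}

# n random unit scatterers in a box (seeded)
random_point_model <- function(n, seed = 1, scale = 3) {
  withr::with_seed(seed, {
    m <- atomic_model(tibble::tibble(
      element = "X", atom_name = sprintf("P%d", seq_len(n)),
      residue_name = "PTS", residue_number = 1L, segment_id = "T",
      x = runif(n, 0, scale), y = runif(n, 0, scale),
      z = runif(n, 0, scale)))
    m$atoms$xray_b <- 1
    m$atoms$neutron_b <- 1
    m
  })
}

# brute-force Debye double sum: the independent oracle for the
# histogram-based evaluator
debye_direct <- function(xyz, b, q_grid) {
  n <- nrow(xyz)
  vapply(q_grid, function(q) {
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        s <- s + b[i] * b[j] *
          (if (q * d < 1e-12) 1 else sin(q * d) / (q * d))
      }
    }
    s
  }, numeric(1))
}

# small protein stub with a resolvable Asn sidechain (for glycan tests)
asn_protein_stub <- function(seed = 3) {
  withr::with_seed(seed, {
    prot <- tibble::tibble(
      element = rep(c("C", "N", "O"), length.out = 40),
      atom_name = sprintf("A%02d", 1:40),
      residue_name = "GLY", residue_number = rep(1:10, each = 4),
      segment_id = "A",
      x = rnorm(40, 0, 0.8), y = rnorm(40, 0, 0.8), z = rnorm(40, 0, 0.8))
    asn <- tibble::tibble(
      element = c("C", "C", "O", "N"),
      atom_name = c("CB", "CG", "OD1", "ND2"),
      residue_name = "ASN", residue_number = 297L, segment_id = "A",
      x = c(1.6, 1.75, 1.8, 1.9), y = 0, z = 0)
    atomic_model(dplyr::bind_rows(prot, asn))
  })
}

# single free phi dihedral, no steric clash possible: N-CA-C chain plus a
# downstream probe atom
free_dihedral_model <- function() {
  atoms <- tibble::tibble(
    element = "C",
    atom_name = c("N", "CA", "C", "CB"),
    residue_name = "LNK",
    residue_number = c(1L, 1L, 1L, 2L),
    segment_id = "L",
    x = c(0, 0.15, 0.30, 0.45),
    y = c(0, 0.10, 0.00, 0.10),
    z = 0)
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4))
  flex <- tibble::tibble(segment_id = "L", residue_number = 1L,
                         dihedral = "phi")
  m <- atomic_model(atoms, bonds = bonds, flexible_regions = flex)
  m$atoms$xray_b <- 1
  m$atoms$neutron_b <- 1
  m
}

# rotation angle of the probe atom about the N-CA axis, relative to a
# reference frame (degrees in (-180, 180])
probe_angle <- function(frame, ref, ia = 1, ib = 2, probe = 4) {
  u <- ref[ib, ] - ref[ia, ]
  u <- u / sqrt(sum(u^2))
  proj <- function(fr) {
    v <- fr[probe, ] - fr[ia, ]
    v - sum(v * u) * u
  }
  v1 <- proj(ref)
  v2 <- proj(frame)
  ang <- atan2(sum(pracma::cross(v1, v2) * u), sum(v1 * v2)) * 180 / pi
  if (ang <= -180 + 1e-9) ang + 360 else ang
}

# quaternion (Horn) superposition: independent oracle for the Kabsch
# implementation
horn_superpose <- function(mob, ref) {
  mc <- colMeans(mob); rc <- colMeans(ref)
  A <- sweep(mob, 2, mc); B <- sweep(ref, 2, rc)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  sweep(A %*% t(R), 2, rc, "+")
}

# planted two-cluster frame set for PCA tests
planted_cluster_frames <- function(n_per = 20, n_atoms = 15, shift = 2,
                                   spread = 0.02, seed = 7) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
    fr <- c(
      lapply(seq_len(n_per), function(i) {
        base + matrix(rnorm(n_atoms * 3, sd = spread), n_atoms, 3)
      }),
      lapply(seq_len(n_per), function(i) {
        sh <- matrix(0, n_atoms, 3)
        sh[, 1] <- shift
        base + sh + matrix(rnorm(n_atoms * 3, sd = spread), n_atoms, 3)
      }))
    list(frames = fr, truth = rep(1:2, each = n_per))
  })
}
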