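#' Synthetic biantennary glycan template
#'
#' Builds an idealised complex-type biantennary N-glycan — a Man3GlcNAc2
#' core with two NeuNAc.Gal.GlcNAc antennae (11 sugar residues) — as a
#' coarse synthetic geometry: each sugar is a 6-membered pyranose-like ring
#' (5 C + 1 O, ~0.15 nm ring radius) placed along a branching tree at
#' glycosidic spacing, with ring and glycosidic bonds recorded. This is a
#' synthetic stand-in geometry intended for attachment/stripping and
#' low-resolution scattering work, not a force-field-quality structure.
#' The same structure is shipped as
#' `inst/extdata/glycan_biantennary_synthetic.pdb`.
#'
#' @return An [atomic_model()] whose first atom is the reducing-end
#'   GlcNAc C1 (the attachment atom for [attach_glycan()]).
#' @export
make_glycan_template <- function() {
  ring <- function(center, u, v) {
    # 6-membered ring in the plane spanned by u, v
    ang <- (0:5) * pi / 3
    r <- 0.15
    pos <- t(vapply(ang, function(a) {
      center + r * cos(a) * u + r * sin(a) * v
    }, numeric(3)))
    pos
  }
  unitv <- function(x) x / sqrt(sum(x^2))
  residues <- list(
    list(name = "NAG", center = c(0.00, 0, 0),    parent = NA),
    list(name = "NAG", center = c(0.55, 0, 0),    parent = 1),
    list(name = "BMA", center = c(1.10, 0, 0),    parent = 2),
    list(name = "MAN", center = c(1.55,  0.40, 0), parent = 3),
    list(name = "NAG", center = c(2.00,  0.75, 0), parent = 4),
    list(name = "GAL", center = c(2.45,  1.10, 0), parent = 5),
    list(name = "SIA", center = c(2.90,  1.45, 0), parent = 6),
    list(name = "MAN", center = c(1.55, -0.40, 0), parent = 3),
    list(name = "NAG", center = c(2.00, -0.75, 0), parent = 8),
    list(name = "GAL", center = c(2.45, -1.10, 0), parent = 9),
    list(name = "SIA", center = c(2.90, -1.45, 0), parent = 10)
  )
  atoms <- list()
  bonds <- list()
  names6 <- c("C1", "C2", "C3", "C4", "C5", "O5")
  elem6 <- c("C", "C", "C", "C", "C", "O")
  for (i in seq_along(residues)) {
    res <- residues[[i]]
    axis <- if (is.na(res$parent)) c(1, 0, 0) else
      unitv(res$center - residues[[res$parent]]$center)
    v <- unitv(pracma::cross(axis, c(0, 0, 1)))
    # ring tilted out of the chain plane so consecutive rings do not clash
    w <- unitv(pracma::cross(axis, v) + 0.4 * c(0, 0, 1))
    pos <- ring(res$center, v, w)
    # put C1 nearest the parent (start of the ring toward -axis)
    d <- pos %*% axis
    ord <- order(d)
    pos <- pos[c(ord[1], setdiff(seq_len(6), ord[1])), , drop = FALSE]
    base <- (i - 1) * 6
    atoms[[i]] <- tibble(
      element = elem6, atom_name = names6, residue_name = res$name,
      residue_number = i, segment_id = "GLYC",
      x = pos[, 1], y = pos[, 2], z = pos[, 3])
    bonds[[length(bonds) + 1]] <-
      cbind(base + 1:6, base + c(2:6, 1))          # ring bonds
    if (!is.na(res$parent)) {                       # glycosidic bond
      bonds[[length(bonds) + 1]] <-
        cbind((res$parent - 1) * 6 + 4, base + 1)   # parent C4 - child C1
    }
  }
  atomic_model(dplyr::bind_rows(atoms), bonds = do.call(rbind, bonds))
}

#' Attach a glycan template to an asparagine residue
#'
#' Rigid-body placement: the C1 atom of the template's first (reducing-end)
#' GlcNAc is put within `attach_dist` of the Asn sidechain amide nitrogen
#' (ND2), pointing outward from the protein's centre of geometry, and the
#' template is swept deterministically over orientations (golden-angle spin
#' about the placement axis at a few polar tilts) until a pose free of
#' heavy-atom clashes with the protein is found. A glycosidic ND2-C1 bond
#' record is added.
#'
#' @param model An [atomic_model()] containing the target Asn.
#' @param asn_residue A list or vector with `segment_id` and
#'   `residue_number` identifying the asparagine.
#' @param glycan_template An [atomic_model()], by default
#'   [make_glycan_template()].
#' @param attach_dist Target C1-ND2 distance, nm (default 0.13,
#'   within the 0.14 nm placement criterion).
#' @param clash_cutoff Heavy-atom clash distance, nm.
#' @return The model with glycan atoms appended (flagged `is_glycan`) and
#'   the glycosidic bond recorded.
#' @export
attach_glycan <- function(model, asn_residue,
                          glycan_template = make_glycan_template(),
                          attach_dist = 0.13, clash_cutoff = 0.20) {
  a <- model$atoms
  asn_residue <- as.list(asn_residue)
  sel <- which(a$segment_id == asn_residue$segment_id &
               a$residue_number == as.integer(asn_residue$residue_number))
  if (length(sel) == 0) abort("Target residue not found")
  if (toupper(a$residue_name[sel[1]]) != "ASN") {
    abort(sprintf("Target residue %s %s is %s, not ASN",
                  asn_residue$segment_id, asn_residue$residue_number,
                  a$residue_name[sel[1]]))
  }
  nd2 <- sel[a$atom_name[sel] == "ND2"]
  if (length(nd2) != 1) abort("Asn sidechain N (ND2) not resolved")
  nd2_pos <- as.numeric(a[nd2, c("x", "y", "z")])
  prot_xyz <- coords(model)
  heavy_prot <- which(!a$is_hydrogen & !(seq_len(nrow(a)) %in% sel))
  ctr <- colMeans(prot_xyz)
  axis <- nd2_pos - ctr
  axis <- axis / sqrt(sum(axis^2))

  g_xyz0 <- coords(glycan_template)
  g_heavy <- !glycan_template$atoms$is_hydrogen
  c1 <- 1L  # template convention: first atom is the reducing-end C1
  golden <- pi * (3 - sqrt(5))
  best_min <- -Inf
  rot_about <- function(u, theta) {
    u <- u / sqrt(sum(u^2))
    ct <- cos(theta); st <- sin(theta)
    ux <- u[1]; uy <- u[2]; uz <- u[3]
    matrix(c(
      ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
      uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
      uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
      3, 3, byrow = TRUE)
  }
  # align template long axis (C1 -> centroid) onto the outward axis
  t_axis <- colMeans(g_xyz0) - g_xyz0[c1, ]
  t_axis <- t_axis / sqrt(sum(t_axis^2))
  v <- pracma::cross(t_axis, axis)
  s <- sqrt(sum(v^2))
  R0 <- if (s < 1e-12) diag(3) else rot_about(v / s, atan2(s, sum(t_axis * axis)))
  perp <- pracma::cross(axis, if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
  perp <- perp / sqrt(sum(perp^2))
  for (tilt in c(0, 20, -20, 40, -40) * pi / 180) {
    Rt <- rot_about(perp, tilt) %*% R0
    for (k in 0:63) {
      R <- rot_about(axis, k * golden) %*% Rt
      g <- (g_xyz0 - matrix(g_xyz0[c1, ], nrow(g_xyz0), 3, byrow = TRUE)) %*% t(R)
      g <- g + matrix(nd2_pos + attach_dist * axis, nrow(g), 3, byrow = TRUE)
      # min heavy-atom distance glycan vs protein (anchor residue excluded)
      dmin <- min(.min_cross_dist(g[g_heavy, , drop = FALSE],
                                  prot_xyz[heavy_prot, , drop = FALSE]))
      if (dmin > best_min) best_min <- dmin
      if (dmin >= clash_cutoff) {
        return(.merge_glycan(model, glycan_template, g, nd2))
      }
    }
  }
  abort(sprintf(
    "No clash-free glycan placement found; best minimum heavy-atom distance %.3f nm (cutoff %.3f nm)",
    best_min, clash_cutoff))
}

.min_cross_dist <- function(A, B) {
  # min distance between two point sets (vectorised, fine for <= ~1e4 x 1e3)
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  d2 <- outer(aa, bb, "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

.merge_glycan <- function(model, template, g_xyz, nd2_index) {
  ga <- template$atoms
  ga$x <- g_xyz[, 1]; ga$y <- g_xyz[, 2]; ga$z <- g_xyz[, 3]
  n_chains <- length(unique(model$atoms$segment_id[model$atoms$is_glycan]))
  ga$segment_id <- sprintf("GL%02d", n_chains + 1)
  ga$residue_number <- ga$residue_number + max(model$atoms$residue_number)
  ga$is_glycan <- TRUE
  offset <- n_atoms(model)
  bonds <- rbind(model$bonds,
                 template$bonds + offset,
                 c(nd2_index, offset + 1L))
  atoms <- dplyr::bind_rows(model$atoms, ga)
  out <- atomic_model(atoms, bonds = bonds, vbar = model$vbar,
                      flexible_regions = model$flexible_regions)
  out
}
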