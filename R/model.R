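#' Construct an atomic model
#'
#' The central container: an ordered atom table (one row per atom, positions
#' in nm), an optional bond list, rigid-body membership, flexible-region
#' definitions, and solution parameters (mass, partial specific volume).
#'
#' @param atoms A data frame with columns `element`, `atom_name`,
#'   `residue_name`, `residue_number`, `segment_id`, `x`, `y`, `z` (nm).
#'   Optional columns `xray_b` (electrons), `neutron_b` (fm), `is_hydrogen`,
#'   `is_exchangeable`, `is_glycan`, `rigid_body` are filled with defaults
#'   when absent.
#' @param bonds Two-column integer matrix of atom indices (1-based), or NULL.
#' @param mass Molecular mass in kDa; computed from element masses when NA.
#' @param vbar Partial specific volume, ml/g.
#' @param flexible_regions A tibble with columns `segment_id`,
#'   `residue_number`, `dihedral` (one row per variable dihedral), or NULL.
#' @param glycan_residues Extra residue names to flag as glycan.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, bonds = NULL, mass = NA_real_, vbar = 0.73,
                         flexible_regions = NULL,
                         glycan_residues = character()) {
  atoms <- as_tibble(atoms)
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "segment_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste("atoms is missing column(s):", paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("atoms must contain at least one atom")
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) abort("atom positions must be finite")
  if (is.null(atoms[["is_hydrogen"]])) {
    atoms$is_hydrogen <- .element_key(atoms$element) %in% c("H", "D")
  }
  if (is.null(atoms[["is_glycan"]])) {
    atoms$is_glycan <- is_glycan_residue(atoms$residue_name, glycan_residues)
  }
  if (is.null(atoms[["is_exchangeable"]])) atoms$is_exchangeable <- FALSE
  if (any(atoms$is_exchangeable & !atoms$is_hydrogen)) {
    abort("is_exchangeable implies is_hydrogen")
  }
  if (is.null(atoms[["xray_b"]])) atoms$xray_b <- NA_real_
  if (is.null(atoms[["neutron_b"]])) atoms$neutron_b <- NA_real_
  if (is.null(atoms[["rigid_body"]])) atoms$rigid_body <- 0L
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) > 0 &&
        (min(bonds) < 1 || max(bonds) > nrow(atoms))) {
      abort("bond indices out of range")
    }
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  if (is.na(mass)) {
    mass <- sum(element_property(atoms$element, .element_mass,
                                 "mass")) / 1000
  }
  if (mass <= 0) abort("mass must be positive")
  if (is.null(flexible_regions)) {
    flexible_regions <- tibble(segment_id = character(),
                               residue_number = integer(),
                               dihedral = character())
  }
  structure(
    list(atoms = atoms, bonds = bonds, mass = mass, vbar = vbar,
         flexible_regions = as_tibble(flexible_regions)),
    class = "atomic_model"
  )
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<atomic_model> %d atoms (%d glycan, %d hydrogen), %d bonds\n",
    nrow(a), sum(a$is_glycan), sum(a$is_hydrogen), nrow(x$bonds)))
  cat(sprintf("  mass %.1f kDa, vbar %.3f ml/g, %d variable dihedral(s)\n",
              x$mass, x$vbar, nrow(x$flexible_regions)))
  invisible(x)
}

#' Number of atoms in a model
#' @param model An `atomic_model`.
#' @return Integer count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract the coordinate matrix of a model
#' @param model An `atomic_model`.
#' @return An n x 3 numeric matrix (nm).
#' @export
coords <- function(model) {
  unname(as.matrix(model$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a model
#' @param model An `atomic_model`.
#' @param xyz An n x 3 matrix (nm).
#' @return The model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == n_atoms(model), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# scattering-length vector for a contrast, with errors if unassigned
.model_b <- function(model, contrast = c("xray", "neutron")) {
  contrast <- match.arg(contrast)
  b <- if (contrast == "xray") model$atoms$xray_b else model$atoms$neutron_b
  if (anyNA(b)) {
    abort(paste0("Scattering lengths (", contrast, ") not assigned; ",
                 "call assign_scattering_lengths() first"))
  }
  b
}

#' Coordinate-space radius of gyration
#'
#' Scattering-length-weighted RMS distance of the atoms from their weighted
#' centre. With `weights = NULL` the atoms are weighted equally.
#'
#' @param model An `atomic_model`, or an n x 3 coordinate matrix.
#' @param weights Per-atom weights (e.g. scattering lengths); NULL = equal.
#' @return R_G in nm.
#' @export
model_rg <- function(model, weights = NULL) {
  xyz <- if (inherits(model, "atomic_model")) coords(model) else model
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  w <- weights / sum(weights)
  ctr <- colSums(xyz * w)
  d2 <- rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)
  sqrt(sum(w * d2))
}

#' Assign per-atom scattering lengths
#'
#' X-ray amplitudes are atomic numbers (electron counts, the Q -> 0 value;
#' no excluded-volume or hydration term). Neutron amplitudes are tabulated
#' bound coherent scattering lengths; labile hydrogens (bonded to N/O/S)
#' exchange with solvent deuterium as
#' `b = (1 - f_ex * f_D2O) * b_H + f_ex * f_D2O * b_D`.
#' Models without explicit hydrogens get the implicit-H scattering of each
#' known residue folded uniformly into that residue's heavy atoms, using a
#' built-in per-residue count of total and exchangeable hydrogens.
#'
#' @param model An `atomic_model`.
#' @param contrast `"xray"`, `"neutron"`, or `"both"` (default: both columns
#'   are filled; they are independent).
#' @param d2o_fraction Solvent 2H2O volume fraction in \[0, 1\].
#' @param exchange_fraction Fraction of labile H that actually exchange.
#' @return The model with `xray_b` and `neutron_b` columns filled.
#' @export
assign_scattering_lengths <- function(model, contrast = "both",
                                      d2o_fraction = 0,
                                      exchange_fraction = 0.9) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1,
            exchange_fraction >= 0, exchange_fraction <= 1)
  a <- model$atoms
  xb <- element_property(a$element, .element_xray_b, "X-ray scattering")
  nb <- element_property(a$element, .element_neutron_b, "neutron scattering")
  fx <- exchange_fraction * d2o_fraction
  bH <- flexsas_constants$b_H_fm
  bD <- flexsas_constants$b_D_fm
  exch <- a$is_exchangeable
  nb[exch] <- (1 - fx) * bH + fx * bD
  has_h <- any(a$is_hydrogen)
  if (!has_h && any(.element_key(a$element) != "X")) {
    # fold implicit hydrogens into heavy atoms, residue by residue
    res_key <- paste(a$segment_id, a$residue_number)
    for (key in unique(res_key)) {
      sel <- which(res_key == key)
      rname <- toupper(a$residue_name[sel[1]])
      row <- .residue_hydrogens[.residue_hydrogens$residue == rname, ]
      if (nrow(row) == 0) next
      n_h <- row$n_h
      n_ex <- row$n_exch
      b_impl <- (n_h - n_ex) * bH + n_ex * ((1 - fx) * bH + fx * bD)
      nb[sel] <- nb[sel] + b_impl / length(sel)
      xb[sel] <- xb[sel] + n_h / length(sel)
    }
  }
  if (contrast %in% c("xray", "both")) model$atoms$xray_b <- xb
  if (contrast %in% c("neutron", "both")) model$atoms$neutron_b <- nb
  model
}

#' Remove glycan atoms from a model
#'
#' Drops every atom flagged `is_glycan` together with any bond touching it,
#' and recomputes the mass from the remaining elements. A model without
#' glycans is returned unchanged (idempotent).
#'
#' @param model An `atomic_model`.
#' @return The deglycosylated model.
#' @export
strip_glycans <- function(model) {
  keep <- !model$atoms$is_glycan
  if (all(keep)) return(model)
  new_index <- cumsum(keep)
  b <- model$bonds
  if (nrow(b) > 0) {
    ok <- keep[b[, 1]] & keep[b[, 2]]
    b <- cbind(new_index[b[ok, 1]], new_index[b[ok, 2]])
  }
  model$atoms <- model$atoms[keep, ]
  model$bonds <- matrix(as.integer(b), ncol = 2)
  model$mass <- sum(element_property(model$atoms$element, .element_mass,
                                     "mass")) / 1000
  model
}
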