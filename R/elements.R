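# Element tables: atomic numbers (X-ray scattering amplitude in electron
# units at Q -> 0), bound coherent neutron scattering lengths (fm), and
# atomic masses (Da). "X" is a unit point scatterer used by the synthetic
# generators; "D" is deuterium. Neutron lengths are the standard tabulated
# bound coherent values (Sears compilation, as shipped by e.g. periodictable).

.element_xray_b <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
  NA_ = 11, MG = 12, CL = 17, K = 19, CA = 20, FE = 26, ZN = 30, SE = 34,
  X = 1
)

.element_neutron_b <- c(
  H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803, S = 2.847,
  P = 5.13, NA_ = 3.63, MG = 5.375, CL = 9.577, K = 3.67, CA = 4.70,
  FE = 9.45, ZN = 5.680, SE = 7.970, X = 1
)

.element_mass <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA_ = 22.990, MG = 24.305, CL = 35.45, K = 39.098,
  CA = 40.078, FE = 55.845, ZN = 65.38, SE = 78.971, X = 1
)

.element_key <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  key
}

element_property <- function(element, table, what) {
  key <- .element_key(element)
  miss <- setdiff(unique(key), names(table))
  if (length(miss) > 0) {
    abort(paste0("Unknown element(s) for ", what, ": ",
                 paste(sub("_$", "", miss), collapse = ", ")))
  }
  unname(table[key])
}

#' Reference constants
#'
#' Named physical and study-reference constants used across the package:
#' water viscosity and density at 20 degrees C (the s20,w standard state),
#' neutron scattering lengths of hydrogen and deuterium, and the
#' sequence-calculated masses (kDa) and partial specific volumes (ml/g) of
#' the reference glycosylated/deglycosylated IgG4 antibody. Two published
#' values exist for the deglycosylated mass (143.7 and 143.1 kDa); both are
#' carried, and the 143.1 kDa value is the one consistent with the quoted
#' 5.0 kDa mass reduction.
#'
#' @format A named list.
#' @export
flexsas_constants <- list(
  eta_20w_poise   = 0.0100194,
  rho_20w_g_ml    = 0.99823,
  b_H_fm          = -3.7390,
  b_D_fm          = 6.671,
  svedberg_s      = 1e-13,
  avogadro        = 6.02214076e23,
  igg4_mass_glyc_kda          = 148.1,
  igg4_mass_deglyc_kda        = 143.1,
  igg4_mass_deglyc_table_kda  = 143.7,
  igg4_vbar_glyc_ml_g         = 0.730,
  igg4_vbar_deglyc_ml_g       = 0.732,
  igg4_s_glyc_S               = 6.52
)

#' Default Guinier-analysis Q windows (nm^-1)
#'
#' Named presets for the Q fit windows used for antibodies: the overall
#' radius of gyration R_G, and the two cross-sectional fits R_XS-1 (Fab-Fc
#' separation) and R_XS-2 (subunit cross-section). X-ray and neutron R_G
#' windows differ; `rg_xray_wide` is an alternative upper limit sometimes
#' used for the X-ray R_G fit.
#'
#' @format A named list of two-element numeric vectors `c(q_min, q_max)`.
#' @export
q_windows <- list(
  rg_xray      = c(0.10, 0.22),
  rg_xray_wide = c(0.10, 0.27),
  rg_neutron   = c(0.07, 0.27),
  rxs1         = c(0.29, 0.52),
  rxs2         = c(0.66, 1.05)
)

# Residue names recognised as glycan components (PDB chemical component
# codes plus legacy aliases; PDB glycan nomenclature is notoriously
# inconsistent). User-extensible via the `extra` argument of is_glycan_residue().
.glycan_residues <- c(
  "NAG", "NDG", "BMA", "MAN", "GAL", "GLA", "SIA", "SLB", "NAN",
  "FUC", "FUL", "GLC", "BGC", "XYS", "XYP",
  # legacy / force-field aliases
  "AGLC", "BGLC", "AMAN", "BMAN", "AGAL", "BGAL", "ANE5", "BNE5", "NE5A"
)

#' Test residue names against the glycan residue set
#'
#' @param residue_name Character vector of residue names.
#' @param extra Additional residue names to treat as glycans.
#' @return Logical vector.
#' @export
is_glycan_residue <- function(residue_name, extra = character()) {
  toupper(residue_name) %in% c(.glycan_residues, toupper(extra))
}

# Per-residue implicit-hydrogen bookkeeping for models without explicit
# hydrogens: total bonded H and how many are exchangeable (bonded to N/O/S),
# for the 20 amino acids (backbone included, neutral pH protonation) and
# common sugar residues. Used to fold implicit-H scattering into the heavy
# atoms of each residue.
.residue_hydrogens <- tibble::tribble(
  ~residue, ~n_h, ~n_exch,
  "ALA",  7, 1, "ARG", 16, 5, "ASN",  8, 3, "ASP",  7, 1, "CYS",  7, 2,
  "GLN", 10, 3, "GLU",  9, 1, "GLY",  5, 1, "HIS",  9, 2, "ILE", 13, 1,
  "LEU", 13, 1, "LYS", 14, 4, "MET", 11, 1, "PHE", 11, 1, "PRO",  7, 0,
  "SER",  7, 2, "THR",  9, 2, "TRP", 12, 2, "TYR", 11, 2, "VAL", 11, 1,
  "NAG", 13, 3, "NDG", 13, 3, "BMA", 10, 4, "MAN", 10, 4, "GAL", 10, 4,
  "SIA", 17, 5, "FUC", 10, 3, "GLC", 10, 4, "BGC", 10, 4
)
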