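#' Pipeline configuration
#'
#' Assembles (with defaults mirroring the standard analysis: 15 degree
#' torsion step, 0.20 nm clash cutoff, 680-point X-ray / 72-point neutron
#' fit grids on 0-1.5 nm^-1, best-100 selection, 4 PCA groups) the
#' configuration consumed by [run_pipeline()].
#'
#' @param model An [atomic_model()], or NULL to use `model_path`.
#' @param model_path Path to a PDB file (used when `model` is NULL).
#' @param curves List of experiments, each a list with elements `curve` (a
#'   [scattering_curve()] or a file path) and `concentration` (mg/ml).
#' @param contrast `"xray"` or `"neutron"`.
#' @param n_moves,step,cutoff,seed Monte Carlo settings (see
#'   [tamc_sample()]).
#' @param n_points,q_max Fit grid (see [regularize_curve()]); `n_points`
#'   NULL = 680 for X-ray, 72 for neutron.
#' @param n_best Models kept per curve.
#' @param n_groups PCA groups.
#' @param dmax P(r) maximum dimension, nm (NULL = scan with
#'   [estimate_dmax()]).
#' @param n_hydro Number of pooled best-fit models given hull s20,w values.
#' @param d2o_fraction,exchange_fraction Neutron contrast settings.
#' @param output_dir Optional directory for intermediate artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = NULL, model_path = NULL, curves = list(),
                            contrast = "xray", n_moves = 10000, step = 15,
                            cutoff = 0.20, seed = 1, n_points = NULL,
                            q_max = 1.5, n_best = 100, n_groups = 4,
                            dmax = NULL, n_hydro = 25, d2o_fraction = 0,
                            exchange_fraction = 0.9, output_dir = NULL) {
  structure(list(model = model, model_path = model_path, curves = curves,
                 contrast = contrast, n_moves = n_moves, step = step,
                 cutoff = cutoff, seed = seed,
                 n_points = n_points %||%
                   if (contrast == "xray") 680L else 72L,
                 q_max = q_max, n_best = n_best, n_groups = n_groups,
                 dmax = dmax, n_hydro = n_hydro,
                 d2o_fraction = d2o_fraction,
                 exchange_fraction = exchange_fraction,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value sections matching the arguments of [pipeline_config()];
#' `curves` is a list of `{path, concentration}` entries.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$curves <- lapply(y$curves, function(cv) {
    list(curve = cv$path, concentration = cv$concentration)
  })
  do.call(pipeline_config, y)
}

#' Run the full ensemble-fit analysis
#'
#' Orchestrates: conformer sampling -> per-curve Guinier/cross-section/
#' P(r)/Kratky analytics -> curve regularisation -> R-factor scoring ->
#' per-curve best-n selection -> pooled superposition and PCA grouping
#' with centroid models -> hull-based s20,w for the pooled best set.
#' Deterministic given the config seeds.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (length(config$curves) == 0) abort("nothing to fit: no curves supplied")
  model <- config$model %||% (if (!is.null(config$model_path)) {
    read_pdb(config$model_path)
  } else {
    abort("Stage 'input': no model or model_path in config")
  })
  model <- assign_scattering_lengths(model,
                                     d2o_fraction = config$d2o_fraction,
                                     exchange_fraction =
                                       config$exchange_fraction)
  ensemble <- tamc_sample(model, n_moves = config$n_moves,
                          step = config$step, cutoff = config$cutoff,
                          seed = config$seed)
  rg_window <- if (config$contrast == "xray") {
    q_windows$rg_xray
  } else {
    q_windows$rg_neutron
  }
  per_curve <- purrr::imap(config$curves, function(entry, ci) {
    curve <- entry$curve
    if (is.character(curve)) curve <- read_curve(curve, config$contrast)
    gf <- guinier_fit(curve, rg_window[1], rg_window[2])
    rxs1 <- tryCatch(cross_section_fit(curve, which = "RXS1"),
                     error = function(e) NULL)
    rxs2 <- tryCatch(cross_section_fit(curve, which = "RXS2"),
                     error = function(e) NULL)
    reg <- regularize_curve(curve, n_points = config$n_points,
                            q_max = config$q_max, fit = gf)
    dmax <- config$dmax %||% as.numeric(estimate_dmax(reg))
    pr <- tryCatch(ift_pr(reg, dmax = dmax), error = function(e) NULL)
    kr <- kratky_normalized(curve, gf)
    scores <- score_ensemble(ensemble, reg, contrast = config$contrast)
    best <- select_best(scores, n = min(config$n_best, nrow(scores)))
    list(concentration = entry$concentration, guinier = gf,
         rxs1 = rxs1, rxs2 = rxs2, pr = pr,
         kratky_peaks = kratky_peaks(kr), scores = scores, best = best,
         chevron = chevron_table(scores))
  })
  pooled_ids <- unique(unlist(lapply(per_curve, `[[`, "best")))
  pooled <- ensemble$frames[pooled_ids]
  fab_sel <- which(model$atoms$rigid_body %in% c(1L, 3L))
  if (length(fab_sel) == 0) fab_sel <- seq_len(n_atoms(model))
  aligned <- superpose_set(pooled, pooled[[1]], selection = fab_sel)
  pca <- if (length(aligned) >= config$n_groups) {
    tryCatch(pca_cluster(aligned, n_groups = config$n_groups,
                         topology = model, seed = config$seed),
             error = function(e) NULL)
  }
  fc_sel <- which(model$atoms$rigid_body == 2L)
  fc_spread <- if (length(fc_sel) > 0 && length(aligned) > 1) {
    fc_occupancy_summary(aligned, fc_sel)
  } else {
    NA_real_
  }
  hydro_ids <- pooled_ids[seq_len(min(config$n_hydro, length(pooled_ids)))]
  s_values <- vapply(hydro_ids, function(i) {
    hull_s20w(set_coords(model, ensemble$frames[[i]]))$s20w
  }, numeric(1))
  conc <- vapply(per_curve, function(pc) pc$concentration %||% NA_real_,
                 numeric(1))
  rg_series <- tibble(concentration = conc,
                      value = vapply(per_curve,
                                     function(pc) pc$guinier$rg, numeric(1)))
  rg_zero <- if (sum(!is.na(conc)) >= 2) {
    concentration_series_extrapolate(rg_series)
  }
  report <- list(
    per_curve = per_curve,
    ensemble_stats = list(attempted = ensemble$attempted,
                          accepted = ensemble$accepted),
    pooled_best_ids = pooled_ids,
    pca = pca, fc_spread = fc_spread,
    s20w = list(values = s_values, range = range(s_values),
                model_ids = hydro_ids),
    rg_zero_concentration = rg_zero,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config),
                      n_moves = config$n_moves,
                      package_version =
                        as.character(utils::packageVersion("flexsas"))))
  class(report) <- "run_report"
  if (!is.null(config$output_dir)) .persist_report(report, model, config)
  report
}

.persist_report <- function(report, model, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (ci in seq_along(report$per_curve)) {
    write.table(report$per_curve[[ci]]$scores,
                file.path(config$output_dir,
                          sprintf("scores_curve%02d.tsv", ci)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$pca)) {
    write.table(report$pca$projections,
                file.path(config$output_dir, "pca_projections.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  Monte Carlo: %d moves attempted, %d accepted\n",
              x$ensemble_stats$attempted, x$ensemble_stats$accepted))
  for (ci in seq_along(x$per_curve)) {
    pc <- x$per_curve[[ci]]
    rr <- range(pc$scores$r_factor[pc$best])
    cat(sprintf(
      "  curve %d (%.3g mg/ml): R_G %.2f nm; best-%d R-factor %.2f-%.2f%%\n",
      ci, pc$concentration %||% NA, pc$guinier$rg, length(pc$best),
      rr[1], rr[2]))
  }
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: %d groups, PC1 fraction %.2f\n",
                length(x$pca$centroid_ids), x$pca$variance_fractions[1]))
  }
  cat(sprintf("  hull s20,w range: %.2f-%.2f S over %d models\n",
              x$s20w$range[1], x$s20w$range[2], length(x$s20w$values)))
  invisible(x)
}

#' Zero-concentration extrapolation of a parameter series
#'
#' Ordinary (unweighted) least-squares line of parameter value vs
#' concentration; returns the intercept (the infinite-dilution value) with
#' its standard error. With a single concentration the value is returned
#' with a warning and NA standard error.
#'
#' @param values Data frame with columns `concentration` (mg/ml) and
#'   `value`.
#' @param weights Optional per-point weights for weighted least squares.
#' @return A list with `intercept`, `se`, `slope`.
#' @export
concentration_series_extrapolate <- function(values, weights = NULL) {
  stopifnot(all(c("concentration", "value") %in% names(values)))
  if (length(unique(values$concentration)) < 2) {
    warn("Single concentration: returning the value without extrapolation")
    return(list(intercept = values$value[1], se = NA_real_,
                slope = NA_real_))
  }
  fit <- lm(value ~ concentration, data = values, weights = weights)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  list(intercept = unname(coef(fit)[1]), se = sm[1, 2],
       slope = unname(coef(fit)[2]))
}
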