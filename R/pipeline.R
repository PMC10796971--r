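#' Predict type-specific surround suppression from CSR quartiles
#'
#' The combined prediction step: the bottom-quartile mean ribbon CSR is
#' assigned to the strongly suppressed cell type's dendritic arbors and the
#' top-quartile mean to the weakly suppressed type's arbors, the subunit
#' receptive-field model predicts each arbor's spot-size response (center
#' and surround sizes fixed at the values fitted to the strongly suppressed
#' type), and the suppression statistic is averaged per type. No arithmetic
#' beyond composing [predict_response()] and [suppression()].
#'
#' @param q1_csr,q4_csr quartile mean CSR values (`q1_csr <= q4_csr`).
#' @param pixon_skeletons,onalpha_skeletons lists of [tree_morphology()]
#'   dendritic skeletons for the two cell types.
#' @param sigma_c,sigma_s fixed DoG sizes, um (from the strong-suppression
#'   fit).
#' @param diameters spot diameters, um.
#' @param density subunit placement density, um/synapse.
#' @param seed placement seed.
#' @return A one-row data frame of class `prediction_pair` with the two
#'   predicted mean suppressions and the CSR values used.
#' @export
predict_pair <- function(q1_csr, q4_csr, pixon_skeletons, onalpha_skeletons,
                         sigma_c = 22, sigma_s = 75,
                         diameters = default_diameters(), density = 0.3,
                         seed = 1L) {
  if (!(q1_csr <= q4_csr)) stop("q1_csr must be <= q4_csr")
  if (length(pixon_skeletons) == 0L || length(onalpha_skeletons) == 0L)
    stop("skeleton sets must be nonempty")
  # placement seed depends only on the cell index, so identical skeleton
  # sets with equal CSR values give identical predictions
  mean_sup <- function(skeletons, csr) {
    dog <- dog_params(sigma_c = sigma_c, sigma_s = sigma_s,
                      csr = max(csr, 1))
    mean(vapply(seq_along(skeletons), function(i) {
      l <- place_subunits(skeletons[[i]], density = density,
                          seed = derive_seed(seed, "layout", i))
      suppression(predict_response(l, dog, diameters))$suppression
    }, numeric(1)))
  }
  out <- data.frame(
    q1_csr = q1_csr, q4_csr = q4_csr,
    predicted_pixon_suppression = mean_sup(pixon_skeletons, q1_csr),
    predicted_onalpha_suppression = mean_sup(onalpha_skeletons, q4_csr))
  class(out) <- c("prediction_pair", "data.frame")
  out
}

#' Default pipeline configuration
#'
#' Returns the packaged configuration (a nested list, also shipped as a
#' YAML file in `inst/extdata/default_config.yaml`) driving the synthetic
#' generators, the cable model, the CSR sweeps and the receptive-field fit.
#'
#' @param base_seed integer base seed; all stage seeds derive from it.
#' @return A named list.
#' @export
default_config <- function(base_seed = 1L) {
  list(
    base_seed = as.integer(base_seed),
    bc = list(n_ribbons = 84L, n_inhibitory = 120L, n_excitatory = 8L,
              arbor_radius = 20, soma_radius = 3, axon_stalk_length = 30,
              branch_order = 5L, branch_length_mean = 7,
              neurite_radius = 0.15),
    rgc = list(pixon = list(n_cells = 6L, field_diameter = 250,
                            total_dendrite_length = 2500),
               onalpha = list(n_cells = 6L, field_diameter = 350,
                              total_dendrite_length = 3000)),
    rf = list(sigma_c = 22, density = 0.3, true_sigma_s = 100,
              true_csr = 1.8, noise_sd = 0.05),
    sim = list(dt = 0.025, settle_time = 500, stim_time = 1000,
               compartment_max_length = 3),
    sweep = list(n_anchors = 12L, n_grid = c(1L, 10L, 30L, 60L, 120L))
  )
}

#' Read a pipeline configuration file
#' @param path YAML configuration file.
#' @return A config list as from [default_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

# Write a reproducibility manifest beside results.
.write_manifest <- function(out_dir, config, extra = list()) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- c(list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    base_seed = config$base_seed,
    package_version = as.character(utils::packageVersion("arborcsr")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Synthetic skeleton sets for both ganglion cell types.
.gen_rgc_sets <- function(config) {
  gen_set <- function(spec, tag) {
    lapply(seq_len(spec$n_cells), function(i)
      gen_rgc_skeleton(rgc_gen_params(
        seed = derive_seed(config$base_seed, tag, i),
        field_diameter = spec$field_diameter,
        total_dendrite_length = spec$total_dendrite_length)))
  }
  list(pixon = gen_set(config$rgc$pixon, "pixon"),
       onalpha = gen_set(config$rgc$onalpha, "onalpha"))
}

# Synthetic calibrated bipolar cell model.
.gen_bc_model <- function(config, active = TRUE, calibrate = TRUE) {
  bc <- do.call(bc_gen_params,
                c(list(seed = derive_seed(config$base_seed, "bc")),
                  config$bc))
  gen <- gen_bc_morphology(bc)
  cfg <- sim_config(dt = config$sim$dt,
                    settle_time = config$sim$settle_time,
                    stim_time = config$sim$stim_time,
                    seed = derive_seed(config$base_seed, "sim"),
                    compartment_max_length = config$sim$compartment_max_length)
  model <- build_bc_model(gen$morphology, gen$sites, active = active,
                          cfg = cfg)
  if (calibrate) model <- calibrate_rates(model)
  model
}

#' Run the receptive-field fitting experiment
#'
#' Generates synthetic ganglion cell skeletons and spot-size response
#' curves from a known subunit receptive field, fits the DoG subunit model,
#' and (optionally) cross-validates across fitting combinations. Results
#' and a manifest are written as CSV/JSON when `out_dir` is given.
#'
#' @param config a [default_config()]-style list or YAML path.
#' @param out_dir optional output directory.
#' @param n_combinations cross-validation combinations (0 to skip).
#' @return List with the fit, the cross-validation (or NULL), skeletons
#'   and curves.
#' @export
run_rf_fit <- function(config = default_config(), out_dir = NULL,
                       n_combinations = 0L) {
  if (is.character(config)) config <- read_config(config)
  sets <- .gen_rgc_sets(config)
  skeletons <- sets$pixon
  truth <- dog_params(sigma_c = config$rf$sigma_c,
                      sigma_s = config$rf$true_sigma_s,
                      csr = config$rf$true_csr)
  curves <- gen_response_curves(skeletons, truth,
                                noise_sd = config$rf$noise_sd,
                                seed = derive_seed(config$base_seed,
                                                   "curves"),
                                density = config$rf$density)
  fit <- fit_dog(skeletons, curves, sigma_c = config$rf$sigma_c,
                 density = config$rf$density,
                 seed = derive_seed(config$base_seed, "fit"))
  cv <- NULL
  if (n_combinations > 0L) {
    cv <- cross_validate(skeletons, curves,
                         fit_size = max(2L, length(skeletons) %/% 2L),
                         n_combinations = n_combinations,
                         seed = derive_seed(config$base_seed, "cv"),
                         density = config$rf$density,
                         sigma_c = config$rf$sigma_c)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_response_curves(curves, file.path(out_dir, "curves.csv"))
    report <- list(truth = unclass(truth), fitted = coef(fit),
                   mae = fit$mae, per_cell_mae = fit$per_cell_mae)
    jsonlite::write_json(report, file.path(out_dir, "rf_fit.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .write_manifest(out_dir, config, list(stage = "rf_fit"))
  }
  list(fit = fit, cv = cv, skeletons = skeletons, curves = curves,
       truth = truth)
}

#' Run the CSR sweep experiment on the synthetic bipolar cell
#'
#' Builds the synthetic bipolar cell model (active or passive), calibrates
#' the event rates to the -45 / -30 mV and Q1 CSR 1.1 setpoints, and runs
#' N-nearest inhibitory sweeps over the configured grid and anchor count.
#'
#' @param config configuration list or YAML path.
#' @param out_dir optional output directory for tidy CSV results.
#' @param active active or passive membrane.
#' @param model optional pre-built calibrated model (skips generation).
#' @return List with the calibrated `model` and one [sweep_inhibitory_sets()]
#'   result per grid value.
#' @export
run_csr_sweep <- function(config = default_config(), out_dir = NULL,
                          active = TRUE, model = NULL) {
  if (is.character(config)) config <- read_config(config)
  model <- model %||% .gen_bc_model(config, active = active)
  anchors <- with_seed(derive_seed(config$base_seed, "anchors"),
                       sort(sample(model$inhibitory$site_id,
                                   min(config$sweep$n_anchors,
                                       nrow(model$inhibitory)))))
  n_grid <- pmin(config$sweep$n_grid, nrow(model$inhibitory))
  n_grid <- sort(unique(n_grid))
  sweeps <- lapply(n_grid, function(n)
    sweep_inhibitory_sets(model, n_active = n, anchors = anchors,
                          seed = derive_seed(config$base_seed, "sweep", n)))
  names(sweeps) <- as.character(n_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ribbons <- do.call(rbind, lapply(sweeps, `[[`, "ribbons"))
    utils::write.csv(ribbons, file.path(out_dir, "csr_ribbons.csv"),
                     row.names = FALSE)
    summary_df <- do.call(rbind, lapply(sweeps, function(s)
      data.frame(n_active = s$n_active, t(s$range_summary),
                 inh_rate = s$inh_rate)))
    utils::write.csv(summary_df, file.path(out_dir, "csr_summary.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, config,
                    list(stage = "csr_sweep", active = active))
  }
  list(model = model, sweeps = sweeps, anchors = anchors)
}

#' Run the combined suppression-prediction experiment
#'
#' Couples the bipolar cable model's CSR quartiles to the subunit
#' receptive-field model: for each sweep condition, the across-anchor mean
#' Q1 and Q4 CSR values drive [predict_pair()] on synthetic dendritic
#' arbors of the two ganglion cell types.
#'
#' @param config configuration list or YAML path.
#' @param out_dir optional output directory.
#' @param sweep_result a [run_csr_sweep()] result (generated if NULL).
#' @param sigma_s surround size fixed for the predictions, um.
#' @return data frame with one row per sweep condition.
#' @export
run_prediction <- function(config = default_config(), out_dir = NULL,
                           sweep_result = NULL, sigma_s = 75) {
  if (is.character(config)) config <- read_config(config)
  sweep_result <- sweep_result %||% run_csr_sweep(config)
  sets <- .gen_rgc_sets(config)
  rows <- lapply(sweep_result$sweeps, function(s) {
    pair <- predict_pair(mean(s$per_anchor$q1_mean),
                         mean(s$per_anchor$q4_mean),
                         sets$pixon, sets$onalpha,
                         sigma_c = config$rf$sigma_c, sigma_s = sigma_s,
                         density = config$rf$density,
                         seed = derive_seed(config$base_seed, "pair"))
    cbind(data.frame(n_active = s$n_active), pair)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "predicted_suppression.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, config, list(stage = "prediction"))
  }
  out
}
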