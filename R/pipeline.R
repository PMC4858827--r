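#' Configuration of a full synthetic modality-comparison study
#'
#' One synthetic "patient" is a phantom geometry imaged under the three
#' modality profiles, reconstructed from each volume, and quantified
#' morphologically and hemodynamically; the cohort is then compared
#' against the DRA-derived reference model (DM), mirroring a
#' three-modality patient study at desk scale.
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param base_spec Template `aneurysm_spec`; per-patient geometry varies
#'   around it within `variation`.
#' @param variation Named list of half-ranges for per-patient uniform
#'   jitter of `sac_radius`, `neck_radius`, `parent_curvature` and
#'   `sac_offset_angle`.
#' @param profiles Named list of three `modality_profile`s.
#' @param seg_config A `segmentation_config` (seed point is set
#'   automatically per patient).
#' @param hemo_cfg A `hemo_config`.
#' @param wss_spec A `wss_synthesis_spec`.
#' @param wave A `waveform`.
#' @param master_seed Integer master seed; per-patient seeds are fanned
#'   out deterministically.
#' @param output_root Output directory, or NULL to skip file output.
#' @return A `study_config`.
#' @export
study_config <- function(n_patients = 5,
                         base_spec = aneurysm_spec(),
                         variation = list(sac_radius = 0.4,
                                          neck_radius = 0.25,
                                          parent_curvature = 0.02,
                                          sac_offset_angle = 0),
                         profiles = default_modality_profiles(),
                         seg_config = segmentation_config(),
                         hemo_cfg = hemo_config(),
                         wss_spec = wss_synthesis_spec(),
                         wave = default_waveform(),
                         master_seed = 1L,
                         output_root = NULL) {
  stopifnot(n_patients >= 1, length(profiles) == 3)
  structure(list(n_patients = as.integer(n_patients), base_spec = base_spec,
                 variation = variation, profiles = profiles,
                 seg_config = seg_config, hemo_cfg = hemo_cfg,
                 wss_spec = wss_spec, wave = wave,
                 master_seed = as.integer(master_seed),
                 output_root = output_root),
            class = "study_config")
}

fan_seed <- function(master, i, salt = 0L) {
  as.integer((as.numeric(master) * 7919 + i * 104729 + salt * 31) %%
               2147483647)
}

patient_spec <- function(config, i) {
  v <- config$variation
  b <- config$base_spec
  with_seed(fan_seed(config$master_seed, i, 1L), {
    jit <- function(x, key) {
      h <- v[[key]]
      if (is.null(h) || h == 0) x else x + runif(1, -h, h)
    }
    aneurysm_spec(
      parent_radius = b$parent_radius,
      parent_length = b$parent_length,
      parent_curvature = max(0, jit(b$parent_curvature, "parent_curvature")),
      sac_radius = jit(b$sac_radius, "sac_radius"),
      neck_radius = min(jit(b$neck_radius, "neck_radius"),
                        b$sac_radius - 0.1),
      sac_offset_angle = max(0, jit(b$sac_offset_angle, "sac_offset_angle")),
      mesh_edge_length = b$mesh_edge_length,
      rng_seed = fan_seed(config$master_seed, i, 2L))
  })
}

modality_code <- c(DRA_like = "DM", CTA_like = "CM", MRA_like = "MM")

#' Run the full synthetic modality-comparison study
#'
#' For each synthetic patient: build the phantom, render the three
#' modality volumes, reconstruct a model from each, partition regions
#' using the phantom's analytic neck curve, compute morphometrics, map one
#' shared synthetic WSS field onto every reconstruction and compute the
#' hemodynamic reports, and measure surface distances of the CTA-like and
#' MRA-like models against the DRA-like reference. Finally summarize the
#' cohort (percent differences, paired Wilcoxon). Failures quarantine the
#' affected patient; the study continues.
#'
#' @param config A `study_config`.
#' @return A `study_result`: list with `patients` (per-patient bundles),
#'   `morpho`, `hemo`, `distance` (long data frames), `comparison`
#'   (a `comparison_result`), `failed` (quarantined patient ids) and
#'   `config_hash`.
#' @export
run_study <- function(config = study_config()) {
  t0 <- Sys.time()
  cfg_hash <- hash_object(config[setdiff(names(config), "output_root")])
  out_root <- config$output_root
  if (!is.null(out_root))
    dir.create(out_root, showWarnings = FALSE, recursive = TRUE)
  patients <- list()
  failed <- character()
  vrows <- list(); drows <- list(); hrows <- list(); mrows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    res <- tryCatch(
      run_one_patient(config, i, pid, cfg_hash),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("patient %s quarantined: %s", pid,
                      conditionMessage(res)))
      failed <- c(failed, pid)
      next
    }
    patients[[pid]] <- res
    mrows[[pid]] <- res$morpho_long
    hrows[[pid]] <- res$hemo_long
    drows[[pid]] <- res$dist_long
  }
  morpho <- do.call(rbind, mrows)
  hemo <- do.call(rbind, hrows)
  dist <- do.call(rbind, drows)
  comparison <- NULL
  if (length(patients) >= 2) {
    # surface distance is pairwise against DM already (raw mm); it is
    # summarized separately in `distance`, not as a percent difference
    values <- rbind(morpho, hemo)
    comparison <- summarize_cohort(values, reference = "DM")
  }
  result <- structure(list(
    patients = patients, morpho = morpho, hemo = hemo, distance = dist,
    comparison = comparison, failed = failed, config_hash = cfg_hash,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_result")
  if (!is.null(out_root)) write_study_outputs(result, config, out_root)
  result
}

run_one_patient <- function(config, i, pid, cfg_hash) {
  spec <- patient_spec(config, i)
  ph <- build_phantom_mesh(spec)
  curve <- phantom_neck_curve(spec)
  wss_spec <- config$wss_spec
  wss_spec$rng_seed <- fan_seed(config$master_seed, i, 3L)
  field <- synthesize_wss(ph$mesh, config$wave, wss_spec)

  recons <- list()
  morpho_rows <- list(); hemo_rows <- list(); dist_rows <- list()
  for (mod in names(config$profiles)) {
    prof <- config$profiles[[mod]]
    prof$rng_seed <- fan_seed(config$master_seed, i,
                              4L + match(mod, names(config$profiles)))
    vol <- voxelize(spec, prof)
    seg <- config$seg_config
    seg$seed_point <- c(0, 0, 0)             # tube centre is always lumen
    mesh <- reconstruct_model(vol, seg, neck_curve = curve,
                              d1 = 2 * spec$parent_radius)
    code <- modality_code[[mod]]
    recons[[code]] <- mesh
    mr <- morphometrics(mesh)
    morpho_rows[[code]] <- data.frame(
      patient_id = pid, modality = code,
      parameter = c("size", "AR", "NA", "PVD", "SR", "AA"),
      value = c(mr$size, mr$AR, mr[["NA"]], mr$PVD, mr$SR, mr$AA),
      stringsAsFactors = FALSE)
    fmap <- map_wss_field(field, mesh)
    hr <- regional_statistics(fmap, config$hemo_cfg)
    hnames <- c("AWSS_A", "AWSS_P", "LWSS_A", "MWSS_A", "WSS90_A",
                "OSI_A", "MOSI_A", "HOSI_A", "AWSSG_A")
    hemo_rows[[code]] <- data.frame(
      patient_id = pid, modality = code, parameter = hnames,
      value = unlist(hr[hnames]), stringsAsFactors = FALSE)
  }
  for (code in c("CM", "MM")) {
    dr <- symmetric_distance(recons$DM, recons[[code]], density = 4)
    dist_rows[[code]] <- data.frame(
      patient_id = pid, modality = code, mean = dr$mean, sd = dr$sd,
      max = dr$max, stringsAsFactors = FALSE)
  }
  list(spec = spec, phantom = ph, field_summary = NULL,
       recons = recons, cfg_hash = cfg_hash,
       ground_truth = ph$ground_truth,
       morpho_long = do.call(rbind, morpho_rows),
       hemo_long = do.call(rbind, hemo_rows),
       dist_long = do.call(rbind, dist_rows))
}

write_study_outputs <- function(result, config, out_root) {
  stamp <- list(config_hash = result$config_hash,
                master_seed = config$master_seed,
                package_version = as.character(utils::packageVersion("aneumorph")))
  for (pid in names(result$patients)) {
    pd <- file.path(out_root, pid)
    dir.create(pd, showWarnings = FALSE, recursive = TRUE)
    p <- result$patients[[pid]]
    jsonlite::write_json(
      c(stamp, list(patient_id = pid,
                    morpho = split(p$morpho_long$value,
                                   p$morpho_long$modality),
                    hemo = split(p$hemo_long$value, p$hemo_long$modality),
                    distance = p$dist_long)),
      file.path(pd, "reports.json"), digits = NA, auto_unbox = TRUE)
  }
  sm <- file.path(out_root, "summary")
  dir.create(sm, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$morpho, file.path(sm, "cohort_morpho.csv"),
            row.names = FALSE)
  write.csv(result$hemo, file.path(sm, "cohort_hemo.csv"), row.names = FALSE)
  write.csv(result$distance, file.path(sm, "cohort_distance.csv"),
            row.names = FALSE)
  if (!is.null(result$comparison)) {
    d <- result$comparison$differences
    write.csv(d[d$parameter %in% c("size", "AR", "NA", "PVD", "SR", "AA"), ],
              file.path(sm, "table_morpho_differences.csv"),
              row.names = FALSE)
    write.csv(d[grepl("WSS|OSI", d$parameter), ],
              file.path(sm, "table_hemo_differences.csv"), row.names = FALSE)
    jsonlite::write_json(c(stamp, list(differences = d)),
                         file.path(sm, "summary.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(out_root)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d patients (%d quarantined), %.1f s\n",
              length(x$patients), length(x$failed), x$elapsed_s))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
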