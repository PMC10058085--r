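#' Pipeline configuration
#'
#' One object collecting every stage's parameters plus the decision
#' thresholds, so a run is fully reproducible from the config and the seed.
#'
#' @param cohort a [cohort_config()].
#' @param rc_params a [renkin_crone_params()].
#' @param solver a [solver_settings()].
#' @param ffr_threshold positivity cutoff on FFR. Default 0.80.
#' @param gray_zone gray-zone interval. Default `c(0.75, 0.80)`.
#' @param cac_threshold Agatston cutoff for severe calcification. Default 400.
#' @param qca_breaks QCA stratum boundaries. Default `c(30, 50, 70, 90)`.
#' @param out_dir output directory.
#' @param seed master seed; overrides `cohort$seed`.
#' @param write_images write NIfTI maps/territories per patient. Default
#'   `TRUE`.
#' @param map_kind `"mbf"` or `"k1"`; see [compute_ctp_ffr()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            rc_params = renkin_crone_params(),
                            solver = solver_settings(),
                            ffr_threshold = 0.80,
                            gray_zone = c(0.75, 0.80),
                            cac_threshold = 400,
                            qca_breaks = c(30, 50, 70, 90),
                            out_dir = tempfile("ctpffr-run-"),
                            seed = cohort$seed,
                            write_images = TRUE,
                            map_kind = "mbf") {
  stopifnot(ffr_threshold > 0, ffr_threshold <= 1,
            length(gray_zone) == 2, gray_zone[1] <= gray_zone[2])
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, rc_params = rc_params, solver = solver,
                 ffr_threshold = ffr_threshold, gray_zone = gray_zone,
                 cac_threshold = cac_threshold, qca_breaks = qca_breaks,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_images = write_images, map_kind = map_kind),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param config a [pipeline_config()].
#' @param path a `.yaml` path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  rc <- do.call(renkin_crone_params, y$rc_params %||% list())
  solver <- do.call(solver_settings, y$solver %||% list())
  extras <- y[setdiff(names(y), c("cohort", "rc_params", "solver"))]
  do.call(pipeline_config,
          c(list(cohort = cohort, rc_params = rc, solver = solver), extras))
}

#' Run the full simulate-to-evaluate pipeline
#'
#' Executes every stage for each patient - simulate (tree, map, ground
#' truth), territories, boundary conditions, network solve, per-vessel
#' CTP-FFR - then the cohort evaluation, writing each stage's artifact
#' (tree JSON, NIfTI map and territories, BC and result CSVs, metrics JSON)
#' under `config$out_dir` along with a manifest of config hash, seed and
#' output checksums. Identical config + seed reproduce identical text
#' outputs and manifest hash.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `records` (per-vessel results),
#'   `diagnostics` ([evaluate_cohort()]) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config$cohort, settings = config$solver)

  checksummed <- character(0)
  listed <- character(0)
  results <- purrr::map_dfr(cohort$patients, function(p) {
    stem <- file.path(out, sprintf("patient-%03d", p$patient_id))
    write_tree_json(p$tree, paste0(stem, "-tree.json"))
    checksummed <<- c(checksummed, paste0(stem, "-tree.json"))
    map <- p$map
    if (config$map_kind == "k1") map <- map_mbf_to_k1(map, config$rc_params)
    ana <- compute_ctp_ffr(p$tree, map, p$hemo, settings = config$solver,
                           map_kind = config$map_kind,
                           rc_params = config$rc_params)
    if (isTRUE(config$write_images)) {
      write_mbf_nifti(p$map, paste0(stem, "-mbf.nii.gz"))
      write_territories_nifti(ana$territories, p$map,
                              paste0(stem, "-territories.nii.gz"))
      listed <<- c(listed, paste0(stem, "-mbf.nii.gz"),
                   paste0(stem, "-mbf_mask.nii.gz"),
                   paste0(stem, "-territories.nii.gz"))
    }
    readr::write_csv(ana$bc, paste0(stem, "-bc.csv"))
    checksummed <<- c(checksummed, paste0(stem, "-bc.csv"))
    dplyr::left_join(p$truth, ana$vessels, by = "vessel")
  })

  results_path <- file.path(out, "vessel-results.csv")
  readr::write_csv(results, results_path)
  diag <- evaluate_cohort(results, index_threshold = config$ffr_threshold,
                          reference_threshold = config$ffr_threshold)
  metrics_path <- file.path(out, "metrics.json")
  jsonlite::write_json(
    list(metrics = tidy(diag), summary = glance(diag)),
    metrics_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  checksummed <- c(checksummed, results_path, metrics_path)

  manifest <- list(
    package = "ctpffr",
    version = as.character(utils::packageVersion("ctpffr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(lapply(unclass(config)[
      setdiff(names(config), "out_dir")],
      function(x) if (is.list(x)) unclass(x) else x)),
    n_patients = length(cohort$patients),
    n_vessels = nrow(results),
    checksums = as.list(tools::md5sum(checksummed)),
    other_outputs = basename(listed)
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(records = results, diagnostics = diag, manifest = manifest,
                 manifest_path = manifest_path))
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes the MD5 checksum of every stage output listed in the manifest
#' and errors on the first mismatch, so silent tampering or truncation of a
#' stage output is caught.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return `TRUE` invisibly if all checksums match.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (f in names(man$checksums)) {
    actual <- unname(tools::md5sum(f))
    if (is.na(actual) || !identical(actual, man$checksums[[f]])) {
      abort(sprintf("checksum mismatch for stage output '%s'", f),
            class = "ctpffr_manifest_error")
    }
  }
  invisible(TRUE)
}

#' Convert an MBF map to a K1 map (Renkin-Crone forward direction)
#'
#' Emulates a scanner export that reports the uncorrected transfer constant:
#' per-mL MBF is taken per-gram through the tissue density, pushed through
#' the extraction relation, and returned per-mL.
#'
#' @param map an [mbf_map()].
#' @param rc_params a [renkin_crone_params()].
#' @return an [mbf_map()] whose masked values are K1.
#' @export
map_mbf_to_k1 <- function(map, rc_params = renkin_crone_params()) {
  idx <- masked_indices(map)
  v <- map$values[idx] / rc_params$tissue_density
  pos <- v > 0
  v[pos] <- k1_from_mbf(v[pos], rc_params)
  map$values[idx] <- v * rc_params$tissue_density
  map
}
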