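# Dataset container and run configuration.
#
# A dataset container is a directory of named arrays: `metadata.csv` plus
# one subdirectory per sample holding the cube (`cube.bin`) and its
# wavelength axis (`wavelength_nm.bin`) as little-endian float64, and a
# JSON descriptor (`attrs.json`) with the array dimensions and the sample
# attributes. Numeric payloads live in the binary files so round trips
# are bit-exact. The schema is validated field by field on read.

container_attrs <- c("dims", "excitation_nm", "laser_index",
                     "pixel_pitch_mm", "shrimp_id", "day")

write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L, endian = "little")
}

read_f64 <- function(path, n, what) {
  if (!file.exists(path)) {
    abort(sprintf("container is missing `%s`", what),
          class = "sors_schema_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) != n) {
    abort(sprintf("`%s` holds %d values, expected %d", what,
                  length(vals), n), class = "sors_schema_error")
  }
  vals
}

#' Write a raw dataset to a container directory
#'
#' @param dataset Tibble from [generate_dataset()] (list-column `cube`).
#' @param path Directory to create (must not already contain samples).
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- dplyr::select(dataset, "sample_id", "shrimp_id", "day",
                        "laser_index")
  write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE)
  for (i in seq_len(nrow(dataset))) {
    cube <- dataset$cube[[i]]
    d <- file.path(path, "samples", dataset$sample_id[i])
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_f64(cube$data, file.path(d, "cube.bin"))
    write_f64(cube$wavelength_nm, file.path(d, "wavelength_nm.bin"))
    jsonlite::write_json(
      list(dims = dim(cube$data),
           excitation_nm = cube$excitation_nm,
           laser_index = cube$laser_index,
           pixel_pitch_mm = cube$pixel_pitch_mm,
           shrimp_id = cube$shrimp_id,
           day = cube$day),
      file.path(d, "attrs.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a dataset container
#'
#' @param path Container directory written by [write_container()].
#' @return A tibble as produced by [generate_dataset()] (without the
#'   simulator's ground-truth artifact records).
#' @export
read_container <- function(path) {
  meta_path <- file.path(path, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort("container is missing `metadata.csv`", class = "sors_schema_error")
  }
  meta <- as_tibble(read.csv(meta_path, stringsAsFactors = FALSE))
  need <- c("sample_id", "shrimp_id", "day", "laser_index")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("metadata.csv is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "sors_schema_error")
  }
  cubes <- purrr::map(meta$sample_id, function(sid) {
    d <- file.path(path, "samples", sid)
    aj <- file.path(d, "attrs.json")
    if (!file.exists(aj)) {
      abort(sprintf("sample %s: missing attrs.json", sid),
            class = "sors_schema_error")
    }
    at <- jsonlite::read_json(aj, simplifyVector = TRUE)
    miss <- setdiff(container_attrs, names(at))
    if (length(miss)) {
      abort(sprintf("sample %s: attrs.json is missing field(s): %s",
                    sid, paste(miss, collapse = ", ")),
            class = "sors_schema_error")
    }
    vals <- read_f64(file.path(d, "cube.bin"), prod(at$dims),
                     paste0(sid, "/cube.bin"))
    wl <- read_f64(file.path(d, "wavelength_nm.bin"), at$dims[3],
                   paste0(sid, "/wavelength_nm.bin"))
    structure(list(data = array(vals, dim = at$dims),
                   wavelength_nm = wl,
                   excitation_nm = at$excitation_nm,
                   laser_index = as.integer(at$laser_index),
                   pixel_pitch_mm = at$pixel_pitch_mm,
                   shrimp_id = as.integer(at$shrimp_id),
                   day = as.integer(at$day)),
              class = "sors_cube")
  })
  if (nrow(meta) != length(cubes)) {
    abort("metadata row count does not match sample count",
          class = "sors_schema_error")
  }
  dplyr::mutate(meta, cube = cubes)
}

# ---- run configuration -----------------------------------------------------

run_config_sections <- c("simulation", "preprocess", "model", "evaluation",
                         "seed")

#' Read a run configuration file
#'
#' YAML with optional sections `simulation`, `preprocess`, `model`,
#' `evaluation` (each holding arguments for the corresponding
#' constructor) and a global `seed`. Unknown sections or keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A list of class `sors_run_config` with fully-constructed
#'   configuration objects.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_sections)
  if (length(unknown)) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "sors_schema_error")
  }
  check_keys <- function(vals, fn, section) {
    bad <- setdiff(names(vals), names(formals(fn)))
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s`: %s", section,
                    paste(bad, collapse = ", ")),
            class = "sors_schema_error")
    }
    vals
  }
  seed <- raw$seed %||% 1L
  sim_args <- check_keys(raw$simulation %||% list(), sim_config, "simulation")
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  cfg <- list(
    simulation = do.call(sim_config, sim_args),
    preprocess = do.call(preprocess_config,
                         check_keys(raw$preprocess %||% list(),
                                    preprocess_config, "preprocess")),
    model = do.call(model_spec,
                    check_keys(raw$model %||% list(), model_spec, "model")),
    evaluation = do.call(eval_protocol,
                         check_keys(raw$evaluation %||% list(),
                                    eval_protocol, "evaluation")),
    seed = as.integer(seed))
  class(cfg) <- "sors_run_config"
  cfg
}

#' Run the complete pipeline from a configuration
#'
#' Simulate, preprocess, train the full model and its ablations, fit the
#' baselines and evaluate, writing all artifacts (metrics JSON,
#' prediction and box-stat CSVs, loss history, manifest) to a directory.
#'
#' @param config A `sors_run_config` from [read_run_config()], or `NULL`
#'   to use defaults.
#' @param out_dir Output directory.
#' @param include_ablations,include_baselines Toggle comparison models.
#' @return The `sors_eval` report, invisibly; artifacts on disk.
#' @export
run_all <- function(config = NULL, out_dir,
                    include_ablations = TRUE, include_baselines = TRUE) {
  if (is.null(config)) {
    config <- structure(list(simulation = sim_config(),
                             preprocess = preprocess_config(),
                             model = model_spec(),
                             evaluation = eval_protocol(),
                             seed = 1L),
                        class = "sors_run_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  processed <- simulate_processed_dataset(config$simulation,
                                          config$preprocess)
  models <- list(attention_lstm = config$model)
  if (include_ablations) {
    models$no_lstm <- ablate(config$model, "lstm")
    models$no_attention <- ablate(config$model, "attention")
    models$no_fc <- ablate(config$model, "fc")
  }
  if (include_baselines) {
    models <- c(models, list(plsr = "plsr", svr = "svr", et = "et"))
  }
  ev <- run_experiment(processed, models, config$evaluation)
  jsonlite::write_json(ev$summary, file.path(out_dir, "metrics.json"),
                       digits = NA, dataframe = "rows")
  write.csv(ev$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(ev$box, file.path(out_dir, "box_stats.csv"), row.names = FALSE)
  manifest <- list(
    n_samples = nrow(processed),
    n_test = length(ev$split$test),
    seed = config$seed,
    models = names(models),
    file_md5 = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                pattern = "[.](csv|json)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
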