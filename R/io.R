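# Plain-text serialization: traces as CSV, parameter vectors as JSON,
# populations as CSV with a JSON metadata sidecar.

#' Write conductance or voltage traces to CSV
#'
#' Long format with columns (time_ms, value, species, depolarization_mV,
#' convention).
#'
#' @param traces A single trace data frame or a list of them.  Conductance
#'   traces carry `g`/`species`/`depolarization_mV`; voltage traces carry
#'   `V_mV` (species recorded as "membrane").
#' @param path Output CSV path.
#' @export
write_traces <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    if ("g" %in% names(tr)) {
      data.frame(time_ms = tr$time_ms, value = tr$g, species = tr$species,
                 depolarization_mV = tr$depolarization_mV,
                 convention = "HH")
    } else {
      data.frame(time_ms = tr$time_ms, value = tr$V_mV,
                 species = "membrane", depolarization_mV = NA_real_,
                 convention = "HH")
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return List of trace data frames, split by species and depolarization.
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  key <- paste0(df$species, "_", df$depolarization_mV)
  lapply(split(df, key), function(b) {
    if (b$species[1] == "membrane")
      data.frame(time_ms = b$time_ms, V_mV = b$value)
    else
      data.frame(time_ms = b$time_ms, g = b$value, species = b$species,
                 depolarization_mV = b$depolarization_mV)
  })
}

#' Write a parameter vector and membrane constants as JSON
#'
#' @param params [voltage_params()] or [gating_rates()] vector.
#' @param path Output path.
#' @param consts Optional [membrane_constants()] config block.
#' @export
write_params_json <- function(params, path, consts = NULL) {
  obj <- list(parameters = as.list(unclass(params)))
  if (!is.null(consts)) obj$constants <- as.list(unclass(consts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a parameter JSON written by [write_params_json()]
#'
#' @param path JSON path.
#' @return List with `parameters` (named numeric) and optionally
#'   `constants`.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- unlist(obj$parameters)
  if (!is.null(obj$constants)) obj$constants <- unlist(obj$constants)
  obj
}

#' Write an ABC-SMC fit to disk
#'
#' Populations go to `<stem>_populations.csv` (generation, particle_id,
#' weight, distance, one column per parameter); run metadata (seed, epsilon
#' history, draw counts) to `<stem>_meta.json`.
#'
#' @param fit An `hh_abc_fit`.
#' @param stem Output path stem.
#' @return Invisibly, the two paths written.
#' @export
write_abc_fit <- function(fit, stem) {
  rows <- lapply(fit, function(pop) {
    data.frame(generation = pop$generation,
               particle_id = seq_len(nrow(pop$theta)),
               weight = pop$weight, distance = pop$distance,
               as.data.frame(pop$theta))
  })
  csv <- paste0(stem, "_populations.csv")
  meta <- paste0(stem, "_meta.json")
  write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  jsonlite::write_json(
    list(seed = attr(fit, "seed"),
         epsilon_history = attr(fit, "epsilon_history"),
         draw_history = attr(fit, "draw_history"),
         parameters = colnames(fit[[1]]$theta)),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Read an ABC-SMC fit written by [write_abc_fit()]
#'
#' @param stem Path stem used when writing.
#' @return An `hh_abc_fit`.
#' @export
read_abc_fit <- function(stem) {
  df <- read.csv(paste0(stem, "_populations.csv"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  pnames <- meta$parameters
  pops <- lapply(split(df, df$generation), function(b) {
    th <- as.matrix(b[, pnames, drop = FALSE])
    rownames(th) <- NULL
    eps <- meta$epsilon_history[b$generation[1] + 1]
    .new_population(th, b$weight, b$distance, eps, b$generation[1],
                    meta$draw_history[b$generation[1] + 1])
  })
  pops <- pops[order(as.integer(names(pops)))]
  names(pops) <- NULL
  structure(pops, class = "hh_abc_fit",
            epsilon_history = meta$epsilon_history,
            draw_history = meta$draw_history, seed = meta$seed)
}

#' Write a synthetic clamp dataset to a directory
#'
#' One CSV per trace plus `manifest.json` carrying the generating spec,
#' seed and ground-truth parameters.
#'
#' @param dataset An `hh_synth_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_clamp_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dataset$traces))
    write.csv(dataset$traces[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  spec <- dataset$truth$spec
  manifest <- list(
    true_params = as.list(unclass(dataset$truth$params)),
    depolarizations = spec$depolarizations[c("K", "Na")],
    excluded = spec$depolarizations$excluded,
    duration_ms = spec$duration_ms,
    sample_interval_ms = spec$sample_interval_ms,
    subsample = spec$subsample, noise_sd = spec$noise_sd,
    noise_mode = spec$noise_mode, seed = spec$seed,
    constants = as.list(unclass(spec$consts)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic clamp dataset directory
#'
#' @param dir Directory written by [write_clamp_dataset()].
#' @return An `hh_synth_dataset` (without the `clean` traces, which are
#'   regenerable from the manifest's ground truth).
#' @export
read_clamp_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), character())
  traces <- lapply(files, function(f) read.csv(file.path(dir, f)))
  names(traces) <- sub("\\.csv$", "", files)
  params <- voltage_params(unlist(manifest$true_params))
  structure(list(traces = traces, clean = NULL,
                 truth = list(params = params, manifest = manifest)),
            class = "hh_synth_dataset")
}
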