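#' Write a plate dataset to the long-format CSV dialect
#'
#' The table holds one row per bin per well (`time_s`, `well_id`,
#' `counts`; time is seconds from recording start, bin-end convention). A
#' JSON sidecar (same path with `.json`) carries the integration time,
#' phase-change times and per-well metadata.
#'
#' @param dataset a `plate_dataset`.
#' @param path CSV path; the sidecar replaces its extension with `.json`.
#' @return the CSV path, invisibly.
#' @export
write_plate <- function(dataset, path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  all_wells <- c(dataset$wells, dataset$empty)
  tau <- dataset$config$tau
  tabs <- lapply(all_wells, function(w) {
    n <- length(w$trace$counts)
    data.frame(time_s = seq_len(n) * tau, well_id = w$well_id,
               counts = w$trace$counts)
  })
  tab <- do.call(rbind, tabs)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  w1 <- all_wells[[1L]]
  meta <- list(
    tau = tau,
    injection_time_s = w1$trace$injection * tau,
    discharge_time_s = w1$trace$discharge * tau,
    seed = dataset$seed,
    wells = stats::setNames(lapply(all_wells, function(w) {
      list(preset_id = w$preset_id, species = w$species, tissue = w$tissue,
           stimulus = w$stimulus, dose = w$dose, dose_units = w$dose_units,
           la3plus = w$la3plus, section_id = w$section_id,
           replicate = w$replicate, is_empty = w$is_empty, seed = w$seed)
    }), vapply(all_wells, function(w) w$well_id, character(1))))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a plate dataset from CSV + JSON sidecar
#'
#' Strict validation: every well in the table must be described in the
#' sidecar, counts must be non-negative, all wells must share one time
#' axis, the time spacing must equal the sidecar's integration time, and
#' the discharge time must be present; violations raise errors naming the
#' offending well or field.
#'
#' @param path the plate CSV (sidecar found next to it).
#' @return a `plate_dataset`.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop(sprintf("plate file '%s' not found", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop(sprintf("metadata sidecar '%s' not found", sc))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "well_id", "counts") %in% names(tab)))
    stop("plate table must have columns time_s, well_id, counts")
  meta <- jsonlite::read_json(sc, simplifyVector = FALSE)
  for (f in c("tau", "injection_time_s", "discharge_time_s"))
    if (is.null(meta[[f]]))
      stop(sprintf("metadata field '%s' is missing", f))
  tau <- meta$tau
  if (any(tab$counts < 0)) {
    bad <- unique(tab$well_id[tab$counts < 0])[1L]
    stop(sprintf("negative counts in well '%s'", bad))
  }
  sp <- split(tab, tab$well_id)
  times <- lapply(sp, function(d) d$time_s)
  ref <- times[[1L]]
  for (wid in names(times))
    if (!isTRUE(all.equal(times[[wid]], ref)))
      stop(sprintf("well '%s' has a different time axis", wid))
  if (length(ref) > 1L && !isTRUE(all.equal(diff(ref),
                                            rep(tau, length(ref) - 1L))))
    stop(sprintf("time spacing %g s does not match metadata tau %g s",
                 stats::median(diff(ref)), tau))
  injection <- as.integer(round(meta$injection_time_s / tau))
  discharge <- as.integer(round(meta$discharge_time_s / tau))
  wells <- list(); empty <- list()
  for (wid in names(sp)) {
    wm <- meta$wells[[wid]]
    if (is.null(wm))
      stop(sprintf("well '%s' has no metadata entry", wid))
    trace <- lum_trace(sp[[wid]]$counts, tau = tau, injection = injection,
                       discharge = discharge)
    null2na <- function(x, cast = as.numeric)
      if (is.null(x)) cast(NA) else cast(x)
    w <- structure(list(
      trace = trace,
      replicate = null2na(wm$replicate, as.integer),
      seed = null2na(wm$seed, as.integer),
      is_empty = isTRUE(wm$is_empty), well_id = wid,
      preset_id = null2na(wm$preset_id, as.character),
      species = null2na(wm$species, as.character),
      tissue = null2na(wm$tissue, as.character),
      stimulus = null2na(wm$stimulus, as.character),
      dose = null2na(wm$dose),
      dose_units = null2na(wm$dose_units, as.character),
      la3plus = isTRUE(wm$la3plus),
      section_id = null2na(wm$section_id, as.character)),
      class = "well_record")
    if (w$is_empty) empty[[length(empty) + 1L]] <- w
    else wells[[length(wells) + 1L]] <- w
  }
  n <- length(ref)
  cfg <- sim_config(tau = tau, baseline_s = injection * tau,
                    post_s = (discharge - injection) * tau,
                    discharge_s = (n - discharge) * tau)
  structure(list(wells = wells, empty = empty, config = cfg,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed),
            class = "plate_dataset")
}

preset_fields <- c("id", "species", "tissue", "stimulus", "dose",
                   "dose_units", "baseline", "amplitude", "onset", "ttp",
                   "decay_half", "sustained", "osc_amp", "osc_period",
                   "osc_damp", "osc_count", "dose_threshold",
                   "dose_halfsat", "dose_decline", "inhibition",
                   "la3plus", "section_id")

#' Load a signature-preset library from JSON
#'
#' All preset invariants are enforced at load time and unknown keys are
#' rejected, so a library that loads is guaranteed valid.
#'
#' @param path JSON file with fields `library_version` and `presets`.
#' @return named list of [signature_preset()]s with attribute
#'   `library_version`.
#' @export
load_presets <- function(path) {
  if (!file.exists(path)) stop(sprintf("preset file '%s' not found", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$presets)) stop("preset file lacks a 'presets' array")
  out <- lapply(doc$presets, function(p) {
    unknown <- setdiff(names(p), preset_fields)
    if (length(unknown))
      stop(sprintf("preset '%s': unknown field(s): %s",
                   if (is.null(p$id)) "?" else p$id,
                   paste(unknown, collapse = ", ")))
    required <- c("id", "species", "tissue", "stimulus", "dose",
                  "amplitude", "ttp", "decay_half")
    missing <- setdiff(required, names(p))
    if (length(missing))
      stop(sprintf("preset '%s': missing field(s): %s",
                   if (is.null(p$id)) "?" else p$id,
                   paste(missing, collapse = ", ")))
    do.call(signature_preset, p)
  })
  names(out) <- vapply(out, function(p) p$id, character(1))
  if (anyDuplicated(names(out)))
    stop("duplicate preset ids in library")
  attr(out, "library_version") <-
    if (is.null(doc$library_version)) "unversioned" else doc$library_version
  out
}

#' Write a results table as TSV
#'
#' @param df data.frame (e.g. from [summarize_plate()], [dose_response()],
#'   [section_profile()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
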