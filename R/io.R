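#' Read a diffuse-reflectance profile from CSV
#'
#' Expects columns `rho_mm` and `R` (or `R_per_mm2`), with optional `R_se`
#' and `hits`. Rows are sorted by radius; a missing `R_se` column is filled
#' with zeros with a warning. Empty (masked) bins may be stored as zero
#' reflectance and survive a round trip.
#'
#' @param path CSV file path.
#' @return a `dr_profile` (with `n_photons = NA` unless a JSON sidecar
#'   written by [write_profile_csv()] sits next to the file).
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcol <- if ("R_per_mm2" %in% names(df)) "R_per_mm2" else "R"
  if (!all(c("rho_mm", rcol) %in% names(df))) {
    stop("CSV must have columns rho_mm and R (or R_per_mm2)")
  }
  df <- df[order(df$rho_mm), , drop = FALSE]
  if (anyDuplicated(df$rho_mm) || any(diff(df$rho_mm) <= 0)) {
    stop("rho_mm must be strictly increasing after sorting")
  }
  bad <- which(is.finite(df[[rcol]]) & df[[rcol]] < 0)
  if (length(bad)) {
    stop(sprintf("negative reflectance in row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (!"R_se" %in% names(df)) {
    warning("no R_se column; uncertainties set to zero")
    df$R_se <- 0
  }
  meta <- list()
  n_photons <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (!is.null(meta$n_photons)) n_photons <- meta$n_photons
  }
  structure(
    list(rho = df$rho_mm, R = df[[rcol]], R_se = df$R_se,
         hits = if ("hits" %in% names(df)) df$hits else rep(NA_real_, nrow(df)),
         n_photons = n_photons,
         audit = NULL,
         meta = meta),
    class = "dr_profile")
}

#' Write a diffuse-reflectance profile to CSV (plus JSON sidecar)
#'
#' Writes `rho_mm, R_per_mm2, R_se[, hits]` with full double precision, and
#' (optionally) a `<path>.json` sidecar recording photon count, seed, medium
#' and configuration for provenance.
#'
#' @param profile a `dr_profile`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar, default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, sidecar = TRUE) {
  stopifnot(inherits(profile, "dr_profile"))
  df <- data.frame(rho_mm = profile$rho,
                   R_per_mm2 = profile$R,
                   R_se = profile$R_se)
  if (!all(is.na(profile$hits))) df$hits <- profile$hits
  utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(n_photons = profile$n_photons)
    cfg <- profile$meta$config
    if (!is.null(cfg)) {
      meta$seed <- cfg$seed
      meta$weight_threshold <- cfg$weight_threshold
      meta$roulette_survival <- cfg$roulette_survival
    }
    med <- profile$meta$medium
    if (!is.null(med)) {
      meta$layers <- lapply(med$layers, function(l)
        list(mu_a = l$props$mu_a, mu_s = l$props$mu_s, g = l$props$g,
             n = l$props$n, thickness = l$thickness))
      meta$ambient_n <- med$ambient_n
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Write a study's artifacts to a directory
#'
#' Layout: `manifest.json`, `profiles/<label>.csv` (+ sidecars),
#' `cp/<label>.json`, `relation.json`. Numbers are written at full
#' precision.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cp_study"))
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cp"), showWarnings = FALSE)
  jsonlite::write_json(
    c(as.list(study$manifest),
      list(master_seed = study$settings$master_seed, m = study$settings$m)),
    file.path(dir, "manifest.json"), auto_unbox = FALSE, digits = NA)
  for (lab in names(study$profiles)) {
    write_profile_csv(study$profiles[[lab]],
                      file.path(dir, "profiles", paste0(lab, ".csv")))
  }
  for (lab in names(study$cp_results)) {
    r <- study$cp_results[[lab]]
    jsonlite::write_json(
      list(label = lab, cp = r$cp, found = r$found,
           slope_before = r$slope_before, slope_after = r$slope_after,
           monolayer_slope = r$monolayer_slope,
           alpha = r$cfg$alpha, window = r$cfg$window,
           persistence = r$cfg$persistence),
      file.path(dir, "cp", paste0(lab, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  rel <- study$relation
  if (!is.null(rel)) {
    jsonlite::write_json(
      list(slope = rel$slope, intercept = rel$intercept,
           r_squared = rel$r_squared, n_used = rel$n_used,
           points = rel$points),
      file.path(dir, "relation.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
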