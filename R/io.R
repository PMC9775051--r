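# Plain-text readers/writers and the end-to-end pipeline driver.
#
# Decays and IRFs travel as two-column ASCII (channel index, counts) with
# metadata in '#' header comments; spectra as two-column CSV (nm,
# intensity); nu(t) tables as TSV; run manifests as JSON; toy trajectories
# as (multi-frame) GRO text.

#' Write / read a TCSPC decay file
#'
#' Two-column ASCII (channel index, counts) with metadata header comments
#' `# channel_width_ns:` and `# wavelength_nm:`.
#'
#' @param decay a [decay_curve()]
#' @param path file path
#' @return `read_decay_file()` returns a validated [decay_curve()];
#'   malformed lines are reported with their line numbers
#' @export
write_decay_file <- function(decay, path) {
  stopifnot(inherits(decay, "decay_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# channel_width_ns: %.10g", decay$channel_width),
    sprintf("# wavelength_nm: %s",
            if (is.na(decay$wavelength)) "NA" else
              sprintf("%.10g", decay$wavelength))), con)
  utils::write.table(data.frame(channel = seq_along(decay$counts),
                                counts = decay$counts),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_file
#' @export
read_decay_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(\\S+)",
                                      lines[h]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$channel_width_ns))
    stop("missing metadata field 'channel_width_ns' in ", path)
  if (is.null(meta$wavelength_nm))
    stop("missing metadata field 'wavelength_nm' in ", path)
  body_idx <- setdiff(which(nzchar(trimws(lines))), hdr)
  if (length(body_idx) == 0L) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  bad <- which(lengths(parts) != 2L |
                 vapply(parts, function(p) anyNA(suppressWarnings(as.numeric(p))),
                        logical(1)))
  if (length(bad))
    stop("malformed line(s) in ", path, ": ",
         paste(body_idx[utils::head(bad, 5)], collapse = ", "))
  counts <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (any(counts < 0))
    stop("negative count at line ", body_idx[which(counts < 0)[1]], " in ", path)
  decay_curve(counts,
              channel_width = as.numeric(meta$channel_width_ns),
              wavelength = suppressWarnings(as.numeric(meta$wavelength_nm)))
}

#' Write / read a two-column spectrum CSV
#'
#' @param spectrum data.frame with `wavelength` (nm) and `intensity`
#' @param path file path
#' @return `read_spectrum_csv()` returns the validated data.frame
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(all(c("wavelength", "intensity") %in% names(spectrum)))
  utils::write.csv(spectrum[c("wavelength", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  sp <- utils::read.csv(path)
  names(sp)[1:2] <- c("wavelength", "intensity")
  if (is.unsorted(sp$wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing in ", path)
  if (any(sp$intensity < 0)) stop("negative intensity in ", path)
  sp
}

#' Write a synthetic dataset to a directory
#'
#' Lays a [generate_dataset()] result out as the pipeline expects to find
#' measured data: one decay file per wavelength, `irf.txt`, and
#' `steady_state.csv`.
#'
#' @param dataset a `"tdfs_dataset"`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tdfs_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in dataset$decays)
    write_decay_file(d, file.path(dir, sprintf("decay_%03.0f.txt",
                                               d$wavelength)))
  write_decay_file(dataset$irf, file.path(dir, "irf.txt"))
  write_spectrum_csv(dataset$steady_state, file.path(dir, "steady_state.csv"))
  invisible(dir)
}

#' Write / read a (multi-frame) GRO trajectory
#'
#' Plain-text GROMACS GRO format; internal coordinates are Å and are
#' converted to/from the nm of the format.  Multiple frames are
#' concatenated blocks.
#'
#' @param traj a [bilayer_trajectory()]
#' @param path file path
#' @return `read_gro()` returns a [bilayer_trajectory()] whose groups are
#'   recovered from the residue names
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  resname <- character(nrow(traj$frames[[1]]$xyz))
  for (g in names(traj$groups)) resname[traj$groups[[g]]] <- g
  con <- file(path, "w"); on.exit(close(con))
  for (f in traj$frames) {
    n <- nrow(f$xyz)
    writeLines(sprintf("toy bilayer, t= 0.0"), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(n) %% 100000L, substr(resname, 1, 5),
                       substr(resname, 1, 5), seq_len(n) %% 100000L,
                       f$xyz[, 1] / 10, f$xyz[, 2] / 10, f$xyz[, 3] / 10),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1] / 10, f$box[2] / 10,
                       f$box[3] / 10), con)
  }
  invisible(path)
}

#' @rdname write_gro
#' @param lipids_per_leaflet stored on the returned trajectory
#' @export
read_gro <- function(path, lipids_per_leaflet = NA_integer_) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; resnames <- NULL
  while (i < length(lines)) {
    n <- as.integer(trimws(lines[i + 1L]))
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    xyz <- cbind(as.numeric(substr(atom_lines, 21, 28)),
                 as.numeric(substr(atom_lines, 29, 36)),
                 as.numeric(substr(atom_lines, 37, 44))) * 10
    rn <- trimws(substr(atom_lines, 6, 10))
    if (is.null(resnames)) resnames <- rn
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3] * 10
    frames[[length(frames) + 1L]] <- list(xyz = xyz, box = box)
    i <- i + 3L + n
  }
  groups <- split(seq_along(resnames), resnames)
  bilayer_trajectory(frames, groups = groups,
                     lipids_per_leaflet = lipids_per_leaflet)
}

#' Run the full TDFS pipeline from files
#'
#' Reads every decay file in a directory plus the IRF and the steady-state
#' spectrum, runs [tdfs()] (fit, reconstruct, maxima, metrics) and writes
#' the \eqn{\nu(t)} table (TSV), the headline metrics and per-stage
#' diagnostics (JSON), and a machine-readable run manifest (input MD5
#' hashes, seed, settings, package version).  Rerunning an unchanged
#' configuration reproduces the outputs exactly.
#'
#' @param config named list, or path to a YAML/JSON file, with fields:
#'   `decay_dir`, `irf_file`, `steady_state_file`, `out_dir`, and optional
#'   `n_components` (default 3), `nu0` ("fit" or a number), `seed`
#'   (default 1), `time_grid_n` (default 100)
#' @return the fitted [tdfs()] object, invisibly; outputs on disk
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- c("decay_dir", "irf_file", "steady_state_file", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  for (p in c(config$decay_dir, config$irf_file, config$steady_state_file))
    if (!file.exists(p)) stop("[input] path does not exist: ", p)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  decay_files <- sort(list.files(config$decay_dir, pattern = "^decay_.*\\.txt$",
                                 full.names = TRUE))
  if (length(decay_files) == 0L)
    stop("[read] no decay_*.txt files in ", config$decay_dir)
  decays <- stage("read", lapply(decay_files, read_decay_file))
  irf <- stage("read", read_decay_file(config$irf_file))
  ss <- stage("read", read_spectrum_csv(config$steady_state_file))

  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  fit <- stage("fit", tdfs(decays, irf = irf, steady_state = ss,
                           n_components = as.integer(config$n_components %||% 3L),
                           nu0 = config$nu0 %||% "fit"))

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(time_ns = fit$response$time, nu_cm1 = fit$response$nu,
               nu_se_cm1 = fit$response$nu_se, argmax_cm1 = fit$response$argmax,
               flagged = fit$response$flagged),
    file.path(out, "nu_t.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

  metrics <- list(
    nu0_cm1 = unname(coef(fit)["nu0"]),
    nu_inf_cm1 = unname(coef(fit)["nu_inf"]),
    delta_nu_cm1 = unname(coef(fit)["delta_nu"]),
    delta_nu_observed_cm1 = fit$delta_nu_observed,
    tau_r_ns = unname(coef(fit)["tau_r"]),
    tau_r_numeric_ns = fit$tau_r_numeric,
    incomplete_relaxation = fit$incomplete,
    nu_components = fit$components,
    decay_fits = data.frame(
      wavelength_nm = vapply(fit$decay_fits, `[[`, numeric(1), "wavelength"),
      chi2_reduced = vapply(fit$decay_fits, `[[`, numeric(1), "chi2_reduced"),
      converged = vapply(fit$decay_fits, `[[`, logical(1), "converged")))
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "tdfs",
    version = as.character(utils::packageVersion("tdfs")),
    seed = seed,
    settings = config[setdiff(names(config), need)],
    inputs = as.list(tools::md5sum(c(decay_files, config$irf_file,
                                     config$steady_state_file))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}
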