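read_hash_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      out[[m[2]]] <- if (is.na(v)) trimws(m[3]) else v
    }
  }
  out
}

#' Write / read a titration experiment as CSV
#'
#' Columns `injection_index`, `volume_ul`, `heat_ucal`; run-level fields
#' (concentrations in mM, cell volume in ul, temperature in K) are kept
#' in `# key: value` header lines so one file round-trips the experiment.
#'
#' @param exp An [itc_experiment()].
#' @param path File path.
#' @return `write_titration_csv` returns `path` invisibly;
#'   `read_titration_csv` returns an [itc_experiment()].
#' @export
write_titration_csv <- function(exp, path) {
  stopifnot(inherits(exp, "itc_experiment"))
  hdr <- c(
    sprintf("# cell_conc_mM: %.10g", exp$cell_conc),
    sprintf("# syringe_conc_mM: %.10g", exp$syringe_conc),
    sprintf("# cell_volume_ul: %.10g", exp$cell_volume),
    sprintf("# temperature_K: %.10g", exp$temperature),
    "injection_index,volume_ul,heat_ucal"
  )
  body <- sprintf("%d,%.10g,%.10g", seq_len(nrow(exp$injections)),
                  exp$injections$volume_ul, exp$injections$heat_ucal)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  meta <- read_hash_header(path)
  need <- c("cell_conc_mM", "syringe_conc_mM", "cell_volume_ul", "temperature_K")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste("titration CSV lacks header fields:",
                                paste(miss, collapse = ", ")))
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  itc_experiment(
    tibble(volume_ul = tab$volume_ul, heat_ucal = tab$heat_ucal),
    cell_conc = meta$cell_conc_mM, syringe_conc = meta$syringe_conc_mM,
    cell_volume = meta$cell_volume_ul, temperature = meta$temperature_K,
    metadata = list(source = path)
  )
}

#' Write / read one umbrella window as CSV
#'
#' Header lines carry the restraint (`center_A`, `spring_kJ_mol_nm2`);
#' the body is one reaction-coordinate sample (Angstrom) per line under a
#' `sample_A` column.
#'
#' @param window An [umbrella_window()].
#' @param path File path.
#' @return `path` invisibly / an [umbrella_window()].
#' @export
write_window_csv <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  writeLines(c(sprintf("# center_A: %.10g", window$center),
               sprintf("# spring_kJ_mol_nm2: %.10g", window$spring_k),
               "sample_A",
               sprintf("%.10g", window$samples)), path)
  invisible(path)
}

#' @rdname write_window_csv
#' @export
read_window_csv <- function(path) {
  meta <- read_hash_header(path)
  if (is.null(meta$center_A) || is.null(meta$spring_kJ_mol_nm2)) {
    abort(sprintf("window CSV %s lacks center_A / spring_kJ_mol_nm2 header", path))
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  umbrella_window(meta$center_A, meta$spring_kJ_mol_nm2, tab$sample_A)
}

#' Write / read a set of umbrella windows via a manifest
#'
#' `write_window_set` writes one CSV per window plus a tab-separated
#' manifest (`path`, `center_A`, `spring_kJ_mol_nm2`);
#' `read_window_manifest` loads the windows back (paths resolved
#' relative to the manifest).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param dir Output directory (created if missing).
#' @param manifest Manifest file path.
#' @return The manifest path, invisibly / a list of windows.
#' @export
write_window_set <- function(windows, dir,
                             manifest = file.path(dir, "windows.tsv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(seq_along(windows), function(i) {
    fn <- sprintf("window_%03d.csv", i)
    write_window_csv(windows[[i]], file.path(dir, fn))
    sprintf("%s\t%.10g\t%.10g", fn, windows[[i]]$center, windows[[i]]$spring_k)
  }, character(1))
  writeLines(c("path\tcenter_A\tspring_kJ_mol_nm2", rows), manifest)
  invisible(manifest)
}

#' @rdname write_window_set
#' @export
read_window_manifest <- function(manifest) {
  tab <- readr::read_tsv(manifest, show_col_types = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    w <- read_window_csv(file.path(dirname(manifest), tab$path[i]))
    if (abs(w$center - tab$center_A[i]) > 1e-6 ||
        abs(w$spring_k - tab$spring_kJ_mol_nm2[i]) > 1e-6) {
      abort(sprintf("manifest row %d disagrees with window file header", i))
    }
    w
  })
}

#' Write a PMF profile as CSV
#'
#' Columns `bin_center_A`, `pmf_kJ_mol` and, when present,
#' `stderr_kJ_mol`; unpopulated bins are written as `NA`.
#'
#' @param pmf A `pmf_profile`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  cols <- intersect(c("bin_center_A", "pmf_kJ_mol", "stderr_kJ_mol"), names(pmf))
  hdr <- sprintf("# kT_kJ_mol: %.10g", pmf_kT(pmf))
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.10g", v), "NA")
  body <- do.call(paste, c(lapply(cols, function(cn) fmt(pmf[[cn]])), sep = ","))
  writeLines(c(hdr, paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Write an ITC fit (or any tidy-able result) as JSON
#'
#' @param fit An `itc_fit` object.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "itc_fit"))
  obj <- list(
    kd_uM = fit$kd, kd_se_uM = fit$kd_se,
    n_sites = fit$n_sites, n_se = fit$n_se,
    dH_kcal_mol = fit$dH, dH_se_kcal_mol = fit$dH_se,
    dG_kcal_mol = fit$dG, minus_TdS_kcal_mol = fit$minus_TdS,
    no_binding = fit$no_binding, residual_norm_ucal = fit$residual_norm,
    temperature_K = fit$temperature
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
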