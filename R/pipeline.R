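#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects every knob of [run_pipeline()]: the output directory, the
#' master seed (all stage seeds derive from it), the temperature, the
#' generator settings and the analysis settings. Defaults are sized so
#' the whole pipeline runs in well under a minute while exercising every
#' stage.
#'
#' @param output_dir Directory for artifacts (created if missing).
#' @param seed Master integer seed.
#' @param temperature Kelvin (default 300; the ITC stage uses its own
#'   293.15 K protocol temperature).
#' @param itc Named list: `kd` (uM), `n_sites`, `dH` (kcal/mol),
#'   `noise_sd` (ucal).
#' @param competition Named list: `a0` (1/uM), `dE` (kJ/mol), `noise_sd`.
#' @param umbrella Named list: `barrier_a`, `barrier_b` (kJ/mol, planted
#'   dissociation barriers of the two profiles), `n_per_window`,
#'   `n_bins`, `n_boot`, `plateau_range` (c(min, max) Angstrom).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1, temperature = 300,
                            itc = list(kd = 10, n_sites = 1, dH = -5,
                                       noise_sd = 0.2),
                            competition = list(a0 = 0.0006, dE = 9.4,
                                               noise_sd = 0.02),
                            umbrella = list(barrier_a = 10, barrier_b = 19.4,
                                            n_per_window = 1000, n_bins = 200,
                                            n_boot = 20,
                                            plateau_range = c(30, 37))) {
  stopifnot(is.character(output_dir), length(output_dir) == 1)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 temperature = temperature, itc = itc,
                 competition = competition, umbrella = umbrella),
            class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> fit/solve -> predict/report over all four
#' analysis stages, writing every artifact plus a reproducibility
#' manifest to `config$output_dir`:
#' \enumerate{
#'   \item titration: generate a noisy single-site titration, write it as
#'     CSV, fit it, write `itc_fit.json`;
#'   \item umbrella sampling: generate biased samples from two planted
#'     dissociation profiles (differing by `barrier_b - barrier_a`),
#'     solve WHAM with bootstrap errors, write both PMF CSVs and
#'     `barriers.json`;
#'   \item competition: generate a noisy displacement series with the
#'     unmodified competitor, fit a0, combine it with the measured
#'     barrier difference, write the predicted y1/y2 displacement table;
#'   \item interface: build the toy complex, write its PDB and the
#'     plain-text interface report.
#' }
#' Every stage failure is rethrown with the stage name attached; a rerun
#' with the same config is byte-identical (no timestamps are written).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths plus the key fitted
#'   quantities.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  paths <- list()

  # -- stage 1: titration -------------------------------------------------
  fit <- stage("itc", {
    e <- gen_itc_titration(
      kd = config$itc$kd, n_sites = config$itc$n_sites, dH = config$itc$dH,
      cfg = generator_config(seed = derive_seed(config$seed, 1),
                             noise_sd = config$itc$noise_sd))
    paths$titration_csv <- file.path(out, "titration.csv")
    write_titration_csv(e, paths$titration_csv)
    f <- fit_single_site(e)
    paths$itc_fit_json <- file.path(out, "itc_fit.json")
    write_fit_json(f, paths$itc_fit_json)
    f
  })

  # -- stage 2: umbrella sampling / WHAM ---------------------------------
  kT <- kT_kJ(config$temperature)
  um <- config$umbrella
  wham_res <- stage("wham", {
    centers <- build_window_schedule(claw_window_segments())
    res <- list()
    for (side in c("a", "b")) {
      depth <- if (side == "a") um$barrier_a else um$barrier_b
      spec <- pmf_dissociation_spec(depth = depth)
      wins <- gen_umbrella_samples(
        spec, centers, n_per_window = um$n_per_window, kT = kT,
        cfg = generator_config(seed = derive_seed(config$seed,
                                                  2 + (side == "b"))))
      boot <- bootstrap_pmf(wins, kT, plateau_range = um$plateau_range,
                            n_boot = um$n_boot, n_bins = um$n_bins,
                            range = c(spec$grid_min, spec$grid_max),
                            seed = derive_seed(config$seed, 4 + (side == "b")))
      pcsv <- file.path(out, sprintf("pmf_%s.csv", side))
      write_pmf_csv(boot$pmf, pcsv)
      paths[[sprintf("pmf_%s_csv", side)]] <- pcsv
      res[[side]] <- boot
    }
    delta <- delta_barrier(res$a$pmf, res$b$pmf, um$plateau_range,
                           error = sqrt(res$a$barrier$error^2 +
                                          res$b$barrier$error^2))
    paths$barriers_json <- file.path(out, "barriers.json")
    jsonlite::write_json(list(
      barrier_a_kJ_mol = res$a$barrier$barrier,
      barrier_a_err = res$a$barrier$error,
      barrier_b_kJ_mol = res$b$barrier$barrier,
      barrier_b_err = res$b$barrier$error,
      delta_kJ_mol = delta$delta, delta_err = delta$error,
      convention = delta$convention, kT_kJ_mol = kT
    ), paths$barriers_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(res = res, delta = delta)
  })

  # -- stage 3: competition ----------------------------------------------
  comp <- stage("competition", {
    series <- gen_competition_series(
      a0 = config$competition$a0, dE = 0, temperature = config$temperature,
      cfg = generator_config(seed = derive_seed(config$seed, 6),
                             noise_sd = config$competition$noise_sd))
    a0_hat <- fit_a0(series)
    params <- competition_params(a0_hat$a0, dE = wham_res$delta$delta,
                                 temperature = config$temperature)
    grid <- 10^seq(0, 4, length.out = 81)
    pred <- predict_displacement_curve(params, grid)
    paths$competition_csv <- file.path(out, "competition.csv")
    writeLines(c(
      sprintf("# a0_fit_1_per_uM: %.10g", a0_hat$a0),
      sprintf("# dE_kJ_mol: %.10g", wham_res$delta$delta),
      sprintf("# temperature_K: %.10g", config$temperature),
      sprintf("# sign_convention: %s", params$sign_convention),
      "conc_uM,y1,y2",
      sprintf("%.10g,%.10g,%.10g", pred$conc, pred$y1, pred$y2)),
      paths$competition_csv)
    list(a0 = a0_hat, prediction = pred)
  })

  # -- stage 4: interface -------------------------------------------------
  iface <- stage("interface", {
    toy <- gen_toy_complex(generator_config(seed = derive_seed(config$seed, 7)))
    paths$complex_pdb <- file.path(out, "toy_complex.pdb")
    write_pdb(toy, paths$complex_pdb)
    rep <- interface_report(toy, "chain A", "chain C")
    paths$interface_txt <- file.path(out, "interface.txt")
    writeLines(unclass(rep), paths$interface_txt)
    rep
  })

  # -- manifest -----------------------------------------------------------
  paths$manifest_json <- file.path(out, "manifest.json")
  jsonlite::write_json(list(
    package = "clawbind",
    version = as.character(packageVersion("clawbind")),
    seed = config$seed, temperature_K = config$temperature,
    config = list(itc = config$itc, competition = config$competition,
                  umbrella = config$umbrella),
    artifacts = lapply(paths[names(paths) != "manifest_json"], basename)
  ), paths$manifest_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(paths = paths, itc_fit = fit,
                 barriers = wham_res, competition = comp,
                 interface = iface))
}
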