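#' Configuration shared by all synthetic-data generators
#'
#' @param seed Integer seed; identical configurations yield bit-identical
#'   output and the caller's RNG stream is left untouched.
#' @param noise_sd Nonnegative noise standard deviation, in the units of
#'   the generated observable (ucal for titration heats, fraction units
#'   for competition data).
#' @param replicate_count Positive number of replicates, for generators
#'   that produce several.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1, noise_sd = 0, replicate_count = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(noise_sd), noise_sd >= 0,
            replicate_count >= 1)
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 replicate_count = as.integer(replicate_count)),
            class = "generator_config")
}

#' Generate a synthetic single-site titration
#'
#' Produces an [itc_experiment()] whose heats follow the forward
#' single-site model of [isotherm_heats()] with Gaussian noise of
#' standard deviation `cfg$noise_sd` (ucal) added per injection. The
#' generating parameters are recorded in the experiment's metadata as
#' ground truth, so recovery tests need no side channel.
#'
#' @inheritParams isotherm_heats
#' @param kd Ground-truth dissociation constant, uM.
#' @param n_sites Ground-truth stoichiometry.
#' @param dH Ground-truth enthalpy, kcal/mol.
#' @param cell_conc,syringe_conc Concentrations, mM.
#' @param schedule Injection volumes, ul (default the 1 + 19 x 2 ul
#'   protocol of [default_injection_schedule()]).
#' @param cell_volume Cell volume, ul.
#' @param temperature Kelvin.
#' @param cfg A [generator_config()].
#' @return An [itc_experiment()] with `metadata$truth`.
#' @examples
#' e <- gen_itc_titration(kd = 10, n_sites = 1, dH = -5,
#'                        cfg = generator_config(seed = 1, noise_sd = 0.2))
#' fit_single_site(e)
#' @export
gen_itc_titration <- function(kd, n_sites = 1, dH = -5, cell_conc = 0.25,
                              syringe_conc = 4,
                              schedule = default_injection_schedule(),
                              cell_volume = 200, temperature = 293.15,
                              cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (kd <= 0 || n_sites <= 0) abort("non-physical parameters: kd and n_sites must be > 0")
  if (cell_conc <= 0 || syringe_conc <= 0) abort("concentrations must be > 0")
  if (length(schedule) == 0) abort("injection schedule must be non-empty")
  exp0 <- itc_experiment(
    tibble(volume_ul = as.numeric(schedule), heat_ucal = 0),
    cell_conc = cell_conc, syringe_conc = syringe_conc,
    cell_volume = cell_volume, temperature = temperature
  )
  clean <- isotherm_heats(kd, n_sites, dH, exp0)
  noisy <- with_seed(cfg$seed, clean + rnorm(length(clean), 0, cfg$noise_sd))
  exp0$injections$heat_ucal <- noisy
  exp0$metadata <- list(
    truth = list(kd = kd, n_sites = n_sites, dH = dH),
    noise_sd = cfg$noise_sd, seed = cfg$seed, generator = "gen_itc_titration"
  )
  exp0
}

#' Generate biased reaction-coordinate samples for umbrella windows
#'
#' For each restraint center the biased density
#' `p(x) proportional to exp(-(U(x) + k/2 ((x - c)/10)^2) / kT)` is formed
#' on the `pmf_spec` grid (bias evaluated at bin centers, the spring
#' constant converted from kJ/mol/nm^2 to Angstrom via the factor 10 A/nm)
#' and sampled by grid-based inverse-CDF: a bin is drawn with the density's
#' weight and the sample placed uniformly within the bin. This matches the
#' binned likelihood WHAM uses, is deterministic given the seed, and is
#' adequate for a 1-D coordinate.
#'
#' @param pmf A [pmf_spec()] ground truth.
#' @param centers Window centers, Angstrom, all inside the spec grid
#'   (e.g. from [build_window_schedule()]).
#' @param spring_k Spring constant, kJ/mol/nm^2 (default 10000).
#' @param n_per_window Samples per window.
#' @param kT Thermal energy, kJ/mol (default 300 K).
#' @param cfg A [generator_config()] (only the seed is used; the samples
#'   are exact draws from the biased density, not further perturbed).
#' @return List of [umbrella_window()] objects; the ground-truth spec and
#'   generation settings are attached as attribute `"truth"`.
#' @export
gen_umbrella_samples <- function(pmf, centers, spring_k = 10000,
                                 n_per_window = 5000, kT = kT_kJ(300),
                                 cfg = generator_config()) {
  stopifnot(inherits(pmf, "pmf_spec"), inherits(cfg, "generator_config"),
            spring_k > 0, kT > 0)
  centers <- as.numeric(centers)
  if (length(centers) == 0) abort("centers must be non-empty")
  if (n_per_window < 1) abort("n_per_window must be >= 1")
  if (any(centers < pmf$grid_min | centers > pmf$grid_max)) {
    abort("all window centers must lie within the pmf_spec grid")
  }
  x <- pmf$bin_centers
  w <- pmf$bin_width
  windows <- with_seed(cfg$seed, {
    lapply(centers, function(cc) {
      logp <- -(pmf$values + bias_kJ(x, cc, spring_k)) / kT
      p <- exp(logp - max(logp))
      p <- p / sum(p)
      bins <- sample.int(pmf$n_bins, n_per_window, replace = TRUE, prob = p)
      samples <- pmf$grid_min + (bins - 1) * w + runif(n_per_window) * w
      umbrella_window(cc, spring_k, samples)
    })
  })
  attr(windows, "truth") <- list(pmf = pmf, spring_k = spring_k,
                                 n_per_window = n_per_window, kT = kT,
                                 seed = cfg$seed)
  windows
}

#' Generate a synthetic competition (displacement) series
#'
#' Fractions of the remaining reporter complex at each competitor
#' concentration, from [y_unmodified()] when `dE` is zero and
#' [y_phospho()] otherwise, plus truncated Gaussian noise kept within
#' (0, 1] (fractions are physical proportions, so draws outside the
#' interval are redrawn).
#'
#' @param a0 Ground-truth competition constant, 1/uM.
#' @param dE Barrier difference, kJ/mol (0 = unmodified competitor).
#' @param temperature Kelvin (default 300).
#' @param sign_convention Passed to [competition_params()].
#' @param concentrations Competitor concentrations, uM, each >= 0.
#' @param cfg A [generator_config()]; `noise_sd` is in fraction units.
#' @return Tibble with columns `conc`, `fraction`, `fraction_true`;
#'   ground truth attached as attribute `"truth"`.
#' @export
gen_competition_series <- function(a0, dE = 0, temperature = 300,
                                   sign_convention = "enhancing",
                                   concentrations = c(0, 10, 30, 100, 300,
                                                      1000, 3000, 10000),
                                   cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (any(concentrations < 0)) abort("negative concentration")
  params <- competition_params(a0, dE, temperature, sign_convention)
  y <- if (dE == 0) y_unmodified(a0, concentrations)
       else y_phospho(params, concentrations)
  fraction <- if (cfg$noise_sd == 0) y else with_seed(cfg$seed, {
    vapply(y, function(yi) {
      for (i in 1:1000) {
        v <- yi + rnorm(1, 0, cfg$noise_sd)
        if (v > 0 && v <= 1) return(v)
      }
      min(max(v, .Machine$double.eps), 1)   # pathological sd: clamp
    }, numeric(1))
  })
  out <- tibble(conc = as.numeric(concentrations), fraction = fraction,
                fraction_true = y)
  attr(out, "truth") <- list(a0 = a0, dE = dE, temperature = temperature,
                             sign_convention = sign_convention,
                             noise_sd = cfg$noise_sd, seed = cfg$seed)
  out
}
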