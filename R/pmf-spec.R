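#' Specify a ground-truth free-energy profile on a grid
#'
#' A `pmf_spec` is a known 1-D potential of mean force used as ground
#' truth by the umbrella-sampling generator and the round-trip tests:
#' free-energy values (kJ/mol) on a uniform grid of reaction-coordinate
#' bins (Angstrom), with the value attached to each bin center.
#'
#' @param grid_min,grid_max Reaction-coordinate range, Angstrom;
#'   `grid_min < grid_max`.
#' @param values Free energy per bin (kJ/mol), finite; length >= 2 sets
#'   the number of bins.
#' @return An object of class `pmf_spec` with fields `grid_min`,
#'   `grid_max`, `n_bins`, `values`, `bin_centers`, `bin_width`.
#' @export
pmf_spec <- function(grid_min, grid_max, values) {
  stopifnot(is.numeric(grid_min), is.numeric(grid_max), grid_min < grid_max)
  values <- as.numeric(values)
  if (length(values) < 2) abort("a pmf_spec needs at least 2 bins")
  if (any(!is.finite(values))) abort("pmf_spec values must be finite")
  n_bins <- length(values)
  width <- (grid_max - grid_min) / n_bins
  centers <- grid_min + width * (seq_len(n_bins) - 0.5)
  structure(
    list(grid_min = grid_min, grid_max = grid_max, n_bins = n_bins,
         values = values, bin_centers = centers, bin_width = width),
    class = "pmf_spec"
  )
}

#' @export
print.pmf_spec <- function(x, ...) {
  cat(sprintf("PMF spec: %d bins over [%.2f, %.2f] A, range %.2f-%.2f kJ/mol\n",
              x$n_bins, x$grid_min, x$grid_max, min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname pmf_spec
#' @param f Function of the reaction coordinate (Angstrom) returning
#'   kJ/mol; evaluated at bin centers.
#' @param n_bins Number of grid bins.
#' @export
pmf_spec_fn <- function(f, grid_min, grid_max, n_bins = 200) {
  width <- (grid_max - grid_min) / n_bins
  centers <- grid_min + width * (seq_len(n_bins) - 0.5)
  pmf_spec(grid_min, grid_max, f(centers))
}

#' Canonical dissociation free-energy profile
#'
#' A binding-funnel ground truth emulating a peptide dissociation PMF: a
#' single bound-state well of depth `depth` below an unbound plateau,
#' with a harmonic inner wall at short distances. The well minimum sits at
#' `x0`; beyond about `x0 + 3*width` the profile is flat at `depth`, so
#' the dissociation barrier (plateau minus minimum) equals `depth`
#' exactly.
#'
#' @param depth Barrier height: plateau minus minimum, kJ/mol
#'   (default 9.4, a typical phosphorylation-induced barrier shift).
#' @param x0 Location of the bound-state minimum, Angstrom (default 17).
#' @param width Gaussian half-width of the well, Angstrom (default 2.5).
#' @param wall_k Inner-wall stiffness, kJ/mol/A^2 (default 2).
#' @param grid_min,grid_max,n_bins Grid layout (defaults 15-38 A, 200
#'   bins, matching the canonical window schedule).
#' @return A [pmf_spec()].
#' @export
pmf_dissociation_spec <- function(depth = 9.4, x0 = 17, width = 2.5,
                                  wall_k = 2, grid_min = 15, grid_max = 38,
                                  n_bins = 200) {
  stopifnot(depth >= 0, width > 0, wall_k >= 0)
  f <- function(x) {
    ifelse(x >= x0,
           depth * (1 - exp(-(x - x0)^2 / (2 * width^2))),
           wall_k * (x - x0)^2)
  }
  spec <- pmf_spec_fn(f, grid_min, grid_max, n_bins)
  spec$truth <- list(depth = depth, x0 = x0, width = width, wall_k = wall_k)
  spec
}

#' Flat free-energy profile
#'
#' All-zero ground truth: under a harmonic restraint the biased density is
#' the pure Gaussian of the bias, the degenerate reference case for the
#' generator and WHAM.
#'
#' @inheritParams pmf_dissociation_spec
#' @return A [pmf_spec()].
#' @export
pmf_flat_spec <- function(grid_min = 15, grid_max = 38, n_bins = 200) {
  pmf_spec(grid_min, grid_max, rep(0, n_bins))
}

# Ground-truth PMF evaluated as a pmf_profile-compatible tibble aligned
# min-zero, for direct comparison with a WHAM solution on the same grid.
#' Convert a `pmf_spec` to a `pmf_profile` table
#'
#' @param spec A [pmf_spec()].
#' @param kT Thermal energy to record, kJ/mol.
#' @return A `pmf_profile` tibble aligned min-zero.
#' @export
as_pmf_profile <- function(spec, kT = kT_kJ(300)) {
  stopifnot(inherits(spec, "pmf_spec"))
  new_pmf_profile(spec$bin_centers, spec$values - min(spec$values), kT)
}
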