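#' Build an umbrella-window schedule from spacing segments
#'
#' Generates restraint centers along the reaction coordinate from a list
#' of (start, stop, spacing) segments. Centers are laid on the half-open
#' interval `[start, stop)` of each segment: a boundary shared by two
#' touching segments is owned by the segment that starts there, and the
#' final global stop is excluded. This is the convention under which the
#' canonical dissociation schedule - 0.5 A spacing from 15 to 25 A and
#' 1.0 A from 25 to 38 A - yields exactly 33 windows (inclusive endpoints
#' would give 34).
#'
#' @param segments A data frame with columns `start`, `stop`, `spacing`
#'   (all in Angstrom), or a list of numeric triples.
#' @return Strictly increasing numeric vector of window centers (Angstrom),
#'   with the segment table and the endpoint convention attached as
#'   attributes `"segments"` and `"convention"`.
#' @examples
#' s <- claw_window_segments()       # the canonical dissociation schedule
#' length(build_window_schedule(s))  # 33
#' @export
build_window_schedule <- function(segments) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, lapply(segments, function(s) {
      tibble(start = s[[1]], stop = s[[2]], spacing = s[[3]])
    }))
  }
  segments <- as_tibble(segments)
  stopifnot(all(c("start", "stop", "spacing") %in% names(segments)))
  if (any(segments$spacing <= 0)) abort("spacing must be > 0")
  if (any(segments$start >= segments$stop)) abort("each segment needs start < stop")
  o <- order(segments$start)
  segments <- segments[o, ]
  if (nrow(segments) > 1) {
    overlap <- segments$stop[-nrow(segments)] > segments$start[-1]
    if (any(overlap)) abort("segments overlap; they must be contiguous or disjoint")
  }
  centers <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    n <- ceiling((seg$stop - seg$start) / seg$spacing - 1e-9)
    seg$start + seg$spacing * (seq_len(n) - 1)
  }))
  stopifnot(all(diff(centers) > 0))
  structure(centers, segments = segments, convention = "half-open [start, stop)")
}

#' Canonical dissociation-coordinate segments
#'
#' The window layout used for claw-domain/peptide dissociation: 0.5 A
#' spacing over 15-25 A of center-of-mass distance, then 1.0 A over
#' 25-38 A.
#'
#' @return Tibble of segments suitable for [build_window_schedule()].
#' @export
claw_window_segments <- function() {
  tibble(start = c(15, 25), stop = c(25, 38), spacing = c(0.5, 1.0))
}

#' Summarise a window schedule
#'
#' Per-window table plus total simulation-time bookkeeping.
#'
#' @param centers Window centers from [build_window_schedule()].
#' @param time_per_window_ns Sampling time allotted to each window, ns.
#' @param spring_k Spring constant recorded for each window,
#'   kJ mol^-1 nm^-2 (default 10000).
#' @return Tibble with one row per window (`center_A`,
#'   `spring_kJ_mol_nm2`, `time_ns`); `n_windows` and `total_time_ns` are
#'   attached as attributes and shown by [glance()].
#' @export
schedule_manifest <- function(centers, time_per_window_ns = 100,
                              spring_k = 10000) {
  stopifnot(length(centers) >= 1, time_per_window_ns > 0, spring_k > 0)
  out <- tibble(center_A = as.numeric(centers),
                spring_kJ_mol_nm2 = spring_k,
                time_ns = time_per_window_ns)
  attr(out, "n_windows") <- length(centers)
  attr(out, "total_time_ns") <- length(centers) * time_per_window_ns
  class(out) <- c("schedule_manifest", class(out))
  out
}

#' @rdname schedule_manifest
#' @param x A `schedule_manifest`.
#' @param ... Unused.
#' @export
glance.schedule_manifest <- function(x, ...) {
  tibble(n_windows = attr(x, "n_windows"),
         total_time_ns = attr(x, "total_time_ns"),
         spring_kJ_mol_nm2 = x$spring_kJ_mol_nm2[1])
}

#' Construct an umbrella window
#'
#' One biased-sampling window: the harmonic restraint center (Angstrom),
#' the spring constant (kJ mol^-1 nm^-2), and the scalar
#' reaction-coordinate samples collected under that bias (Angstrom).
#'
#' @param center Restraint center, Angstrom.
#' @param spring_k Spring constant, kJ mol^-1 nm^-2; > 0.
#' @param samples Numeric vector of reaction-coordinate samples, Angstrom.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, samples) {
  stopifnot(is.numeric(center), length(center) == 1, spring_k > 0)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) abort("samples must be finite")
  structure(list(center = center, spring_k = spring_k, samples = samples),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window: center %.3f A, k = %g kJ/mol/nm^2, %d samples\n",
              x$center, x$spring_k, length(x$samples)))
  invisible(x)
}

new_pmf_profile <- function(bin_centers, free_energy, kT,
                            counts = NULL, stderr = NULL,
                            alignment = "min_zero", extra = list()) {
  out <- tibble(bin_center_A = bin_centers, pmf_kJ_mol = free_energy)
  if (!is.null(stderr)) out$stderr_kJ_mol <- stderr
  if (!is.null(counts)) out$counts <- counts
  attr(out, "kT") <- kT
  attr(out, "alignment") <- alignment
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("pmf_profile", class(out))
  out
}

pmf_kT <- function(pmf) attr(pmf, "kT")

populated <- function(pmf) is.finite(pmf$pmf_kJ_mol)

#' Solve 1-D WHAM for a set of umbrella windows
#'
#' The weighted histogram analysis method combines the biased histograms
#' of all windows into one unbiased free-energy profile. With per-bin
#' counts \eqn{n_i(x)}, window sizes \eqn{N_i} and bias \eqn{b_i(x)}
#' evaluated at bin centers, it iterates
#' \deqn{\rho(x) = \frac{\sum_i n_i(x)}{\sum_i N_i e^{(F_i - b_i(x))/kT}},
#'       \qquad
#'       F_i = -kT \ln \sum_x \rho(x) e^{-b_i(x)/kT}}
#' until the largest change in any window free energy falls below `tol`
#' (in units of kT). The gauge is fixed by pinning the first window's
#' F to zero every iteration. The PMF is `-kT log(rho)`, aligned so its
#' minimum over populated bins is zero; bins with zero total counts are
#' reported as NA, never interpolated silently.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param kT Thermal energy, kJ/mol (see [kT_kJ()]).
#' @param n_bins Number of histogram bins (default 200).
#' @param range Optional c(min, max) binning range in Angstrom; defaults
#'   to the sampled range.
#' @param tol Convergence tolerance on max |dF| in kT units (default 1e-7).
#' @param max_iter Iteration cap (default 1e5).
#' @param f_init Optional warm-start window free energies (kJ/mol).
#' @return A `pmf_profile` tibble: `bin_center_A`, `pmf_kJ_mol`, `counts`,
#'   with `kT`, window free energies, iteration count and convergence
#'   status in attributes. Non-convergence raises an error carrying the
#'   last residual; a gap in window coverage (empty bins splitting the
#'   populated range into disconnected blocks) raises a diagnostic naming
#'   the gap.
#' @export
wham_solve <- function(windows, kT, n_bins = 200, range = NULL,
                       tol = 1e-7, max_iter = 1e5, f_init = NULL) {
  stopifnot(length(windows) >= 1, kT > 0, n_bins >= 2)
  for (w in windows) stopifnot(inherits(w, "umbrella_window"))
  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  if (length(all_samples) == 0) abort("no samples in any window")
  if (is.null(range)) range <- base::range(all_samples)
  if (any(all_samples < range[1] | all_samples > range[2])) {
    abort("samples outside the binning range")
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  W <- length(windows)
  counts <- vapply(windows, function(w) {
    idx <- pmin(pmax(findInterval(w$samples, edges, rightmost.closed = TRUE), 1), n_bins)
    tabulate(idx, nbins = n_bins)
  }, numeric(n_bins))                      # n_bins x W
  n_tot <- rowSums(counts)
  N_i <- colSums(counts)

  # coverage connectivity diagnostic
  pop <- n_tot > 0
  if (any(pop)) {
    r <- base::range(which(pop))
    gap <- which(!pop[r[1]:r[2]])
    if (length(gap) > 0) {
      runs <- rle(!pop[r[1]:r[2]])
      gap_len <- max(runs$lengths[runs$values])
      if (gap_len * diff(edges)[1] > 2 * max(vapply(windows, function(w)
            sqrt(kT / w$spring_k) * claw_constants$A_per_nm, 1))) {
        g0 <- centers[r[1] - 1 + which(!pop[r[1]:r[2]])[1]]
        abort(sprintf(
          "window coverage is disconnected: empty gap near %.2f A; add windows or samples", g0))
      }
    }
  }

  B <- vapply(windows, function(w) bias_kJ(centers, w$center, w$spring_k),
              numeric(n_bins))             # n_bins x W, kJ/mol
  expB <- exp(-B / kT)

  if (any(N_i == 0)) abort("every window must contain at least one sample")
  # Maximise the WHAM log-likelihood over the reduced window free energies
  # g_i = F_i/kT (gauge g_1 = 0): L(g) = sum_i N_i g_i - sum_x M_x log
  # sum_i N_i exp(g_i) c_ix with c_ix = exp(-b_i(x)/kT). L is concave, so a
  # damped Newton iteration converges fast even with stiff, barely
  # overlapping windows where the classic fixed-point update crawls.
  g <- if (is.null(f_init)) numeric(W) else as.numeric(f_init) / kT
  stopifnot(length(g) == W)
  g <- g - g[1]
  loglik <- function(g) {
    denom <- as.vector(expB %*% (N_i * exp(g)))
    sum(N_i * g) - sum(n_tot[n_tot > 0] * log(denom[n_tot > 0]))
  }
  converged <- W == 1
  iter <- 0
  df <- 0
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    wgt <- N_i * exp(g)
    A <- sweep(expB, 2, wgt, `*`)                 # n_bins x W: w_i c_ix
    denom <- rowSums(A)
    P <- A / denom                                # responsibilities
    grad <- N_i - as.vector(crossprod(P, n_tot))
    H <- crossprod(P, P * n_tot)
    diag(H) <- diag(H) - as.vector(crossprod(P, n_tot))
    Hr <- H[-1, -1, drop = FALSE]
    gr <- grad[-1]
    step <- tryCatch(solve(Hr, -gr), error = function(e) gr / max(abs(diag(Hr)), 1))
    L0 <- loglik(g)
    t <- 1
    repeat {
      g_try <- g
      g_try[-1] <- g[-1] + t * step
      if (loglik(g_try) >= L0 - 1e-12) break
      t <- t / 2
      if (t < 1e-8) break
    }
    df <- max(abs(t * step))
    g[-1] <- g[-1] + t * step
    if (df < tol) converged <- TRUE
  }
  if (!converged) {
    abort(sprintf(
      "WHAM did not converge in %d iterations (last max|dF| = %.3g kT)",
      iter, df))
  }
  f <- kT * g
  denom <- as.vector(expB %*% (N_i * exp(g)))
  rho <- ifelse(denom > 0, n_tot / denom, 0)
  pmf <- ifelse(n_tot > 0, -kT * log(pmax(rho, .Machine$double.xmin)), NA_real_)
  pmf <- pmf - min(pmf[n_tot > 0])
  new_pmf_profile(centers, pmf, kT, counts = n_tot,
                  extra = list(window_f_kJ = f, iterations = iter,
                               converged = TRUE, bin_edges = edges,
                               convention = "bias at bin centers"))
}

#' Re-zero a free-energy profile
#'
#' Applies an additive shift only: `min_zero` sets the minimum over
#' populated bins to zero; `plateau_zero` sets the mean over
#' `plateau_range` to zero. The shape is untouched and the alignment mode
#' is recorded on the result.
#'
#' @param pmf A `pmf_profile`.
#' @param mode `"min_zero"` or `"plateau_zero"`.
#' @param plateau_range c(min, max) in Angstrom; required for
#'   `plateau_zero`.
#' @return The shifted `pmf_profile`.
#' @export
align_profile <- function(pmf, mode = c("min_zero", "plateau_zero"),
                          plateau_range = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pmf, "pmf_profile"))
  ok <- populated(pmf)
  shift <- if (mode == "min_zero") {
    min(pmf$pmf_kJ_mol[ok])
  } else {
    if (is.null(plateau_range) || length(plateau_range) != 2) {
      abort("plateau_zero alignment needs plateau_range = c(min, max)")
    }
    sel <- ok & pmf$bin_center_A >= plateau_range[1] &
      pmf$bin_center_A <= plateau_range[2]
    if (!any(sel)) abort("no populated bins inside plateau_range")
    mean(pmf$pmf_kJ_mol[sel])
  }
  pmf$pmf_kJ_mol <- pmf$pmf_kJ_mol - shift
  attr(pmf, "alignment") <- mode
  pmf
}

#' Dissociation activation barrier of a profile
#'
#' The barrier is the mean free energy over the unbound plateau minus the
#' bound-state minimum (the lowest populated bin outside the plateau
#' range; for a well-formed dissociation profile this is the global
#' minimum) - the quantity that sets the dissociation rate through
#' transition-state theory. A profile whose plateau lies at or below the
#' rest of the profile has no bound state to dissociate from and is
#' flagged as pathological.
#'
#' @param pmf A `pmf_profile`.
#' @param plateau_range c(min, max) in Angstrom delimiting the unbound
#'   plateau.
#' @param error Optional barrier error to record (kJ/mol), e.g. from
#'   [bootstrap_pmf()].
#' @return An object of class `barrier_result` with fields `barrier`
#'   (kJ/mol), `minimum_A` (location of the global minimum), `plateau`
#'   (mean plateau free energy) and `error`.
#' @export
dissociation_barrier <- function(pmf, plateau_range, error = NA_real_) {
  stopifnot(inherits(pmf, "pmf_profile"), length(plateau_range) == 2)
  ok <- populated(pmf)
  if (!any(ok)) abort("profile has no populated bins")
  sel <- ok & pmf$bin_center_A >= plateau_range[1] &
    pmf$bin_center_A <= plateau_range[2]
  if (!any(sel)) abort("no populated bins inside plateau_range")
  bound <- ok & !sel
  if (!any(bound)) abort("no populated bins outside plateau_range")
  gmin <- min(pmf$pmf_kJ_mol[bound])
  imin <- which(bound)[which.min(pmf$pmf_kJ_mol[bound])]
  plateau <- mean(pmf$pmf_kJ_mol[sel])
  barrier <- plateau - gmin
  if (barrier < 0) {
    abort("pathological profile: the plateau lies below the bound-state minimum")
  }
  structure(
    list(barrier = barrier, plateau = plateau, minimum_A = pmf$bin_center_A[imin],
         plateau_range = plateau_range, error = error, kT = pmf_kT(pmf)),
    class = "barrier_result"
  )
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("Dissociation barrier: %.3f kJ/mol", x$barrier))
  if (is.finite(x$error)) cat(sprintf(" +/- %.3f", x$error))
  cat(sprintf("  (minimum at %.2f A; plateau %.1f-%.1f A)\n",
              x$minimum_A, x$plateau_range[1], x$plateau_range[2]))
  invisible(x)
}

#' @rdname dissociation_barrier
#' @param x A `barrier_result`.
#' @param ... Unused.
#' @export
tidy.barrier_result <- function(x, ...) {
  tibble(barrier_kJ_mol = x$barrier, error_kJ_mol = x$error,
         minimum_A = x$minimum_A,
         plateau_min_A = x$plateau_range[1], plateau_max_A = x$plateau_range[2])
}

#' Barrier difference between two free-energy profiles
#'
#' `delta = barrier(b) - barrier(a)`: the difference in dissociation
#' activation barrier between two profiles (e.g. unmodified vs
#' phosphorylated peptide), the quantity that enters the competition
#' model's Boltzmann factor. The operand order and resulting sign
#' convention are recorded on the result.
#'
#' @param pmf_a,pmf_b Two `pmf_profile` objects (a = reference, e.g.
#'   unmodified; b = comparison, e.g. phosphorylated).
#' @param plateau_range c(min, max) Angstrom, applied to both.
#' @param error Optional error on the difference (kJ/mol).
#' @return A `barrier_result` whose `barrier` fields are per-profile and
#'   whose `delta` field is barrier(b) - barrier(a); class
#'   `delta_barrier_result`.
#' @export
delta_barrier <- function(pmf_a, pmf_b, plateau_range, error = NA_real_) {
  ka <- pmf_kT(pmf_a); kb <- pmf_kT(pmf_b)
  if (!isTRUE(all.equal(ka, kb))) {
    abort(sprintf("profiles have different kT (%g vs %g kJ/mol); refuse to mix", ka, kb))
  }
  ba <- dissociation_barrier(pmf_a, plateau_range)
  bb <- dissociation_barrier(pmf_b, plateau_range)
  structure(
    list(barrier_a = ba$barrier, barrier_b = bb$barrier,
         delta = bb$barrier - ba$barrier, error = error,
         plateau_range = plateau_range,
         convention = "delta = barrier(b) - barrier(a)"),
    class = "delta_barrier_result"
  )
}

#' @export
print.delta_barrier_result <- function(x, ...) {
  cat(sprintf("Barrier difference: %.3f kJ/mol (%s)\n", x$delta, x$convention))
  cat(sprintf("  barrier(a) = %.3f, barrier(b) = %.3f kJ/mol\n",
              x$barrier_a, x$barrier_b))
  invisible(x)
}

#' @rdname delta_barrier
#' @param x A `delta_barrier_result`.
#' @param ... Unused.
#' @export
tidy.delta_barrier_result <- function(x, ...) {
  tibble(delta_kJ_mol = x$delta, barrier_a_kJ_mol = x$barrier_a,
         barrier_b_kJ_mol = x$barrier_b, error_kJ_mol = x$error)
}

#' Bootstrap errors for a WHAM profile and its barrier
#'
#' Resamples every window's reaction-coordinate samples with replacement,
#' re-solves WHAM for each replicate (warm-started from the full
#' solution), and reports per-bin standard deviations as the profile
#' stderr plus the standard deviation of the dissociation barrier across
#' replicates.
#'
#' @inheritParams wham_solve
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param plateau_range Plateau range for the per-replicate barrier.
#' @param seed Integer seed making the resampling reproducible.
#' @return List with `pmf` (the full-sample `pmf_profile` gaining a
#'   `stderr_kJ_mol` column), `barrier` (a `barrier_result` with its
#'   `error` filled in), and `n_failed` (replicates that failed to
#'   converge; more than 20% failing is an error).
#' @export
bootstrap_pmf <- function(windows, kT, plateau_range, n_boot = 50,
                          n_bins = 200, range = NULL, tol = 1e-7,
                          max_iter = 1e5, seed = 1) {
  stopifnot(n_boot >= 2)
  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) range <- base::range(all_samples)
  full <- wham_solve(windows, kT, n_bins = n_bins, range = range,
                     tol = tol, max_iter = max_iter)
  f0 <- attr(full, "window_f_kJ")
  idx_sets <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      lapply(windows, function(w) {
        sample.int(length(w$samples), length(w$samples), replace = TRUE)
      })
    })
  })
  reps <- vector("list", n_boot)
  n_failed <- 0
  for (b in seq_len(n_boot)) {
    wb <- lapply(seq_along(windows), function(i) {
      w <- windows[[i]]
      umbrella_window(w$center, w$spring_k, w$samples[idx_sets[[b]][[i]]])
    })
    rep_pmf <- tryCatch(
      wham_solve(wb, kT, n_bins = n_bins, range = range, tol = tol,
                 max_iter = max_iter, f_init = f0),
      error = function(e) NULL)
    if (is.null(rep_pmf)) { n_failed <- n_failed + 1; next }
    reps[[b]] <- rep_pmf
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (n_failed > 0.2 * n_boot) {
    abort(sprintf("bootstrap unstable: %d of %d replicates failed to converge",
                  n_failed, n_boot))
  }
  mat <- vapply(reps, function(p) p$pmf_kJ_mol, numeric(nrow(full)))
  stderr <- apply(mat, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) sd(v) else NA_real_
  })
  barriers <- vapply(reps, function(p)
    dissociation_barrier(p, plateau_range)$barrier, numeric(1))
  full$stderr_kJ_mol <- stderr
  barrier <- dissociation_barrier(full, plateau_range, error = sd(barriers))
  list(pmf = full, barrier = barrier, n_failed = n_failed,
       replicate_barriers = barriers)
}
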