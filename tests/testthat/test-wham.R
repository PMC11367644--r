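kT300 <- kT_kJ(300)

test_that("window schedules follow the half-open segment convention", {
  s <- build_window_schedule(claw_window_segments())
  expect_length(s, 33)
  expect_equal(s[1], 15)
  expect_equal(max(s), 37)
  expect_true(all(diff(s) > 0))
  expect_identical(attr(s, "convention"), "half-open [start, stop)")
  expect_equal(as.numeric(build_window_schedule(list(c(0, 1, 0.5)))), c(0, 0.5))
  s10 <- build_window_schedule(list(c(0, 10, 1)))
  expect_length(s10, 10)
  expect_equal(max(s10), 9)
  expect_error(build_window_schedule(list(c(0, 5, 1), c(4, 8, 1))), "overlap")
  expect_error(build_window_schedule(list(c(0, 5, -1))), "spacing")
})

test_that("schedule manifest books total sampling time", {
  s <- build_window_schedule(claw_window_segments())
  m <- schedule_manifest(s, time_per_window_ns = 100)
  g <- glance(m)
  expect_equal(g$n_windows, 33)
  expect_equal(g$total_time_ns, 3300)
  expect_equal(g$spring_kJ_mol_nm2, 10000)
})

test_that("WHAM degenerates to Boltzmann inversion for one unbiased window", {
  spec <- pmf_dissociation_spec(depth = 6, grid_min = 15, grid_max = 25,
                                n_bins = 100)
  wins <- gen_umbrella_samples(spec, centers = 20, spring_k = 1e-6,
                               n_per_window = 40000, kT = kT300,
                               cfg = generator_config(5))
  pmf <- wham_solve(wins, kT300, n_bins = 100, range = c(15, 25))
  h <- hist(wins[[1]]$samples, breaks = attr(pmf, "bin_edges"), plot = FALSE)
  ref <- -kT300 * log(h$counts)
  ok <- is.finite(pmf$pmf_kJ_mol) & is.finite(ref)
  expect_lt(max(abs((pmf$pmf_kJ_mol[ok] - min(pmf$pmf_kJ_mol[ok])) -
                      (ref[ok] - min(ref[ok])))), 1e-5)
})

test_that("WHAM is invariant to window order, duplication and splitting", {
  spec <- pmf_dissociation_spec(depth = 5, grid_min = 15, grid_max = 25,
                                n_bins = 100)
  wins <- gen_umbrella_samples(spec, centers = seq(16, 24, 1), spring_k = 1000,
                               n_per_window = 800, kT = kT300,
                               cfg = generator_config(8))
  base <- wham_solve(wins, kT300, n_bins = 100, range = c(15, 25))
  # reordering
  perm <- wham_solve(rev(wins), kT300, n_bins = 100, range = c(15, 25))
  expect_equal(perm$pmf_kJ_mol, base$pmf_kJ_mol, tolerance = 1e-6)
  # two identical windows equal one window with pooled samples
  w <- wins[[5]]
  half <- length(w$samples) %/% 2
  split2 <- list(umbrella_window(w$center, w$spring_k, w$samples[1:half]),
                 umbrella_window(w$center, w$spring_k, w$samples[-(1:half)]))
  pooled <- wham_solve(list(w), kT300, n_bins = 100, range = c(15, 25))
  split <- wham_solve(split2, kT300, n_bins = 100, range = c(15, 25))
  expect_equal(split$pmf_kJ_mol, pooled$pmf_kJ_mol, tolerance = 1e-6)
})

test_that("WHAM inverts umbrella samples back to the planted profile", {
  # restraints chosen to satisfy the standard overlap rule (sigma about
  # half the spacing), isolating solver accuracy from sampling design
  spec <- pmf_dissociation_spec(depth = 9.4)
  centers <- build_window_schedule(claw_window_segments())
  wins <- gen_umbrella_samples(spec, centers, spring_k = 1000,
                               n_per_window = 3000, kT = kT300,
                               cfg = generator_config(7))
  pmf <- wham_solve(wins, kT300, n_bins = 200, range = c(15, 38))
  truth <- as_pmf_profile(spec, kT300)
  ok <- is.finite(pmf$pmf_kJ_mol)
  rms <- sqrt(mean((pmf$pmf_kJ_mol[ok] - truth$pmf_kJ_mol[ok])^2))
  expect_lt(rms, 0.5)
  b <- dissociation_barrier(pmf, c(30, 37))
  expect_equal(b$barrier, 9.4, tolerance = 0.1)
})

test_that("profile alignment shifts without changing shape", {
  spec <- pmf_dissociation_spec(depth = 8)
  pmf <- as_pmf_profile(spec, kT300)
  a <- align_profile(pmf, "min_zero")
  expect_equal(min(a$pmf_kJ_mol), 0)
  expect_equal(align_profile(a, "min_zero")$pmf_kJ_mol, a$pmf_kJ_mol)  # idempotent
  p <- align_profile(pmf, "plateau_zero", plateau_range = c(30, 37))
  sel <- pmf$bin_center_A >= 30 & pmf$bin_center_A <= 37
  expect_equal(mean(p$pmf_kJ_mol[sel]), 0, tolerance = 1e-12)
  expect_equal(p$pmf_kJ_mol - p$pmf_kJ_mol[1], a$pmf_kJ_mol - a$pmf_kJ_mol[1])
  expect_error(align_profile(pmf, "plateau_zero"), "plateau_range")
})

test_that("dissociation barrier is the plateau height above the minimum", {
  flat <- as_pmf_profile(pmf_flat_spec(), kT300)
  expect_equal(dissociation_barrier(flat, c(30, 37))$barrier, 0)
  spec <- pmf_dissociation_spec(depth = 9.4)
  pmf <- as_pmf_profile(spec, kT300)
  b <- dissociation_barrier(pmf, c(30, 37))
  expect_equal(b$barrier, 9.4, tolerance = 1e-4)
  # shift invariance
  shifted <- pmf
  shifted$pmf_kJ_mol <- shifted$pmf_kJ_mol + 5
  expect_equal(dissociation_barrier(shifted, c(30, 37))$barrier, b$barrier)
  # pathological: inverted profile puts the global minimum on the plateau
  upside <- pmf
  upside$pmf_kJ_mol <- -upside$pmf_kJ_mol
  expect_error(dissociation_barrier(upside, c(30, 38)), "pathological")
})

test_that("barrier differences are antisymmetric and carry their convention", {
  pa <- as_pmf_profile(pmf_dissociation_spec(depth = 10), kT300)
  pb <- as_pmf_profile(pmf_dissociation_spec(depth = 19.4), kT300)
  expect_equal(delta_barrier(pa, pa, c(30, 37))$delta, 0)
  d <- delta_barrier(pa, pb, c(30, 37))
  expect_equal(d$delta, 9.4, tolerance = 1e-4)
  expect_equal(delta_barrier(pb, pa, c(30, 37))$delta, -d$delta)
  expect_match(d$convention, "barrier\\(b\\) - barrier\\(a\\)")
  pc <- as_pmf_profile(pmf_dissociation_spec(depth = 19.4), kT_kJ(310))
  expect_error(delta_barrier(pa, pc, c(30, 37)), "different kT")
})

test_that("bootstrap errors are reproducible and shrink with more sampling", {
  spec <- pmf_dissociation_spec(depth = 5, grid_min = 15, grid_max = 30,
                                n_bins = 150)
  centers <- seq(15.5, 29.5, 1)
  mk <- function(n, seed) gen_umbrella_samples(spec, centers, spring_k = 1000,
                                               n_per_window = n, kT = kT300,
                                               cfg = generator_config(seed))
  w1 <- mk(400, 21)
  b1 <- bootstrap_pmf(w1, kT300, plateau_range = c(27, 29.5), n_boot = 25,
                      n_bins = 150, range = c(15, 30), seed = 5)
  b1b <- bootstrap_pmf(w1, kT300, plateau_range = c(27, 29.5), n_boot = 25,
                       n_bins = 150, range = c(15, 30), seed = 5)
  expect_identical(b1$pmf$stderr_kJ_mol, b1b$pmf$stderr_kJ_mol)
  expect_identical(b1$barrier$error, b1b$barrier$error)
  expect_equal(b1$n_failed, 0)
  w4 <- mk(1600, 22)
  b4 <- bootstrap_pmf(w4, kT300, plateau_range = c(27, 29.5), n_boot = 25,
                      n_bins = 150, range = c(15, 30), seed = 5)
  expect_lt(mean(b4$pmf$stderr_kJ_mol, na.rm = TRUE),
            mean(b1$pmf$stderr_kJ_mol, na.rm = TRUE))
  expect_lt(b4$barrier$error, b1$barrier$error)
})

test_that("bootstrap 2-sigma intervals cover the planted barrier", {
  spec <- pmf_dissociation_spec(depth = 5, grid_min = 15, grid_max = 30,
                                n_bins = 150)
  centers <- seq(15.5, 29.5, 1)
  hits <- vapply(1:25, function(rep) {
    wins <- gen_umbrella_samples(spec, centers, spring_k = 1000,
                                 n_per_window = 400, kT = kT300,
                                 cfg = generator_config(100 + rep))
    bt <- bootstrap_pmf(wins, kT300, plateau_range = c(27, 29.5), n_boot = 20,
                        n_bins = 150, range = c(15, 30), seed = rep)
    abs(bt$barrier$barrier - 5) <= 2 * bt$barrier$error
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("pathological inputs are diagnosed, not absorbed", {
  spec <- pmf_dissociation_spec(depth = 5)
  # disconnected coverage: two stiff windows far apart
  wins <- gen_umbrella_samples(spec, centers = c(16, 33), spring_k = 10000,
                               n_per_window = 200, kT = kT300,
                               cfg = generator_config(2))
  expect_error(wham_solve(wins, kT300, n_bins = 200, range = c(15, 38)),
               "disconnected")
  # iteration budget exhausted
  dense <- gen_umbrella_samples(spec, centers = seq(16, 30, 1), spring_k = 1000,
                                n_per_window = 300, kT = kT300,
                                cfg = generator_config(3))
  expect_error(wham_solve(dense, kT300, n_bins = 150, range = c(15, 38),
                          max_iter = 1),
               "did not converge")
  expect_error(umbrella_window(17, -5, 1:10), "spring_k")
  expect_error(gen_umbrella_samples(spec, centers = numeric(0)), "non-empty")
  expect_error(gen_umbrella_samples(spec, centers = 50), "within")
})

test_that("window CSVs and manifests round-trip the samples and restraints", {
  spec <- pmf_dissociation_spec(depth = 5)
  wins <- gen_umbrella_samples(spec, centers = c(16, 17, 18), spring_k = 10000,
                               n_per_window = 50, kT = kT300,
                               cfg = generator_config(6))
  dir <- withr::local_tempdir()
  manifest <- write_window_set(wins, dir)
  back <- read_window_manifest(manifest)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$center, wins[[i]]$center)
    expect_equal(back[[i]]$spring_k, wins[[i]]$spring_k)
    expect_equal(back[[i]]$samples, wins[[i]]$samples, tolerance = 1e-9)
  }
  pmf <- wham_solve(wins, kT300, n_bins = 60)
  pcsv <- file.path(dir, "pmf.csv")
  write_pmf_csv(pmf, pcsv)
  lines <- readLines(pcsv)
  expect_match(lines[1], "kT_kJ_mol")       # units recorded in the header
  expect_match(lines[2], "bin_center_A,pmf_kJ_mol")
})
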