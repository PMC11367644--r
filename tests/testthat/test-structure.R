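toy <- gen_toy_complex()

test_that("toy complex carries exactly its planted interactions", {
  truth <- toy$metadata$truth
  hb <- detect_hbonds(toy, "chain A", "chain C")
  expect_equal(sum(hb$category == "backbone_backbone"), truth$n_backbone_hbonds)
  expect_equal(sum(hb$category == "sidechain_sidechain"), truth$n_sidechain_hbonds)
  bb <- hb[hb$category == "backbone_backbone", ]
  expect_equal(bb$distance, rep(truth$backbone_hbond_distance, 5),
               tolerance = 1e-6)
  ct <- detect_contacts(toy, "chain A", "chain C")
  expect_equal(sum(ct$type == "charge_charge"), truth$n_charge_contacts)
  expect_equal(sum(ct$type == "hydrophobic"), truth$n_hydrophobic_contacts)
  expect_equal(ct$distance[ct$type == "charge_charge"], truth$charge_distance,
               tolerance = 1e-6)
  expect_equal(ct$distance[ct$type == "hydrophobic"],
               truth$hydrophobic_distance, tolerance = 1e-6)
  # the charge pair is Lys NZ to a phosphate oxygen of the phosphoserine
  cc <- ct[ct$type == "charge_charge", ]
  expect_setequal(c(cc$atom_1, cc$atom_2), c("NZ", "O1P"))
  expect_true("SEP" %in% c(cc$resname_1, cc$resname_2))
})

test_that("detections are invariant under rigid motion and symmetric in groups", {
  set.seed(31)
  for (i in 1:5) {
    moved <- transform_structure(toy, test_rotation(), rnorm(3, 0, 20))
    hb0 <- detect_hbonds(toy, "chain A", "chain C")
    hb1 <- detect_hbonds(moved, "chain A", "chain C")
    expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
    expect_identical(hb1$category, hb0$category)
    ct0 <- detect_contacts(toy, "chain A", "chain C")
    ct1 <- detect_contacts(moved, "chain A", "chain C")
    expect_equal(ct1$distance, ct0$distance, tolerance = 1e-9)
  }
  # swapping the groups yields the identical canonical table
  expect_equal(detect_hbonds(toy, "chain C", "chain A"),
               detect_hbonds(toy, "chain A", "chain C"))
  expect_equal(detect_contacts(toy, "chain C", "chain A"),
               detect_contacts(toy, "chain A", "chain C"))
})

test_that("cutoffs act monotonically and zero cutoffs give empty results", {
  expect_equal(nrow(detect_hbonds(toy, "chain A", "chain C", d_max = 0)), 0)
  expect_equal(nrow(detect_contacts(toy, "chain A", "chain C",
                                    hydrophobic_cutoff = 0,
                                    charge_cutoff = 0)), 0)
  n35 <- nrow(detect_hbonds(toy, "chain A", "chain C", d_max = 3.5))
  n50 <- nrow(detect_hbonds(toy, "chain A", "chain C", d_max = 5.0))
  expect_gte(n50, n35)
  expect_error(detect_hbonds(toy, "chain A", "chain A and name CA"),
               "disjoint|empty")
})

test_that("PDB files round-trip through bio3d at format precision", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy, tf)
  back <- read_pdb(tf)
  a0 <- toy$atoms; a1 <- back$atoms
  expect_equal(nrow(a1), nrow(a0))
  expect_lt(max(abs(a1$x - a0$x)), 1e-3 + 1e-9)
  expect_lt(max(abs(a1$y - a0$y)), 1e-3 + 1e-9)
  expect_lt(max(abs(a1$z - a0$z)), 1e-3 + 1e-9)
  # phosphoserine survives as a HETATM peptide residue with its phosphate
  sep <- a1[a1$resname == "SEP", ]
  expect_true(all(c("P", "O1P", "O2P", "O3P", "N", "CA") %in% sep$atom))
  expect_true(all(sep$type == "HETATM"))
  # re-read detections match the in-memory ones
  expect_equal(nrow(detect_hbonds(back, "chain A", "chain C")),
               nrow(detect_hbonds(toy, "chain A", "chain C")))
  expect_error(read_pdb(withr::local_tempfile(fileext = ".none")), "no such file")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.000  10.000  10.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1      12.000  10.000  10.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   1      13.000  10.000  10.000  0.40 10.00           C",
    "ATOM      4  C  BALA A   2      14.000  10.000  10.000  0.50 10.00           C",
    "ATOM      5  C  AALA A   2      15.000  10.000  10.000  0.50 10.00           C",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  m <- read_pdb(tf)
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 12.0)              # occupancy 0.6 wins
  cc <- m$atoms[m$atoms$atom == "C", ]
  expect_equal(cc$x, 15.0)              # tie: altloc A wins alphabetically
})

test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- matrix(rnorm(3 * n, sd = 5), n)
    # random rigid motion plus structural perturbation
    y <- sweep(x %*% t(test_rotation()), 2, rnorm(3, 0, 10), `+`) +
      matrix(rnorm(3 * n, sd = 0.5), n)
    k <- kabsch_superpose(y, x)
    expect_lt(abs(k$rmsd - quaternion_rmsd(y, x)), 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
  # exact rigid copies superpose to zero
  x <- matrix(rnorm(30), 10)
  y <- sweep(x %*% t(test_rotation()), 2, c(3, -2, 9), `+`)
  expect_lt(kabsch_superpose(y, x)$rmsd, 1e-9)
  k0 <- kabsch_superpose(x, x)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  # a single displaced atom, checked against the oracle
  y2 <- x; y2[4, ] <- y2[4, ] + c(1, 0, 0)
  expect_lt(abs(kabsch_superpose(y2, x)$rmsd - quaternion_rmsd(y2, x)), 1e-9)
  expect_error(kabsch_superpose(x[1:4, ], x), "equal-size")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("CA pairing counts matched and dropped residues", {
  p <- pair_ca_atoms(toy, toy)
  expect_equal(p$n_matched, 13)          # 8 domain + 5 peptide residues
  expect_equal(p$n_only_a, 0)
  pruned <- toy
  pruned$atoms <- pruned$atoms[!(pruned$atoms$resno %in% c(1561, 1563, 124) &
                                   pruned$atoms$atom == "CA"), ]
  p2 <- pair_ca_atoms(toy, pruned)
  expect_equal(p2$n_matched, 10)
  expect_equal(p2$n_only_a, 3)
  # chain mapping: renaming chains and mapping back is equivalent
  renamed <- toy
  renamed$atoms$chain <- c(A = "C", C = "D")[renamed$atoms$chain]
  p3 <- pair_ca_atoms(toy, renamed, chain_map = c(A = "C", C = "D"))
  expect_equal(p3$n_matched, p$n_matched)
  expect_error(pair_ca_atoms(toy, renamed), "no residues in common")
})

test_that("RMSF reproduces closed forms and is rigid-motion invariant", {
  set.seed(23)
  base <- matrix(rnorm(36, sd = 3), 12)
  expect_equal(rmsf_per_atom(list(base, base, base)), rep(0, 12))
  # one atom oscillating +/- d along an axis, superposed on the fixed atoms
  d <- 0.8
  f1 <- base; f2 <- base
  f1[12, 1] <- base[12, 1] + d
  f2[12, 1] <- base[12, 1] - d
  r <- rmsf_per_atom(list(f1, f2), subset = 1:11)
  expect_equal(r[12], d, tolerance = 1e-9)
  expect_lt(max(r[1:11]), 1e-9)
  # rotating every frame rigidly changes nothing
  rot <- lapply(list(f1, f2), function(f)
    sweep(f %*% t(test_rotation()), 2, rnorm(3), `+`))
  expect_equal(rmsf_per_atom(rot, subset = 1:11), r, tolerance = 1e-9)
  expect_equal(rmsf_per_atom(list(f1, f2), superpose_to = "mean",
                             subset = 1:11)[12], d, tolerance = 1e-6)
  expect_error(rmsf_per_atom(list(base, base[1:5, ])), "inconsistent")
})

test_that("pocket detection reports residues by minimum distance", {
  pr <- pocket_residues(toy, "chain C and resi 125 and name CB",
                        receptor = "chain A", cutoff = 4.5)
  expect_equal(pr$resno, c(1566, 1567))   # backbone O of 1566 plus Leu CB
  expect_equal(pr$min_distance[pr$resno == 1567], 4.0, tolerance = 1e-6)
  # tighter cutoff isolates the nearest residue
  one <- pocket_residues(toy, "chain C and resi 125 and name CB",
                         receptor = "chain A", cutoff = 3.9)
  expect_equal(one$resno, 1566)
  expect_equal(nrow(pocket_residues(toy, "chain C and resi 125 and name CB",
                                    receptor = "chain A", cutoff = 3.0)), 0)
  wide <- pocket_residues(toy, "chain C and resi 125 and name CB",
                          receptor = "chain A", cutoff = 8)
  expect_true(all(pr$resno %in% wide$resno))   # enlarging never removes
  expect_error(pocket_residues(toy, "chain Q"), "empty ligand")
})

test_that("contact number decays to zero along a pull-apart trajectory", {
  # identical overlapping groups: n^2 pairs at distance zero
  n <- 4
  at <- tibble::tibble(chain = rep(c("A", "C"), each = n),
                       resno = rep(1:n, 2), resname = "GLY",
                       atom = paste0(rep(c("C", "O"), each = n), 1:n),
                       x = 0, y = 0, z = 0)
  ov <- structure_model(at)
  prof0 <- contact_number_profile(list(ov), 0, "chain A", "chain C", cutoff = 1e-6)
  expect_equal(prof0$contacts, n * n)
  # frames translating the peptide away
  seps <- c(0, 2, 5, 8, 12, 20)
  frames <- lapply(seps, function(s) {
    m <- gen_toy_complex()
    pep <- m$atoms$chain == "C"
    m$atoms$y[pep] <- m$atoms$y[pep] + s
    m
  })
  prof <- contact_number_profile(frames, seps + 10, "chain A", "chain C",
                                 cutoff = 4.5)
  expect_true(all(diff(prof$contacts) <= 0))
  expect_equal(prof$contacts[length(seps)], 0)
  expect_error(contact_number_profile(frames, seps[-1], "chain A", "chain C"),
               "one finite value per frame")
})

test_that("interface reports are deterministic and list the planted contacts", {
  r1 <- interface_report(toy, "chain A", "chain C")
  r2 <- interface_report(toy, "chain A", "chain C")
  expect_identical(unclass(r1), unclass(r2))
  txt <- paste(unclass(r1), collapse = "\n")
  expect_match(txt, "SEP123")
  expect_match(txt, "charge_charge")
  expect_match(txt, "hydrophobic")
  expect_equal(length(grep("hbond_backbone_backbone", unclass(r1))), 5)
  empty <- interface_report(toy, "chain A", "chain C and resi 500")
  expect_match(paste(unclass(empty), collapse = "\n"), "no contacts")
})

test_that("the selection mini-language composes clauses with and", {
  i1 <- select_atoms(toy, "chain A and name CA")
  expect_equal(length(i1), 8)
  i2 <- select_atoms(toy, "chain A and resi 1561-1563 and name CA")
  expect_equal(length(i2), 3)
  i3 <- select_atoms(toy, "resname SEP and elem P")
  expect_equal(length(i3), 1)
  i4 <- select_atoms(toy, "chain C and backbone")
  expect_equal(length(i4), 20)
  expect_error(select_atoms(toy, "chains A"), "unknown selection keyword")
})
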