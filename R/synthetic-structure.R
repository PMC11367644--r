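#' Generate a toy domain-peptide complex with planted interactions
#'
#' Builds a small two-chain model emulating the geometry the interface
#' detectors are designed for: an 8-residue "claw domain" strand
#' (chain A, residues 1561-1568) paired antiparallel-sheet style with a
#' 5-residue phosphopeptide (chain C, residues 121-125, with
#' phosphoserine SEP at 123). The construction plants, with exact
#' distances recorded as ground truth in the metadata:
#' \itemize{
#'   \item five backbone N-H...O=C hydrogen bonds at 2.90 A (peptide
#'     amide nitrogens over domain carbonyl oxygens),
#'   \item one Lys NZ / phosphate O1P charge pair at 3.00 A (which is
#'     also a side-chain hydrogen bond),
#'   \item one side-chain C-C hydrophobic contact at 4.00 A
#'     (Leu CB / Phe CB).
#' }
#' All other cross-group polar pairs exceed 3.5 A and apolar carbon
#' pairs exceed 4.5 A, so default-criteria detection returns exactly the
#' planted set.
#'
#' @param cfg A [generator_config()]; recorded in the metadata (the
#'   geometry itself is deterministic).
#' @return A [structure_model()] with `metadata$truth`.
#' @export
gen_toy_complex <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  rows <- list()
  add <- function(chain, resno, resname, atom, element, x, y, z) {
    rows[[length(rows) + 1]] <<- tibble(
      chain = chain, resno = as.integer(resno), resname = resname,
      atom = atom, element = element, x = x, y = y, z = z,
      type = if (resname == "SEP") "HETATM" else "ATOM")
  }

  # --- domain strand, chain A, residues 1561..1568 along x ---------------
  dom_names <- c("ALA", "ALA", "ALA", "LYS", "ALA", "ALA", "LEU", "ALA")
  for (i in 1:8) {
    rn <- 1560 + i
    x0 <- 3.5 * i
    add("A", rn, dom_names[i], "N", "N", x0 - 1.2, -0.5, 0)
    add("A", rn, dom_names[i], "CA", "C", x0, 0, 0)
    add("A", rn, dom_names[i], "C", "C", x0 + 1.2, 0.5, 0)
    if (i %in% 2:6) {
      add("A", rn, dom_names[i], "O", "O", x0, 1.0, 0)       # acceptor, up
    } else {
      add("A", rn, dom_names[i], "O", "O", x0 + 1.2, -0.7, 0)
    }
    if (dom_names[i] == "ALA") {
      add("A", rn, "ALA", "CB", "C", x0, -1.0, -1.1)
    }
  }
  # Lys 1564 side chain reaching toward the phosphate
  add("A", 1564, "LYS", "CB", "C", 14.1, 0.1, 1.4)
  add("A", 1564, "LYS", "CG", "C", 14.4, 0.2, 2.9)
  add("A", 1564, "LYS", "CD", "C", 14.8, 0.6, 4.4)
  add("A", 1564, "LYS", "CE", "C", 15.0, 0.6, 5.5)
  # NZ placed exactly 3.00 A from SEP O1P (see below)
  add("A", 1564, "LYS", "NZ", "N", 15.2, 0.811924, 6.75)
  # Leu 1567 side chain; CB exactly 4.00 A from Phe 125 CB
  phe_cb <- c(22.2, 4.3, -1.4)
  u <- c(1.8, -3.1, 0.5); u <- u / sqrt(sum(u^2))
  leu_cb <- phe_cb + 4 * u
  add("A", 1567, "LEU", "CB", "C", leu_cb[1], leu_cb[2], leu_cb[3])

  # --- peptide strand, chain C, residues 121..125 ------------------------
  pep_names <- c("ALA", "SER", "SEP", "ALA", "PHE")
  for (j in 1:5) {
    rn <- 120 + j
    xn <- 3.5 * (j + 1)
    nm <- pep_names[j]
    add("C", rn, nm, "N", "N", xn, 3.9, 0)      # donor over domain O: 2.90 A
    add("C", rn, nm, "CA", "C", xn + 1.2, 4.7, 0)
    add("C", rn, nm, "C", "C", xn + 2.4, 4.3, 0)
    add("C", rn, nm, "O", "O", xn + 2.4, 5.5, 0)
    if (nm == "SER") {
      add("C", rn, nm, "CB", "C", xn + 1.2, 5.6, 1.0)
      add("C", rn, nm, "OG", "O", xn + 1.2, 6.5, 1.8)
    } else if (nm == "ALA") {
      add("C", rn, nm, "CB", "C", xn + 1.2, 5.6, 1.0)
    }
  }
  # phosphoserine 123 (N at x = 14, CA at 15.2)
  add("C", 123, "SEP", "CB", "C", 15.2, 4.7, 1.5)
  add("C", 123, "SEP", "OG", "O", 15.2, 4.7, 2.9)
  add("C", 123, "SEP", "P", "P", 15.2, 4.7, 4.5)
  add("C", 123, "SEP", "O1P", "O", 15.2, 3.41, 5.25)   # 3.00 A from Lys NZ
  add("C", 123, "SEP", "O2P", "O", 14.0, 4.7, 4.0)
  add("C", 123, "SEP", "O3P", "O", 16.4, 4.7, 4.0)
  # phenylalanine 125 CB: 4.00 A from Leu 1567 CB
  add("C", 125, "PHE", "CB", "C", 22.2, 4.3, -1.4)

  atoms <- dplyr::bind_rows(rows)
  structure_model(atoms, metadata = list(
    generator = "gen_toy_complex", seed = cfg$seed,
    truth = list(
      n_backbone_hbonds = 5L, backbone_hbond_distance = 2.9,
      n_sidechain_hbonds = 1L,
      n_charge_contacts = 1L, charge_distance = 3.0,
      n_hydrophobic_contacts = 1L, hydrophobic_distance = 4.0,
      domain_selection = "chain A", peptide_selection = "chain C"
    )
  ))
}

#' Apply a rigid transformation to a structure model
#'
#' Rotates (about the origin) and translates every atom of every frame;
#' used to verify rigid-motion invariance of the geometric detectors.
#'
#' @param model A [structure_model()].
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation Length-3 shift, Angstrom (default 0).
#' @return The transformed [structure_model()].
#' @export
transform_structure <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"),
            all(dim(rotation) == c(3, 3)), length(translation) == 3)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) random rotation via QR decomposition of a Gaussian
#' matrix, determinant forced to +1. Seeded and reproducible.
#'
#' @param seed Integer seed.
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = 1) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
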