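#' Structure model container
#'
#' Atomic model held as a tibble of atoms: one row per atom with chain,
#' author residue numbering (insertion codes preserved), residue and atom
#' names, element, orthogonal Angstrom coordinates, occupancy and
#' B-factor; a `model` column indexes frames of multi-model files.
#'
#' @param atoms Data frame with columns `model`, `type`, `chain`, `resno`,
#'   `insert`, `resname`, `atom`, `element`, `x`, `y`, `z`, `occupancy`,
#'   `b_factor` (missing optional columns are filled with defaults).
#' @param metadata Free-form provenance list.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, metadata = list()) {
  atoms <- as_tibble(atoms)
  defaults <- list(model = 1L, type = "ATOM", insert = "", element = NA_character_,
                   occupancy = 1, b_factor = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste("atoms table lacks columns:", paste(miss, collapse = ", ")))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                          guess_element(atoms$atom), atoms$element)
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$insert, atoms$atom)
  if (anyDuplicated(key)) abort("duplicate (model, chain, residue, atom) records")
  atoms <- atoms[order(atoms$model, atoms$chain, atoms$resno, atoms$insert,
                       atoms$atom), ]
  structure(list(atoms = atoms, metadata = metadata), class = "structure_model")
}

# Element from the atom name's leading letters (PDB v3 naming).
guess_element <- function(atom) {
  a <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", atom)))
  ifelse(substr(a, 1, 1) %in% c("C", "N", "O", "S", "P", "H"),
         substr(a, 1, 1), substr(a, 1, 2))
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure model: %d atoms, %d chain(s) [%s], %d model(s)\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              length(unique(a$model))))
  invisible(x)
}

#' @export
as_tibble.structure_model <- function(x, ...) x$atoms

n_models <- function(model) length(unique(model$atoms$model))

# Atoms of one frame.
frame_atoms <- function(model, frame = 1L) {
  model$atoms[model$atoms$model == sort(unique(model$atoms$model))[frame], ]
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Read a PDB file into a `structure_model`
#'
#' Fixed-width parsing is delegated to `bio3d::read.pdb`. Author residue
#' numbering and insertion codes are preserved; alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by the
#' alphabetically first altloc id); HETATM records - including
#' phosphoserine (SEP) - are retained as regular residues.
#'
#' @param path Path to a PDB file.
#' @param multi Read all MODEL frames (default TRUE).
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, multi = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
                  error = function(e) {
                    abort(sprintf("failed to parse PDB %s: %s", path, conditionMessage(e)))
                  })
  at <- pdb$atom
  base <- tibble(
    model = 1L, type = at$type, chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid, atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "", NA_character_, at$elesy),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    alt = ifelse(is.na(at$alt), "", at$alt)
  )
  # altloc resolution: keep highest occupancy, ties -> first alphabetically
  base <- dplyr::group_by(base, .data$chain, .data$resno, .data$insert, .data$atom)
  base <- dplyr::arrange(base, dplyr::desc(.data$occupancy), .data$alt,
                         .by_group = TRUE)
  base <- dplyr::ungroup(dplyr::slice_head(base, n = 1))
  base$alt <- NULL
  nmod <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (multi && nmod > 1) {
    # read.pdb keeps every altloc row in xyz; altloc-resolved structures with
    # multiple models are rebuilt frame by frame from the xyz matrix
    idx <- match(paste(base$chain, base$resno, base$insert, base$atom),
                 paste(at$chain, at$resno,
                       ifelse(is.na(at$insert), "", at$insert), at$elety))
    frames <- lapply(seq_len(nmod), function(m) {
      fr <- base
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      fr$x <- xyz[idx, 1]; fr$y <- xyz[idx, 2]; fr$z <- xyz[idx, 3]
      fr$model <- m
      fr
    })
    base <- dplyr::bind_rows(frames)
  }
  structure_model(base, metadata = list(source = path))
}

#' Write a `structure_model` to a PDB file
#'
#' Delegates record formatting to `bio3d::write.pdb` (coordinates at the
#' format's 3-decimal precision). Multi-model ensembles are written as
#' MODEL/ENDMDL blocks.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  frames <- sort(unique(model$atoms$model))
  a1 <- frame_atoms(model, 1L)
  xyz <- do.call(rbind, lapply(seq_along(frames), function(i) {
    as.vector(t(coords(frame_atoms(model, i))))
  }))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = a1$type, resno = a1$resno,
    resid = a1$resname, chain = a1$chain, insert = ifelse(a1$insert == "",
                                                          NA, a1$insert),
    elety = a1$atom, o = a1$occupancy, b = a1$b_factor,
    elesy = a1$element, eleno = seq_len(nrow(a1))
  )
  invisible(path)
}

#' Select atoms with a small chain/residue/name expression language
#'
#' Grammar: clauses joined by `and`, each clause one of
#' `chain <id>[,<id>...]`, `resi <n>[-<m>][,...]`, `resno` (alias of
#' `resi`), `name <atom>[,<atom>...]`, `resname <res>[,...]`,
#' `elem <element>[,...]`, `backbone`, `sidechain`, `all`.
#' Example: `"chain A and resi 1560-1594 and name CA"`.
#'
#' @param model A [structure_model()].
#' @param expr Selection string, or a logical/integer vector of atom rows
#'   (passed through).
#' @param frame Model frame the indices refer to (default 1).
#' @return Integer row indices into `frame_atoms(model, frame)`.
#' @export
select_atoms <- function(model, expr, frame = 1L) {
  atoms <- frame_atoms(model, frame)
  if (is.logical(expr)) { stopifnot(length(expr) == nrow(atoms)); return(which(expr)) }
  if (is.numeric(expr)) return(as.integer(expr))
  stopifnot(is.character(expr), length(expr) == 1)
  keep <- rep(TRUE, nrow(atoms))
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  backbone_names <- c("N", "CA", "C", "O")
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "" || tolower(cl) == "all") next
    if (tolower(cl) == "backbone") { keep <- keep & atoms$atom %in% backbone_names; next }
    if (tolower(cl) == "sidechain") { keep <- keep & !atoms$atom %in% backbone_names; next }
    parts <- strsplit(cl, "\\s+")[[1]]
    if (length(parts) != 2) abort(sprintf("cannot parse selection clause '%s'", cl))
    key <- tolower(parts[1]); vals <- strsplit(parts[2], ",")[[1]]
    keep <- keep & switch(key,
      chain = atoms$chain %in% vals,
      resi = , resno = {
        nums <- unlist(lapply(vals, function(v) {
          if (grepl("-", v, fixed = TRUE) && !grepl("^-", v)) {
            r <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
            seq(r[1], r[2])
          } else as.integer(v)
        }))
        atoms$resno %in% nums
      },
      name = atoms$atom %in% vals,
      resname = atoms$resname %in% vals,
      elem = toupper(atoms$element) %in% toupper(vals),
      abort(sprintf("unknown selection keyword '%s'", key))
    )
  }
  which(keep)
}
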