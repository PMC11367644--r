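#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid superposition of paired coordinate sets via the
#' SVD of the covariance matrix, with a proper rotation enforced
#' (determinant +1, so mirror solutions are excluded).
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), paired
#'   row by row; n >= 3 non-collinear points.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(R) + translation`), `rmsd` (Angstrom) and
#'   `transformed` (the superposed mobile coordinates).
#' @examples
#' set.seed(1); x <- matrix(rnorm(30), 10)
#' kabsch_superpose(x, x)$rmsd   # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv <- svd(A)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-9)) {
    abort("degenerate (collinear) coordinates: superposition is not unique")
  }
  H <- crossprod(A, B)                  # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(A %*% t(R), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((transformed - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, transformed = transformed)
}

#' Pair CA atoms of two models by chain and residue number
#'
#' Builds the paired coordinate sets behind an "n-n atoms" CA comparison:
#' CA atoms are matched by (mapped chain, residue number, insertion
#' code); unmatched residues are dropped and counted.
#'
#' @param a,b Two [structure_model()] objects.
#' @param selection_a,selection_b Selection expressions restricting each
#'   model (default all CA atoms).
#' @param chain_map Named character vector mapping chains of `a` onto
#'   chains of `b`, e.g. `c(A = "C", B = "D")`; default identity.
#' @return List with `xyz_a`, `xyz_b` (paired n x 3 matrices),
#'   `n_matched`, `n_only_a`, `n_only_b` and the pairing table `pairs`.
#' @export
pair_ca_atoms <- function(a, b, selection_a = "name CA",
                          selection_b = "name CA", chain_map = NULL) {
  ta <- frame_atoms(a)[select_atoms(a, selection_a), ]
  tb <- frame_atoms(b)[select_atoms(b, selection_b), ]
  ta <- ta[ta$atom == "CA", ]; tb <- tb[tb$atom == "CA", ]
  if (nrow(ta) == 0 || nrow(tb) == 0) abort("selection resolves to no CA atoms")
  mapped <- if (is.null(chain_map)) ta$chain else {
    unname(ifelse(ta$chain %in% names(chain_map), chain_map[ta$chain], ta$chain))
  }
  key_a <- paste(mapped, ta$resno, ta$insert)
  key_b <- paste(tb$chain, tb$resno, tb$insert)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) abort("no residues in common between the selections")
  ia <- match(common, key_a); ib <- match(common, key_b)
  ord <- order(tb$chain[ib], tb$resno[ib], tb$insert[ib])
  ia <- ia[ord]; ib <- ib[ord]
  list(
    xyz_a = coords(ta[ia, ]), xyz_b = coords(tb[ib, ]),
    n_matched = length(ia),
    n_only_a = nrow(ta) - length(ia), n_only_b = nrow(tb) - length(ib),
    pairs = tibble(chain_a = ta$chain[ia], resno_a = ta$resno[ia],
                   chain_b = tb$chain[ib], resno_b = tb$resno[ib])
  )
}

#' Per-atom root-mean-square fluctuation over an ensemble
#'
#' Each frame is rigidly superposed (on a chosen atom subset) either onto
#' the first frame or onto the iteratively refined ensemble mean; the
#' RMSF of atom i is `sqrt(mean_frames |r_i - <r_i>|^2)` after
#' superposition.
#'
#' @param ensemble List of n x 3 coordinate matrices (equal n), or a
#'   multi-model [structure_model()] (all atoms of each frame).
#' @param superpose_to `"first"` or `"mean"`.
#' @param subset Integer indices of the atoms used for superposition
#'   (default all atoms).
#' @return Numeric vector of per-atom RMSF values (Angstrom).
#' @export
rmsf_per_atom <- function(ensemble, superpose_to = c("first", "mean"),
                          subset = NULL) {
  superpose_to <- match.arg(superpose_to)
  if (inherits(ensemble, "structure_model")) {
    ensemble <- lapply(seq_len(n_models(ensemble)), function(i)
      coords(frame_atoms(ensemble, i)))
  }
  stopifnot(is.list(ensemble), length(ensemble) >= 2)
  n <- nrow(ensemble[[1]])
  if (any(vapply(ensemble, nrow, 0L) != n)) abort("inconsistent atom counts across frames")
  if (is.null(subset)) subset <- seq_len(n)
  fit_frames <- function(ref) {
    lapply(ensemble, function(fr) {
      k <- kabsch_superpose(fr[subset, , drop = FALSE], ref[subset, , drop = FALSE])
      sweep(sweep(fr, 2, colMeans(fr[subset, , drop = FALSE])) %*% t(k$rotation),
            2, colMeans(ref[subset, , drop = FALSE]), `+`)
    })
  }
  fitted <- fit_frames(ensemble[[1]])
  if (superpose_to == "mean") {
    for (it in 1:10) {
      m <- Reduce(`+`, fitted) / length(fitted)
      new_fitted <- fit_frames(m)
      shift <- max(abs(Reduce(`+`, new_fitted) / length(new_fitted) - m))
      fitted <- new_fitted
      if (shift < 1e-10) break
    }
  }
  m <- Reduce(`+`, fitted) / length(fitted)
  sq <- Reduce(`+`, lapply(fitted, function(fr) rowSums((fr - m)^2))) / length(fitted)
  sqrt(sq)
}
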