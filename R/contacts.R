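backbone_atom_names <- c("N", "CA", "C", "O")

charged_group_atoms <- function(atoms) {
  (atoms$resname == "LYS" & atoms$atom == "NZ") |
  (atoms$resname == "ARG" & atoms$atom %in% c("NH1", "NH2", "NE")) |
  (atoms$resname == "ASP" & atoms$atom %in% c("OD1", "OD2")) |
  (atoms$resname == "GLU" & atoms$atom %in% c("OE1", "OE2")) |
  (atoms$atom %in% c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"))
}

# All cross distances between two atom tables; long tibble (i, j, distance).
cross_distances <- function(ta, tb, cutoff) {
  xa <- coords(ta); xb <- coords(tb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  tibble(i = hit[, 1], j = hit[, 2],
         distance = sqrt(pmax(d2[hit], 0)))
}

# Covalently-bonded heavy neighbour of each atom (nearest same-residue heavy
# atom within 1.8 A); NA when the residue has no such neighbour.
antecedent_coords <- function(atoms, idx) {
  out <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) {
    a <- atoms[idx[k], ]
    res <- atoms[atoms$chain == a$chain & atoms$resno == a$resno &
                   atoms$insert == a$insert & atoms$atom != a$atom &
                   toupper(atoms$element) != "H", ]
    if (nrow(res) == 0) next
    d <- sqrt((res$x - a$x)^2 + (res$y - a$y)^2 + (res$z - a$z)^2)
    if (min(d) > 1.8) next
    out[k, ] <- as.numeric(res[which.min(d), c("x", "y", "z")])
  }
  out
}

atom_label_cols <- function(atoms, idx, suffix) {
  out <- atoms[idx, c("chain", "resno", "resname", "atom")]
  names(out) <- paste0(names(out), suffix)
  out
}

# Canonical ordering so results are invariant under swapping the groups:
# within each pair, side 1 is the lexicographically smaller atom.
canonicalize_pairs <- function(ta, tb, hits, extra = NULL) {
  key <- function(at, i) sprintf("%s|%09d|%s|%s", at$chain[i], at$resno[i] + 1e8,
                                 at$insert[i], at$atom[i])
  ka <- key(ta, hits$i); kb <- key(tb, hits$j)
  first_a <- ka <= kb
  a1 <- dplyr::bind_rows(atom_label_cols(ta, hits$i[first_a], "_1"),
                         atom_label_cols(tb, hits$j[!first_a], "_1"))
  a2 <- dplyr::bind_rows(atom_label_cols(tb, hits$j[first_a], "_2"),
                         atom_label_cols(ta, hits$i[!first_a], "_2"))
  out <- dplyr::bind_cols(a1, a2)
  out$distance <- c(hits$distance[first_a], hits$distance[!first_a])
  if (!is.null(extra)) {
    for (nm in names(extra)) out[[nm]] <- c(extra[[nm]][first_a], extra[[nm]][!first_a])
  }
  dplyr::arrange(out, .data$chain_1, .data$resno_1, .data$atom_1,
                 .data$chain_2, .data$resno_2, .data$atom_2)
}

#' Detect hydrogen bonds between two atom groups
#'
#' Heavy-atom criterion suited to crystal structures without hydrogens:
#' a nitrogen or oxygen of one group within `d_max` of a nitrogen or
#' oxygen of the other group, in different residues, with a
#' donor-antecedent angle (angle at the candidate donor between its
#' covalently bonded neighbour and the acceptor) of at least `angle_min`
#' degrees on at least one side of the pair. Categories follow the atom
#' names: backbone atoms are N, CA, C, O; phosphoserine (SEP) side-chain
#' oxygens count as side-chain acceptors.
#'
#' @param model A [structure_model()].
#' @param groupA,groupB Disjoint selections (see [select_atoms()]).
#' @param d_max Heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min Donor-antecedent angle cutoff, degrees (default 90).
#' @return Tibble of hydrogen bonds: partner atoms (canonically ordered,
#'   so the result is invariant under swapping the groups), `distance`
#'   (Angstrom) and `category` (backbone_backbone, backbone_sidechain or
#'   sidechain_sidechain), sorted deterministically.
#' @export
detect_hbonds <- function(model, groupA, groupB, d_max = 3.5, angle_min = 90) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- frame_atoms(model)
  ia <- select_atoms(model, groupA); ib <- select_atoms(model, groupB)
  if (length(ia) == 0 || length(ib) == 0) abort("empty selection")
  if (length(intersect(ia, ib)) > 0) abort("groupA and groupB must be disjoint")
  empty <- tibble(chain_1 = character(), resno_1 = integer(),
                  resname_1 = character(), atom_1 = character(),
                  chain_2 = character(), resno_2 = integer(),
                  resname_2 = character(), atom_2 = character(),
                  distance = numeric(), category = character())
  if (d_max <= 0) return(empty)
  polar <- function(at) toupper(at$element) %in% c("N", "O")
  ta <- atoms[ia, ][polar(atoms[ia, ]), ]
  tb <- atoms[ib, ][polar(atoms[ib, ]), ]
  if (nrow(ta) == 0 || nrow(tb) == 0) return(empty)
  hits <- cross_distances(ta, tb, d_max)
  if (nrow(hits) == 0) return(empty)
  same_res <- ta$chain[hits$i] == tb$chain[hits$j] &
    ta$resno[hits$i] == tb$resno[hits$j] & ta$insert[hits$i] == tb$insert[hits$j]
  hits <- hits[!same_res, ]
  if (nrow(hits) == 0) return(empty)
  ang_ok <- function(at_d, id, at_a, ia2) {
    ante <- antecedent_coords(atoms, match(paste(at_d$chain[id], at_d$resno[id],
                                                 at_d$insert[id], at_d$atom[id]),
                                           paste(atoms$chain, atoms$resno,
                                                 atoms$insert, atoms$atom)))
    don <- coords(at_d[id, ]); acc <- coords(at_a[ia2, ])
    v1 <- ante - don; v2 <- acc - don
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * pmax(sqrt(rowSums(v2^2)), 1e-12))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ifelse(is.na(ang), TRUE, ang >= angle_min)   # no antecedent: accept
  }
  ok <- ang_ok(ta, hits$i, tb, hits$j) | ang_ok(tb, hits$j, ta, hits$i)
  hits <- hits[ok, ]
  if (nrow(hits) == 0) return(empty)
  bb_a <- ta$atom[hits$i] %in% backbone_atom_names
  bb_b <- tb$atom[hits$j] %in% backbone_atom_names
  category <- ifelse(bb_a & bb_b, "backbone_backbone",
                     ifelse(bb_a | bb_b, "backbone_sidechain", "sidechain_sidechain"))
  canonicalize_pairs(ta, tb, hits, extra = list(category = category))
}

#' Detect hydrophobic and charge-charge contacts between two groups
#'
#' Hydrophobic contacts are pairs of apolar (side-chain) carbon atoms
#' within `hydrophobic_cutoff`; charge-charge contacts are pairs of
#' charged-group atoms (Lys NZ; Arg NH1/NH2/NE; Asp OD1/OD2; Glu
#' OE1/OE2; phosphate O1P/O2P/O3P or OP1/OP2/OP3) within
#' `charge_cutoff`.
#'
#' @inheritParams detect_hbonds
#' @param hydrophobic_cutoff Carbon-carbon cutoff, Angstrom (default 4.5).
#' @param charge_cutoff Charged-atom cutoff, Angstrom (default 4.0).
#' @return Tibble of contacts with canonical pair columns, `distance`
#'   and `type` (`hydrophobic` or `charge_charge`).
#' @export
detect_contacts <- function(model, groupA, groupB, hydrophobic_cutoff = 4.5,
                            charge_cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- frame_atoms(model)
  ia <- select_atoms(model, groupA); ib <- select_atoms(model, groupB)
  if (length(ia) == 0 || length(ib) == 0) abort("empty selection")
  if (length(intersect(ia, ib)) > 0) abort("groupA and groupB must be disjoint")
  pieces <- list()
  apolar <- function(at) toupper(at$element) == "C" &
    !at$atom %in% c("C", "CA")
  if (hydrophobic_cutoff > 0) {
    ta <- atoms[ia, ][apolar(atoms[ia, ]), ]
    tb <- atoms[ib, ][apolar(atoms[ib, ]), ]
    if (nrow(ta) > 0 && nrow(tb) > 0) {
      hits <- cross_distances(ta, tb, hydrophobic_cutoff)
      if (nrow(hits) > 0) {
        pieces$hydro <- canonicalize_pairs(
          ta, tb, hits, extra = list(type = rep("hydrophobic", nrow(hits))))
      }
    }
  }
  if (charge_cutoff > 0) {
    ta <- atoms[ia, ][charged_group_atoms(atoms[ia, ]), ]
    tb <- atoms[ib, ][charged_group_atoms(atoms[ib, ]), ]
    if (nrow(ta) > 0 && nrow(tb) > 0) {
      hits <- cross_distances(ta, tb, charge_cutoff)
      if (nrow(hits) > 0) {
        pieces$charge <- canonicalize_pairs(
          ta, tb, hits, extra = list(type = rep("charge_charge", nrow(hits))))
      }
    }
  }
  if (length(pieces) == 0) {
    return(tibble(chain_1 = character(), resno_1 = integer(),
                  resname_1 = character(), atom_1 = character(),
                  chain_2 = character(), resno_2 = integer(),
                  resname_2 = character(), atom_2 = character(),
                  distance = numeric(), type = character()))
  }
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$type, .data$chain_1, .data$resno_1, .data$atom_1,
                 .data$chain_2, .data$resno_2, .data$atom_2)
}

#' Receptor residues lining a ligand pocket
#'
#' Receptor residues owning at least one atom within `cutoff` of at least
#' one ligand atom, with the per-residue minimum distance.
#'
#' @param model A [structure_model()].
#' @param ligand Selection of the ligand atoms (e.g. one side chain).
#' @param receptor Selection of candidate pocket atoms (default: all
#'   atoms not in `ligand`).
#' @param cutoff Distance cutoff, Angstrom (default 4.5).
#' @return Tibble (`chain`, `resno`, `resname`, `min_distance`) sorted by
#'   chain and residue number.
#' @export
pocket_residues <- function(model, ligand, receptor = NULL, cutoff = 4.5) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- frame_atoms(model)
  il <- select_atoms(model, ligand)
  if (length(il) == 0) abort("empty ligand selection")
  ir <- if (is.null(receptor)) setdiff(seq_len(nrow(atoms)), il)
        else setdiff(select_atoms(model, receptor), il)
  ta <- atoms[ir, ]; tl <- atoms[il, ]
  if (nrow(ta) == 0 || cutoff <= 0) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), min_distance = numeric()))
  }
  hits <- cross_distances(ta, tl, cutoff)
  if (nrow(hits) == 0) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), min_distance = numeric()))
  }
  res <- tibble(chain = ta$chain[hits$i], resno = ta$resno[hits$i],
                resname = ta$resname[hits$i], distance = hits$distance)
  res <- dplyr::summarise(dplyr::group_by(res, .data$chain, .data$resno,
                                          .data$resname),
                          min_distance = min(.data$distance), .groups = "drop")
  dplyr::arrange(res, .data$chain, .data$resno)
}

#' Contact count versus reaction coordinate across an ensemble
#'
#' For each frame, counts heavy-atom pairs between the two groups within
#' `cutoff`; ordered by the per-frame scalar reaction coordinate (e.g.
#' center-of-mass distance), the standard diagnostic that contacts decay
#' to zero as a complex separates.
#'
#' @param frames A multi-model [structure_model()] or list of
#'   single-model ones.
#' @param d_com Numeric reaction-coordinate value per frame, Angstrom.
#' @param groupA,groupB Selections evaluated on each frame.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 4.5).
#' @return Tibble (`d_com`, `contacts`) sorted by `d_com`.
#' @export
contact_number_profile <- function(frames, d_com, groupA, groupB, cutoff = 4.5) {
  if (inherits(frames, "structure_model")) {
    frames <- lapply(seq_len(n_models(frames)), function(i) {
      structure_model(frame_atoms(frames, i))
    })
  }
  if (length(d_com) != length(frames) || anyNA(d_com)) {
    abort("d_com must supply one finite value per frame")
  }
  counts <- vapply(frames, function(fr) {
    atoms <- frame_atoms(fr)
    ia <- select_atoms(fr, groupA); ib <- select_atoms(fr, groupB)
    ta <- atoms[ia, ]; tb <- atoms[ib, ]
    ta <- ta[toupper(ta$element) != "H", ]; tb <- tb[toupper(tb$element) != "H", ]
    if (nrow(ta) == 0 || nrow(tb) == 0) return(0L)
    nrow(cross_distances(ta, tb, cutoff))
  }, integer(1))
  dplyr::arrange(tibble(d_com = as.numeric(d_com), contacts = counts), .data$d_com)
}

#' Plain-text interface report for a domain-peptide complex
#'
#' Merges hydrogen bonds, charge-charge pairs and hydrophobic contacts
#' into a deduplicated listing grouped by peptide residue, each
#' interaction with its distance in Angstrom; repeated invocation yields
#' byte-identical text.
#'
#' @param model A [structure_model()].
#' @param domain,peptide Disjoint selections.
#' @param d_max,hydrophobic_cutoff,charge_cutoff Criteria forwarded to
#'   [detect_hbonds()] and [detect_contacts()].
#' @return Character vector of report lines (class `interface_report`);
#'   the underlying tables are attached as attributes `hbonds` and
#'   `contacts`.
#' @export
interface_report <- function(model, domain, peptide, d_max = 3.5,
                             hydrophobic_cutoff = 4.5, charge_cutoff = 4.0) {
  ip <- select_atoms(model, peptide)
  atoms <- frame_atoms(model)
  header <- "Domain-peptide interface report"
  if (length(ip) == 0) {
    out <- c(header, "  no contacts (empty peptide selection)")
    class(out) <- c("interface_report", class(out))
    return(out)
  }
  hb <- detect_hbonds(model, domain, peptide, d_max = d_max)
  ct <- detect_contacts(model, domain, peptide,
                        hydrophobic_cutoff = hydrophobic_cutoff,
                        charge_cutoff = charge_cutoff)
  pep_res <- unique(atoms[ip, c("chain", "resno", "resname")])
  pep_key <- paste(pep_res$chain, pep_res$resno)
  lines <- header
  any_contact <- FALSE
  fmt_side <- function(ch, rn, rnm, at) sprintf("%s/%s%d/%s", ch, rnm, rn, at)
  for (r in order(pep_res$chain, pep_res$resno)) {
    key <- pep_key[r]
    side1_pep_hb <- paste(hb$chain_1, hb$resno_1) == key
    side2_pep_hb <- paste(hb$chain_2, hb$resno_2) == key
    side1_pep_ct <- paste(ct$chain_1, ct$resno_1) == key
    side2_pep_ct <- paste(ct$chain_2, ct$resno_2) == key
    rows <- list()
    pick <- function(tab, s1, s2, kind_col) {
      if (!any(s1 | s2)) return(NULL)
      sub <- tab[s1 | s2, ]
      flip <- paste(sub$chain_1, sub$resno_1) != key
      tibble(
        pep = ifelse(flip,
                     fmt_side(sub$chain_2, sub$resno_2, sub$resname_2, sub$atom_2),
                     fmt_side(sub$chain_1, sub$resno_1, sub$resname_1, sub$atom_1)),
        dom = ifelse(flip,
                     fmt_side(sub$chain_1, sub$resno_1, sub$resname_1, sub$atom_1),
                     fmt_side(sub$chain_2, sub$resno_2, sub$resname_2, sub$atom_2)),
        kind = sub[[kind_col]], distance = sub$distance)
    }
    rows <- dplyr::bind_rows(pick(hb, side1_pep_hb, side2_pep_hb, "category"),
                             pick(ct, side1_pep_ct, side2_pep_ct, "type"))
    if (is.null(rows) || nrow(rows) == 0) next
    rows$kind <- ifelse(rows$kind %in% c("hydrophobic", "charge_charge"),
                        rows$kind, paste0("hbond_", rows$kind))
    rows <- unique(dplyr::arrange(rows, .data$distance, .data$kind, .data$dom))
    any_contact <- TRUE
    lines <- c(lines, sprintf("%s %s%d:", pep_res$chain[r], pep_res$resname[r],
                              pep_res$resno[r]))
    lines <- c(lines, sprintf("  %-18s %s -- %s  %.2f A",
                              rows$kind, rows$pep, rows$dom, rows$distance))
  }
  if (!any_contact) lines <- c(lines, "  no contacts")
  out <- lines
  attr(out, "hbonds") <- hb
  attr(out, "contacts") <- ct
  class(out) <- c("interface_report", class(out))
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
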