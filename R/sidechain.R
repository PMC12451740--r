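#' Default switching parameters for side-chain packing features
#'
#' Rational switch on the distance between side-chain centers of mass:
#' `r0 = 6.5` Angstrom (typical side-chain contact scale), `n = 6`,
#' `m = 10`, hard cutoff `d_max = 19.5` Angstrom.
#'
#' @return An `fcv_switch`.
#' @export
sc_switch_params <- function() switch_params(r0 = 6.5, n = 6L, m = 10L, d0 = 0, d_max = 19.5)

.backbone_names <- c("N", "CA", "C", "O", "OXT",
                     "H", "HN", "H1", "H2", "H3", "HA", "HA1", "HA2", "HA3")

#' Side-chain center of mass
#'
#' Mass-weighted center of a residue's non-backbone atoms (heavy atoms and
#' their hydrogens; backbone = N, CA, C, O and backbone hydrogens).
#' Glycine, which has no side chain, is represented by its CA position so
#' that it can still participate in packing features.
#'
#' @param top An `fcv_topology`.
#' @param frame An `fcv_frame`.
#' @param residue 0-based residue index (must be protein).
#' @return Length-3 numeric position (Angstrom).
#' @export
sidechain_com <- function(top, frame, residue) {
  .check_frame(frame, top)
  idx <- .sidechain_atoms(top, residue)
  w <- top$atoms$mass[idx]
  colSums(frame$xyz[idx, , drop = FALSE] * w) / sum(w)
}

## 1-based atom row indices of the residue's side chain (CA for glycine)
.sidechain_atoms <- function(top, residue) {
  a <- top$atoms
  rows <- which(a$resid == residue)
  if (length(rows) == 0L) .stopf("residue %d not in topology", residue)
  if (!all(a$is_protein[rows])) .stopf("residue %d is not a protein residue", residue)
  sc <- rows[!(a$name[rows] %in% .backbone_names)]
  if (length(sc) == 0L) {
    sc <- rows[a$name[rows] == "CA"]
    if (length(sc) == 0L) .stopf("residue %d has neither side-chain atoms nor CA", residue)
  }
  sc
}

#' Construct a side-chain packing feature
#'
#' A rational switch on the minimum-image distance between the side-chain
#' centers of mass of two residues.  Native features originate from the
#' folded basin (coefficient +1 in the CV), non-native from the unfolded
#' basin (coefficient -1).
#'
#' @param top An `fcv_topology`.
#' @param i,j 0-based residue indices with `|i - j| >= min_sep`.
#' @param kind `"native"` or `"non-native"`.
#' @param params Switch parameters; default [sc_switch_params()].
#' @param min_sep Minimum sequence separation (default 2; adjacent side
#'   chains are near-always in contact and carry no discriminative signal).
#' @return An object of class `fcv_sc_feature`.
#' @export
sc_feature <- function(top, i, j, kind = c("native", "non-native"),
                       params = sc_switch_params(), min_sep = 2L) {
  kind <- match.arg(kind)
  if (abs(i - j) < min_sep)
    .stopf("residues %d and %d are %d apart (minimum separation %d)", i, j, abs(i - j), min_sep)
  ai <- .sidechain_atoms(top, i)  # validates residues
  aj <- .sidechain_atoms(top, j)
  structure(list(
    i = as.integer(min(i, j)), j = as.integer(max(i, j)), kind = kind,
    origin = if (kind == "native") "folded" else "unfolded",
    atoms_i = as.integer(if (i < j) ai else aj) - 1L,
    atoms_j = as.integer(if (i < j) aj else ai) - 1L,
    params = params
  ), class = "fcv_sc_feature")
}

#' @export
print.fcv_sc_feature <- function(x, ...) {
  cat(sprintf("<sidechain %s> residues %d-%d, r0 = %g A\n", x$kind, x$i, x$j, x$params$r0))
  invisible(x)
}

#' Evaluate a side-chain packing feature on one frame
#'
#' @param f An `fcv_sc_feature`.
#' @param frame An `fcv_frame`.
#' @param top The matching `fcv_topology`.
#' @return Scalar in `[0, 1]`: the rational switch on the COM-COM
#'   minimum-image distance.  Symmetric in the two residues.
#' @export
evaluate_sc_feature <- function(f, frame, top) {
  .check_frame(frame, top)
  ci <- sidechain_com(top, frame, f$i)
  cj <- sidechain_com(top, frame, f$j)
  rational_switch(.pbc_dist(ci, cj, frame$box), f$params)
}

## Vectorised over frames: COM series (3 x nframes) of a fixed atom set
.com_series <- function(traj, atoms0) {
  w <- traj$topology$atoms$mass[atoms0 + 1L]
  acc <- 0
  for (k in seq_along(atoms0)) acc <- acc + w[k] * .atom_series(traj, atoms0[k])
  acc / sum(w)
}

.eval_sc_frames <- function(f, traj) {
  ci <- .com_series(traj, f$atoms_i)
  cj <- .com_series(traj, f$atoms_j)
  rational_switch(.pbc_dist_frames(ci, cj, traj$box), f$params)
}
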