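#' Default switching parameters for hydrogen-bond features
#'
#' Rational switch on the donor-heavy-atom to acceptor distance:
#' `r0 = 3.0` Angstrom, `n = 6`, `m = 10`, `d0 = 0`, hard cutoff
#' `d_max = 9` Angstrom.  These defaults are configuration choices (typical
#' hydrogen-bond length scales), exposed rather than hard-wired.
#'
#' @return An `fcv_switch`.
#' @export
hb_switch_params <- function() switch_params(r0 = 3.0, n = 6L, m = 10L, d0 = 0, d_max = 9)

#' Default switching parameters for water-competition terms
#'
#' Applied to distances between a protein polar atom and water oxygens.
#'
#' @return An `fcv_switch`.
#' @export
water_switch_params <- function() switch_params(r0 = 3.0, n = 6L, m = 10L, d0 = 0, d_max = 9)

#' Identify hydrogen-bond donors and acceptors in a protein topology
#'
#' Donors are protein N/O/S heavy atoms with at least one covalently bonded
#' hydrogen (assigned by distance < 1.2 Angstrom when, as in most PDB
#' files, no bond table exists); acceptors are all protein N/O/S heavy
#' atoms.  Backbone and side-chain polar atoms are both included.  Water
#' atoms are excluded throughout.
#'
#' @param top An `fcv_topology` including hydrogens.
#' @param frame An `fcv_frame` used for the distance-based
#'   hydrogen-to-donor assignment; defaults to the frame read with the
#'   topology file.
#' @return A list with `donors` (data frame, columns `heavy` and
#'   `hydrogen`, 0-based atom indices; one row per D-H pair) and
#'   `acceptors` (0-based integer vector).
#' @export
identify_donors_acceptors <- function(top, frame = attr(top, "frame")) {
  a <- top$atoms
  polar <- which(a$is_protein & a$element %in% c("N", "O", "S"))
  hyd <- which(a$is_protein & a$element == "H")
  if (length(polar) > 0L && length(hyd) == 0L)
    .stopf(paste("topology contains no hydrogens: supply an H-complete",
                 "structure (donors cannot be identified without hydrogens)"))
  if (length(polar) == 0L)
    return(list(donors = data.frame(heavy = integer(0), hydrogen = integer(0)),
                acceptors = integer(0)))
  if (is.null(frame)) .stopf("a coordinate frame is required to assign hydrogens to donors")
  .check_frame(frame, top)
  xyz <- frame$xyz
  donors <- list()
  for (h in hyd) {
    d2 <- colSums((t(xyz[polar, , drop = FALSE]) - xyz[h, ])^2)
    j <- which(d2 < 1.2^2)
    if (length(j) > 0L) {
      j <- j[which.min(d2[j])]
      donors[[length(donors) + 1L]] <- c(heavy = polar[j] - 1L, hydrogen = h - 1L)
    }
  }
  donors <- if (length(donors)) as.data.frame(do.call(rbind, donors))
            else data.frame(heavy = integer(0), hydrogen = integer(0))
  list(donors = donors, acceptors = polar - 1L)
}

#' Construct a hydrogen-bond feature
#'
#' A native hydrogen-bond feature is the product of a rational switch on
#' the donor-heavy-atom to acceptor distance and an angular term on the
#' D-H...A angle, minus competing protein-water and protein-protein terms
#' attached to the same polar atoms.  A non-native feature (harvested from
#' the unfolded basin) is the bare distance-times-angular switch of that
#' contact; it is subtracted at CV level with coefficient -1.
#'
#' @param top An `fcv_topology` (used for validation).
#' @param donor,hydrogen,acceptor 0-based atom indices of the donor heavy
#'   atom, its hydrogen, and the acceptor.
#' @param kind `"native"` or `"non-native"`; sets the origin basin
#'   (`folded` / `unfolded`).
#' @param dist_switch,ang_switch,water_switch Switch parameters
#'   ([switch_params()]); defaults [hb_switch_params()], [angular_params()],
#'   [water_switch_params()].
#' @param competitors 0-based indices of competing protein acceptors that
#'   can seize the donor (native features only).
#' @param lambda_w,lambda_p Weights in `[0, 1]` of the water and protein
#'   competition terms (default 1); ablation modes zero them.
#' @param min_sep Minimum donor-acceptor residue separation (default 2).
#' @return An object of class `fcv_hbond_feature`.
#' @export
hbond_feature <- function(top, donor, hydrogen, acceptor, kind = c("native", "non-native"),
                          dist_switch = hb_switch_params(),
                          ang_switch = angular_params(),
                          water_switch = water_switch_params(),
                          competitors = integer(0),
                          lambda_w = 1, lambda_p = 1, min_sep = 2L) {
  kind <- match.arg(kind)
  a <- top$atoms
  idx <- c(donor, hydrogen, acceptor, competitors) + 1L
  if (any(idx < 1L | idx > nrow(a))) .stopf("atom index out of range for topology")
  if (!all(a$is_protein[c(donor, acceptor) + 1L]))
    .stopf("hydrogen-bond donor and acceptor must be protein atoms")
  if (donor == acceptor) .stopf("donor and acceptor must be distinct")
  sep <- abs(a$resid[donor + 1L] - a$resid[acceptor + 1L])
  if (sep < min_sep)
    .stopf("donor and acceptor are %d residues apart (minimum separation %d)", sep, min_sep)
  structure(list(
    donor = as.integer(donor), hydrogen = as.integer(hydrogen),
    acceptor = as.integer(acceptor), kind = kind,
    origin = if (kind == "native") "folded" else "unfolded",
    dist_switch = dist_switch, ang_switch = ang_switch, water_switch = water_switch,
    competitors = as.integer(competitors),
    lambda_w = lambda_w, lambda_p = lambda_p
  ), class = "fcv_hbond_feature")
}

#' @export
print.fcv_hbond_feature <- function(x, ...) {
  cat(sprintf("<hbond %s> D=%d H=%d A=%d, %d protein competitor(s), lw=%g lp=%g\n",
              x$kind, x$donor, x$hydrogen, x$acceptor, length(x$competitors),
              x$lambda_w, x$lambda_p))
  invisible(x)
}

#' Protein-water competition term
#'
#' Sum over all water oxygens of the rational switch on the distance
#' (minimum image when the frame has a box) between a protein polar atom
#' and the water oxygen.  Zero when no water is within range.
#'
#' @param polar_atom 0-based index of a protein donor/acceptor atom.
#' @param frame An `fcv_frame`.
#' @param top The matching `fcv_topology`.
#' @param params Switch parameters; default [water_switch_params()].
#' @return Non-negative scalar.
#' @export
water_competition <- function(polar_atom, frame, top, params = water_switch_params()) {
  .check_frame(frame, top)
  wo <- which(top$atoms$is_water & top$atoms$element == "O")
  if (length(wo) == 0L) return(0)
  p <- frame$xyz[polar_atom + 1L, ]
  d <- frame$xyz[wo, , drop = FALSE] - matrix(p, length(wo), 3, byrow = TRUE)
  d <- .min_image(d, frame$box)
  sum(rational_switch(sqrt(rowSums(d * d)), params))
}

#' Evaluate a hydrogen-bond feature on one frame
#'
#' For a native feature the value is
#' `s_native - lambda_w * (water competition on donor and acceptor)
#'  - lambda_p * (sum of switches to competing protein acceptors)`,
#' where `s_native` is the distance switch times the angular term.  The
#' value is ~1 for an ideal native geometry with no competitors, ~0 when
#' the contact is absent, and negative when a competing (non-native)
#' interaction has replaced it.  Non-native features evaluate to the bare
#' `s_native` of their own contact.  Bounded above by 1.
#'
#' @param f An `fcv_hbond_feature`.
#' @param frame An `fcv_frame`.
#' @param top The matching `fcv_topology`.
#' @return Scalar feature value.
#' @export
evaluate_hbond_feature <- function(f, frame, top) {
  .check_frame(frame, top)
  traj <- new_trajectory(top, array(frame$xyz, dim = c(nrow(frame$xyz), 3, 1)),
                         time = frame$time,
                         box = if (is.null(frame$box)) NULL else matrix(frame$box, 1, 3))
  .eval_hb_frames(f, traj)[1]
}

## 3 x nframes coordinate series of one atom (0-based index)
.atom_series <- function(traj, i0) {
  matrix(traj$coords[i0 + 1L, , ], nrow = 3)
}

## Vectorised evaluation of a hydrogen-bond feature over all frames.
.eval_hb_frames <- function(f, traj) {
  top <- traj$topology
  if (max(f$donor, f$hydrogen, f$acceptor, f$competitors, -1L) + 1L > top$n_atoms)
    .stopf("feature atom index out of range for topology")
  box <- traj$box
  D <- .atom_series(traj, f$donor)
  H <- .atom_series(traj, f$hydrogen)
  A <- .atom_series(traj, f$acceptor)
  s_nat <- rational_switch(.pbc_dist_frames(D, A, box), f$dist_switch) *
    .angular_frames(D, H, A, f$ang_switch)
  if (f$kind == "non-native") return(s_nat)
  val <- s_nat
  if (f$lambda_w != 0) {
    wo <- which(top$atoms$is_water & top$atoms$element == "O") - 1L
    if (length(wo) > 0L) {
      wc <- 0
      for (w in wo) {
        W <- .atom_series(traj, w)
        wc <- wc + rational_switch(.pbc_dist_frames(D, W, box), f$water_switch) +
          rational_switch(.pbc_dist_frames(A, W, box), f$water_switch)
      }
      val <- val - f$lambda_w * wc
    }
  }
  if (f$lambda_p != 0 && length(f$competitors) > 0L) {
    cp <- 0
    for (cc in f$competitors) {
      C <- .atom_series(traj, cc)
      cp <- cp + rational_switch(.pbc_dist_frames(D, C, box), f$dist_switch)
    }
    val <- val - f$lambda_p * cp
  }
  val
}
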