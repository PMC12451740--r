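#' Specification of a synthetic two-state peptide fixture
#'
#' The fixture is a small poly-peptide (alanine-like residues with a
#' glycine, hydrogens included) in explicit water, built geometrically in
#' two reference conformations: a "folded" hairpin-like frame in which
#' every planted native contact has ideal geometry, and a "misfolded"
#' frame in which the planted non-native contacts are satisfied instead.
#' Trajectories are reference frames plus isotropic Gaussian coordinate
#' noise, optionally switching basins as a two-state telegraph (Markov)
#' process with known stationary populations, so featurization, feature
#' selection and the thermodynamic estimators can all be validated against
#' planted ground truth with no external data.
#'
#' Planted hydrogen bonds are `(donor_residue, acceptor_residue)` pairs
#' (0-based): the backbone N-H of the donor residue donates to the
#' backbone O of the acceptor residue at D-A = 2.85 Angstrom, collinear
#' D-H...A.  Planted side-chain contacts place the two side-chain centers
#' of mass at 0.8 * r0 of the side-chain switch.  Waters sit in a slab at
#' least 4 Angstrom from the protein, except designated bridging waters.
#'
#' @param n_residues Number of residues (default 6; residue 2 is glycine).
#' @param n_waters Number of water molecules (default 30).
#' @param native_hb,native_sc Planted native contacts (lists of 0-based
#'   residue index pairs; defaults `(4,0), (5,1)` and `(0,5)`).
#' @param nonnative_hb,nonnative_sc Planted misfold contacts satisfied
#'   only in the misfolded frame (defaults `(3,0)` and `(0,3)`).
#' @param p_fold Stationary folded probability of the telegraph process
#'   (0 < p_fold < 1; default 0.5).
#' @param sigma Isotropic coordinate noise, Angstrom (default 0.05: small
#'   relative to the switch widths, so planted contacts stay committed).
#' @param n_frames Frames per sampled trajectory (default 200).
#' @param dt_ps Frame spacing in ps (default 100).
#' @param flip_rate Total per-frame flip probability scale of the
#'   telegraph process (default 0.02; mean dwell ~ 1/flip_rate frames).
#' @param box Cubic box edge, Angstrom (default 40).
#' @param bridging_waters List of `list(residue=, atom=)` entries; the
#'   corresponding waters are placed 2.9 Angstrom from that atom in both
#'   reference frames instead of in the bulk slab.
#' @param seed RNG seed for [sample_trajectory()] (default 42).
#' @return A list of class `fcv_fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 6L, n_waters = 30L,
                         native_hb = list(c(4L, 0L), c(5L, 1L)),
                         native_sc = list(c(0L, 5L)),
                         nonnative_hb = list(c(3L, 0L)),
                         nonnative_sc = list(c(0L, 3L)),
                         p_fold = 0.5, sigma = 0.05,
                         n_frames = 200L, dt_ps = 100, flip_rate = 0.02,
                         box = 40, bridging_waters = list(), seed = 42L) {
  if (!(p_fold > 0 && p_fold < 1)) .stopf("p_fold must lie strictly between 0 and 1")
  if (sigma < 0) .stopf("sigma must be non-negative")
  allres <- unlist(c(native_hb, native_sc, nonnative_hb, nonnative_sc))
  if (length(allres) && (min(allres) < 0 || max(allres) >= n_residues))
    .stopf("planted contact lists reference residues outside 0..%d", n_residues - 1L)
  structure(list(
    n_residues = as.integer(n_residues), n_waters = as.integer(n_waters),
    native_hb = native_hb, native_sc = native_sc,
    nonnative_hb = nonnative_hb, nonnative_sc = nonnative_sc,
    p_fold = p_fold, sigma = sigma, n_frames = as.integer(n_frames),
    dt_ps = dt_ps, flip_rate = flip_rate, box = box,
    bridging_waters = bridging_waters, seed = as.integer(seed)
  ), class = "fcv_fixture_spec")
}

## residue template, Angstrom, bond lengths chemically plausible
.res_template <- function(resname) {
  base <- list(
    N = c(0, 0, 0), H = c(0, 0, 1.00), CA = c(1.46, 0, 0),
    C = c(2.20, 1.25, 0), O = c(2.20, 2.48, 0)
  )
  if (resname == "GLY") {
    base$HA2 <- c(1.75, -0.95, -0.45); base$HA3 <- c(1.75, -0.95, 0.45)
  } else {
    base$HA <- c(1.75, -0.95, -0.45)
    base$CB <- c(1.96, -1.30, 0.60)
    base$HB1 <- c(1.55, -2.20, 0.30); base$HB2 <- c(2.90, -1.45, 0.95)
    base$HB3 <- c(1.40, -1.10, 1.45)
  }
  base
}

#' Build the fixture topology and its two reference frames
#'
#' Constructs the peptide-in-water system of a [fixture_spec()]:
#' a topology plus a folded and a misfolded reference frame.  In the
#' folded frame every planted native hydrogen bond has ideal geometry
#' (D-A = 2.85 Angstrom, collinear) and every planted native side-chain
#' pair sits at 0.8 * r0; in the misfolded frame the planted non-native
#' contacts are satisfied instead and the native ones are broken.  Output
#' is deterministic (no randomness is used here).
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fcv_fixture` with elements `topology`,
#'   `folded`, `misfolded` (frames), and `spec`.
#' @export
make_topology <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fcv_fixture_spec"))
  nres <- spec$n_residues
  seqnames <- rep("ALA", nres)
  if (nres >= 3L) seqnames[3] <- "GLY"

  ## residue placement: folded = antiparallel hairpin, misfolded = parallel
  half <- ceiling(nres / 2)
  offset_folded <- function(r) {
    if (r < half) c(r * 4.8, 0, 0) else c((nres - 1 - r) * 4.8, 8.0, 0)
  }
  offset_misfolded <- function(r) {
    if (r < half) c(r * 4.8, 0, 0) else c((r - half) * 4.8, 8.0, 0)
  }

  name <- character(0); resid <- integer(0); resname <- character(0)
  xyzF <- NULL; xyzM <- NULL
  atom_row <- new.env(parent = emptyenv())  # "res|name" -> row
  for (r in seq_len(nres) - 1L) {
    tpl <- .res_template(seqnames[r + 1L])
    for (an in names(tpl)) {
      name <- c(name, an); resid <- c(resid, r); resname <- c(resname, seqnames[r + 1L])
      xyzF <- rbind(xyzF, tpl[[an]] + offset_folded(r))
      xyzM <- rbind(xyzM, tpl[[an]] + offset_misfolded(r))
      assign(sprintf("%d|%s", r, an), length(name), envir = atom_row)
    }
  }
  n_protein <- length(name)
  row_of <- function(r, an) {
    key <- sprintf("%d|%s", r, an)
    if (!exists(key, envir = atom_row)) .stopf("fixture residue %d has no atom %s", r, an)
    get(key, envir = atom_row)
  }

  ## plant hydrogen bonds: move the acceptor residue's backbone O onto the
  ## donor's N-H axis at H + 1.85 A (D-A = 2.85 A, collinear D-H...A)
  plant_hb <- function(xyz, pairs) {
    used <- integer(0)
    for (p in pairs) {
      dres <- p[1]; ares <- p[2]
      if (abs(dres - ares) < 2L) .stopf("planted hydrogen bond (%d,%d) violates sequence separation", dres, ares)
      orow <- row_of(ares, "O")
      if (orow %in% used)
        .stopf("over-constrained fixture: acceptor O of residue %d used by two hydrogen bonds", ares)
      used <- c(used, orow)
      nN <- xyz[row_of(dres, "N"), ]; nH <- xyz[row_of(dres, "H"), ]
      u <- (nH - nN) / sqrt(sum((nH - nN)^2))
      xyz[orow, ] <- nH + 1.85 * u
    }
    xyz
  }

  ## plant side-chain contacts: rigidly translate residue j's side chain so
  ## the two side-chain COMs sit at 0.8 * r0 of the default SC switch
  plant_sc <- function(xyz, pairs) {
    r0 <- sc_switch_params()$r0
    for (p in pairs) {
      i <- p[1]; j <- p[2]
      if (abs(i - j) < 2L) .stopf("planted side-chain contact (%d,%d) violates sequence separation", i, j)
      sc_i <- .sc_rows(name, resid, resname, i)
      sc_j <- .sc_rows(name, resid, resname, j)
      wi <- .mass_of(.element_from_name(name[sc_i]))
      wj <- .mass_of(.element_from_name(name[sc_j]))
      ci <- colSums(xyz[sc_i, , drop = FALSE] * wi) / sum(wi)
      cj <- colSums(xyz[sc_j, , drop = FALSE] * wj) / sum(wj)
      dir <- cj - ci
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-6) dir <- c(0, 0, 1) else dir <- dir / nd
      shift <- (ci + 0.8 * r0 * dir) - cj
      xyz[sc_j, ] <- sweep(xyz[sc_j, , drop = FALSE], 2, shift, `+`)
    }
    xyz
  }

  xyzF <- plant_hb(xyzF, spec$native_hb)
  xyzF <- plant_sc(xyzF, spec$native_sc)
  xyzM <- plant_hb(xyzM, spec$nonnative_hb)
  xyzM <- plant_sc(xyzM, spec$nonnative_sc)

  ## waters: rigid 3-site molecules on a deterministic grid in a slab at
  ## least 4 A above the protein (protein z extent is about -2.2..+2.9 A)
  woff <- list(OW = c(0, 0, 0), HW1 = c(0.96, 0, 0), HW2 = c(-0.24, 0.93, 0))
  grid <- .water_grid(spec$n_waters, spec$box)
  bridged <- rep(FALSE, spec$n_waters)
  if (length(spec$bridging_waters) > 0L) {
    if (length(spec$bridging_waters) > spec$n_waters)
      .stopf("more bridging waters requested than waters in the system")
    for (k in seq_along(spec$bridging_waters)) bridged[k] <- TRUE
  }
  wxyzF <- NULL; wxyzM <- NULL
  for (w in seq_len(spec$n_waters)) {
    if (bridged[w]) {
      bw <- spec$bridging_waters[[w]]
      tgtF <- xyzF[row_of(bw$residue, bw$atom), ] + c(0, 0, 2.9)
      tgtM <- xyzM[row_of(bw$residue, bw$atom), ] + c(0, 0, 2.9)
    } else {
      tgtF <- tgtM <- grid[w, ]
    }
    for (an in names(woff)) {
      name <- c(name, an); resid <- c(resid, nres + w - 1L); resname <- c(resname, "SOL")
      wxyzF <- rbind(wxyzF, tgtF + woff[[an]])
      wxyzM <- rbind(wxyzM, tgtM + woff[[an]])
    }
  }
  if (spec$n_waters > 0L) { xyzF <- rbind(xyzF, wxyzF); xyzM <- rbind(xyzM, wxyzM) }

  top <- new_topology(data.frame(name = name, resid = resid, resname = resname,
                                 stringsAsFactors = FALSE))
  ## shift everything into the box interior
  shift <- c(10, 10, 10)
  xyzF <- sweep(xyzF, 2, shift, `+`); xyzM <- sweep(xyzM, 2, shift, `+`)
  box <- rep(spec$box, 3)
  fixture <- list(topology = top,
                  folded = new_frame(xyzF, box = box, time = 0),
                  misfolded = new_frame(xyzM, box = box, time = 0),
                  spec = spec, n_protein_atoms = n_protein)
  class(fixture) <- "fcv_fixture"
  attr(fixture$topology, "frame") <- fixture$folded
  fixture
}

.sc_rows <- function(name, resid, resname, r) {
  rows <- which(resid == r & !(name %in% .backbone_names))
  if (length(rows) == 0L) rows <- which(resid == r & name == "CA")
  rows
}

## deterministic grid in the water slab z in [18, 30] (box-interior coords)
.water_grid <- function(n, box) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  per <- ceiling(n^(1 / 3))
  pts <- as.matrix(expand.grid(x = seq_len(per), y = seq_len(per), z = seq_len(per)))
  pts <- pts[seq_len(n), , drop = FALSE]
  cbind(-6 + pts[, 1] * 3.1, -6 + pts[, 2] * 3.1, 8 + pts[, 3] * 3.1)
}

#' @export
print.fcv_fixture <- function(x, ...) {
  cat(sprintf("<fcv_fixture> %d residues + %d waters (%d atoms), box %g A\n",
              x$spec$n_residues, x$spec$n_waters, x$topology$n_atoms, x$spec$box))
  invisible(x)
}

#' Sample a synthetic trajectory from a fixture
#'
#' Frames are the basin's reference frame plus isotropic Gaussian noise of
#' standard deviation `sigma` per coordinate.  Bulk water positions are
#' resampled uniformly within the water slab in every frame (so water
#' identities carry no information and permutation invariance is
#' exercised); bridging waters stay at their planted positions plus noise.
#' In `"telegraph"` mode the basin switches as a two-state Markov chain
#' with stationary folded probability `p_fold`, so the ground-truth
#' folding free energy is `-kB T log(p_fold / (1 - p_fold))`.
#'
#' @param spec A [fixture_spec()]; all randomness is driven by its `seed`.
#' @param basin `"folded"`, `"unfolded"` (misfolded reference), or
#'   `"telegraph"`.
#' @param fixture Optionally a pre-built [make_topology()] result.
#' @param n_frames Override of `spec$n_frames`.
#' @return An `fcv_trajectory`; the per-frame ground-truth labels are
#'   attached as `attr(traj, "labels")` (factor with levels `folded`,
#'   `unfolded`).
#' @export
sample_trajectory <- function(spec = fixture_spec(),
                              basin = c("folded", "unfolded", "telegraph"),
                              fixture = NULL, n_frames = NULL) {
  basin <- match.arg(basin)
  if (is.null(fixture)) fixture <- make_topology(spec)
  nf <- as.integer(n_frames %||% spec$n_frames)
  top <- fixture$topology
  n <- top$n_atoms

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  labels <- switch(basin,
    folded = rep("folded", nf),
    unfolded = rep("unfolded", nf),
    telegraph = {
      a <- spec$flip_rate * spec$p_fold        # unfolded -> folded
      b <- spec$flip_rate * (1 - spec$p_fold)  # folded -> unfolded
      st <- character(nf)
      st[1] <- if (stats::runif(1) < spec$p_fold) "folded" else "unfolded"
      u <- stats::runif(nf)
      for (t in seq_len(nf - 1L)) {
        st[t + 1L] <- if (st[t] == "folded") {
          if (u[t] < b) "unfolded" else "folded"
        } else {
          if (u[t] < a) "folded" else "unfolded"
        }
      }
      st
    })
  foldv <- as.numeric(labels == "folded")

  coords <- array(stats::rnorm(n * 3 * nf, sd = spec$sigma), dim = c(n, 3, nf))
  bf <- fixture$folded$xyz; bm <- fixture$misfolded$xyz
  for (k in 1:3)
    coords[, k, ] <- coords[, k, ] + outer(bf[, k], foldv) + outer(bm[, k], 1 - foldv)

  ## resample bulk waters uniformly in the slab, every frame
  if (spec$n_waters > 0L) {
    woff <- rbind(OW = c(0, 0, 0), HW1 = c(0.96, 0, 0), HW2 = c(-0.24, 0.93, 0))
    n_bridge <- length(spec$bridging_waters)
    for (w in seq_len(spec$n_waters)) {
      if (w <= n_bridge) next  # bridging waters stay planted (base + noise)
      orow <- fixture$n_protein_atoms + (w - 1L) * 3L + 1L
      pos <- cbind(stats::runif(nf, 6, 34), stats::runif(nf, 6, 34), stats::runif(nf, 26, 38))
      for (s in 1:3) for (k in 1:3)
        coords[orow + s - 1L, k, ] <- pos[, k] + woff[s, k]
    }
  }

  traj <- new_trajectory(top, coords, time = spec$dt_ps * (seq_len(nf) - 1L),
                         box = rep(spec$box, 3))
  attr(traj, "labels") <- factor(labels, levels = c("folded", "unfolded"))
  attr(traj, "source") <- sprintf("synthetic:%s(seed=%d)", basin, spec$seed)
  traj
}
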