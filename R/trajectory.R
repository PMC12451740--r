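#' Construct a trajectory object
#'
#' @param top An `fcv_topology`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param time Numeric vector of frame times (ps), strictly increasing.
#' @param box `NULL`, or an `n_frames x 3` matrix (or length-3 vector,
#'   recycled) of orthorhombic box edges in Angstrom.
#' @return An object of class `fcv_trajectory`.
#' @export
new_trajectory <- function(top, coords, time = NULL, box = NULL) {
  stopifnot(inherits(top, "fcv_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    .stopf("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != top$n_atoms)
    .stopf("trajectory has %d atoms but topology has %d", dim(coords)[1], top$n_atoms)
  nf <- dim(coords)[3]
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  if (length(time) != nf) .stopf("time vector length does not match frame count")
  if (nf > 1 && any(diff(time) <= 0)) .stopf("frame times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    if (nrow(box) != nf || ncol(box) != 3) .stopf("box must be n_frames x 3")
    if (any(box <= 0)) .stopf("box lengths must be strictly positive")
  }
  structure(list(topology = top, coords = coords, time = as.numeric(time), box = box),
            class = "fcv_trajectory")
}

#' Number of frames in a trajectory
#' @param traj An `fcv_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj An `fcv_trajectory`.
#' @param i Frame index (1-based, R convention).
#' @return An `fcv_frame`.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1 || i > nf) .stopf("frame index %d out of range 1..%d", i, nf)
  new_frame(traj$coords[, , i, drop = TRUE],
            box = if (is.null(traj$box)) NULL else traj$box[i, ],
            time = traj$time[i])
}

#' @export
print.fcv_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("<fcv_trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              nf, dim(x$coords)[1], x$time[1], x$time[nf]))
  invisible(x)
}

#' Read a trajectory from a multi-frame PDB or DCD file
#'
#' Frames are returned in file order with coordinates in Angstrom.  For PDB
#' input each `MODEL` block is one frame; single-model PDB files yield a
#' one-frame trajectory.  DCD files (CHARMM/NAMD binary, Angstrom) are read
#' through bio3d.  XTC is not supported; convert to DCD or multi-frame PDB
#' upstream.
#'
#' @param path Path to the trajectory file.
#' @param top The matching `fcv_topology` (atom counts must agree).
#' @param dt Frame spacing in ps used when the format carries no time
#'   information (default 1 ps).
#' @return An `fcv_trajectory`.
#' @export
read_trajectory <- function(path, top, dt = 1) {
  if (!file.exists(path)) .stopf("cannot read trajectory file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- matrix(xyz, nrow = nrow(xyz))
    box <- NULL
  } else if (ext == "gro") {
    t2 <- .read_gro(path)
    fr <- attr(t2, "frame")
    if (t2$n_atoms != top$n_atoms)
      .stopf("trajectory has %d atoms but topology has %d", t2$n_atoms, top$n_atoms)
    return(new_trajectory(top, array(fr$xyz, dim = c(top$n_atoms, 3, 1)),
                          time = 0,
                          box = if (is.null(fr$box)) NULL else matrix(fr$box, 1, 3)))
  } else if (ext == "xtc") {
    .stopf("XTC reading is not supported; convert to DCD or multi-frame PDB")
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    box <- .pdb_box(path)
  }
  natom <- ncol(xyz) / 3
  if (natom != top$n_atoms)
    .stopf("trajectory has %d atoms but topology has %d", natom, top$n_atoms)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(top$n_atoms, 3, nf))
  for (i in seq_len(nf)) coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  new_trajectory(top, coords, time = dt * (seq_len(nf) - 1),
                 box = if (is.null(box)) NULL else matrix(box, nf, 3, byrow = TRUE))
}
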