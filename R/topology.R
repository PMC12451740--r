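#' Construct a topology object
#'
#' A topology holds per-atom metadata for a molecular system: atom names,
#' inferred elements, 0-based residue indices, residue names, chain ids,
#' protein/water/heavy-atom flags, and masses (amu).  Coordinates live in
#' separate frames/trajectories ([read_trajectory()]).
#'
#' @param atoms A data frame with columns `name`, `resid` (0-based integer
#'   residue index), `resname`, and optionally `chain` and `element`.
#'   Elements are inferred from atom names when absent.
#' @return An object of class `fcv_topology` whose `$atoms` data frame
#'   additionally carries `element`, `is_protein`, `is_water`, `is_heavy`,
#'   and `mass` columns.  Atom indices are implicit row positions, 0-based
#'   when referenced by feature definitions.
#' @export
new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(c("name", "resid", "resname") %in% names(atoms)))
  if (nrow(atoms) == 0L) .stopf("topology has zero atoms")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  atoms$name <- trimws(atoms$name)
  atoms$resid <- as.integer(atoms$resid)
  if (anyNA(atoms$resid)) .stopf("topology has atoms without a residue")
  atoms$is_water <- toupper(atoms$resname) %in% .water_resnames
  atoms$is_protein <- !atoms$is_water
  atoms$is_heavy <- atoms$element != "H"
  atoms$mass <- .mass_of(atoms$element)
  top <- structure(
    list(atoms = atoms, n_atoms = nrow(atoms)),
    class = "fcv_topology"
  )
  top
}

#' @export
print.fcv_topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<fcv_topology> %d atoms, %d residues (%d protein atoms, %d water molecules)\n",
    nrow(a), length(unique(a$resid)), sum(a$is_protein),
    sum(a$is_water & a$element == "O")
  ))
  invisible(x)
}

#' Read a topology from a PDB or GRO file
#'
#' Protein/water flags are assigned from residue names (water: HOH, SOL,
#' WAT, TIP3, ...).  Hydrogens are retained.  Coordinates present in the
#' file are returned as the `frame` attribute (Angstrom; GRO input in nm is
#' converted).
#'
#' @param path Path to a readable `.pdb` or `.gro` file.
#' @return An `fcv_topology`.  The first set of coordinates in the file is
#'   attached as `attr(top, "frame")`, an [new_frame()] object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) .stopf("cannot read topology file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(.read_gro(path))
  .read_pdb_topology(path)
}

.read_pdb_topology <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) .stopf("not a readable PDB file: '%s' (%s)", path, conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) .stopf("PDB file '%s' contains zero atoms", path)
  resid0 <- .resid_runs(paste(a$chain, a$resno, a$insert, sep = "|"))
  atoms <- data.frame(
    name = a$elety, resid = resid0, resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    stringsAsFactors = FALSE
  )
  top <- new_topology(atoms)
  xyz <- cbind(a$x, a$y, a$z)
  attr(top, "frame") <- new_frame(xyz, box = .pdb_box(path), time = 0)
  top
}

## Map arbitrary residue keys (in file order) to contiguous 0-based indices.
.resid_runs <- function(key) {
  r <- rle(key)
  rep.int(seq_along(r$lengths) - 1L, r$lengths)
}

## Extract an orthorhombic box from a CRYST1 record, if any.
.pdb_box <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(NULL)
  v <- suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33)
  )))
  if (anyNA(v) || any(v <= 0) || all(v == 1)) return(NULL)  # CRYST1 1 1 1 = no box
  v
}

## GRO fixed-width format (nm): resid(5) resname(5) name(5) serial(5)
## x(8.3) y(8.3) z(8.3); last line is the box.
.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) .stopf("GRO file '%s' is truncated", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0L) .stopf("GRO file '%s': bad atom count line", path)
  if (length(lines) < 2L + n + 1L) .stopf("GRO file '%s' is truncated", path)
  rec <- lines[3:(2 + n)]
  atoms <- data.frame(
    name = trimws(substr(rec, 11, 15)),
    resid = NA_integer_,
    resname = trimws(substr(rec, 6, 10)),
    chain = "A",
    stringsAsFactors = FALSE
  )
  reskey <- paste0(trimws(substr(rec, 1, 5)), "|", atoms$resname)
  atoms$resid <- .resid_runs(reskey)
  xyz <- 10 * cbind(  # nm -> Angstrom
    as.numeric(substr(rec, 21, 28)),
    as.numeric(substr(rec, 29, 36)),
    as.numeric(substr(rec, 37, 44))
  )
  if (anyNA(xyz)) .stopf("GRO file '%s': malformed coordinate fields", path)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n + 1]), "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && !anyNA(boxv[1:3]) && all(boxv[1:3] > 0)) 10 * boxv[1:3] else NULL
  top <- new_topology(atoms)
  attr(top, "frame") <- new_frame(xyz, box = box, time = 0)
  top
}

#' Construct a single coordinate frame
#'
#' @param xyz Numeric `n_atoms x 3` matrix of coordinates (Angstrom).
#' @param box Length-3 numeric of orthorhombic box edges (Angstrom), or
#'   `NULL` for a non-periodic system.
#' @param time Frame time in ps.
#' @return An object of class `fcv_frame`.
#' @export
new_frame <- function(xyz, box = NULL, time = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, is.numeric(xyz))
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0)) .stopf("box lengths must be 3 strictly positive values")
  }
  structure(list(xyz = xyz, box = box, time = as.numeric(time)), class = "fcv_frame")
}

#' @export
print.fcv_frame <- function(x, ...) {
  cat(sprintf("<fcv_frame> %d atoms, t = %g ps, box = %s\n", nrow(x$xyz), x$time,
              if (is.null(x$box)) "none" else paste(signif(x$box, 5), collapse = " x ")))
  invisible(x)
}

## internal validity check used by feature evaluation
.check_frame <- function(frame, top) {
  if (nrow(frame$xyz) != top$n_atoms)
    .stopf("frame has %d atoms but topology has %d", nrow(frame$xyz), top$n_atoms)
  invisible(TRUE)
}

#' Write a topology + frame as a PDB file
#'
#' Atom serials are 1-based in the emitted file (internal indices are
#' 0-based).  A `CRYST1` record is written when the frame has a box.
#'
#' @param top An `fcv_topology`.
#' @param frame An `fcv_frame` (or a trajectory, in which case all frames
#'   are written as `MODEL`/`ENDMDL` blocks).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(top, frame, path) {
  if (inherits(frame, "fcv_trajectory")) {
    frames <- lapply(seq_len(n_frames(frame)), function(i) get_frame(frame, i))
  } else {
    frames <- list(frame)
  }
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  a <- top$atoms
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    .check_frame(frames[[m]], top)
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]$xyz
    name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4), sprintf(" %-3s", a$name))
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      (seq_len(nrow(a)) - 1L) %% 99999L + 1L, name4, substr(a$resname, 1, 4),
      substr(a$chain, 1, 1), a$resid %% 9999L + 1L,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element
    ), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a topology + frame as a GRO file (nm)
#'
#' Internal Angstrom coordinates are converted to nm on output.
#'
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_gro <- function(top, frame, path) {
  .check_frame(frame, top)
  a <- top$atoms
  xyz <- frame$xyz / 10
  lines <- c(
    "foldcv generated",
    sprintf("%5d", nrow(a)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$resid %% 99999L + 1L, substr(a$resname, 1, 5), substr(a$name, 1, 5),
            (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    if (is.null(frame$box)) "   0.00000   0.00000   0.00000"
    else sprintf("%10.5f%10.5f%10.5f", frame$box[1] / 10, frame$box[2] / 10, frame$box[3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}
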