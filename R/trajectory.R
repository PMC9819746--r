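# Trajectory container + DCD/PDB I/O. DCD reading goes through bio3d; the
# CHARMM-format DCD writer is implemented here (no installed R package writes
# DCD). Coordinates are nm internally; DCD and PDB store Angstrom.

#' Construct an in-memory trajectory
#'
#' @param topology an `lu_topology`.
#' @param coords numeric array `natoms x 3 x nframes`, in nm.
#' @param time_ps per-frame times (ps), strictly increasing.
#' @param box per-frame box dimensions, `nframes x 3` matrix or length-3
#'   vector recycled to all frames (nm).
#' @return object of class `lu_trajectory`.
#' @export
trajectory <- function(topology, coords, time_ps = NULL, box = NULL) {
  stopifnot(inherits(topology, "lu_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be a natoms x 3 x nframes array")
  }
  if (dim(coords)[1] != topology$natoms) {
    stop("coordinate array has ", dim(coords)[1], " atoms but topology has ",
         topology$natoms)
  }
  nf <- dim(coords)[3]
  if (nf < 1) stop("trajectory needs at least one frame")
  if (is.null(time_ps)) time_ps <- as.numeric(seq_len(nf) - 1)
  if (length(time_ps) != nf) stop("time_ps length must equal frame count")
  if (nf > 1 && any(diff(time_ps) <= 0)) stop("frame times must be strictly increasing")
  if (is.null(box)) box <- matrix(0, nf, 3)
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  structure(list(topology = topology, coords = coords,
                 time_ps = as.numeric(time_ps), box = box, nframes = nf),
            class = "lu_trajectory")
}

#' @export
print.lu_trajectory <- function(x, ...) {
  cat("lu_trajectory:", x$nframes, "frames x", x$topology$natoms, "atoms, ",
      sprintf("t = %g..%g ps\n", x$time_ps[1], x$time_ps[x$nframes]))
  invisible(x)
}

#' Number of frames
#' @param traj an `lu_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) traj$nframes

#' Extract one frame's coordinates
#' @param traj an `lu_trajectory`.
#' @param i frame index (1-based).
#' @return `natoms x 3` matrix (nm).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Load a coordinate trajectory for a topology
#'
#' Reads a DCD trajectory (binary, CHARMM/NAMD flavour, via bio3d) or a
#' ground-truth-style TSV written by the synthetic generator. DCD coordinates
#' (Angstrom) are converted to nm on load. Every `stride`-th frame is kept.
#'
#' @param topology an `lu_topology`; the file's atom count must match.
#' @param path trajectory file path (`.dcd`).
#' @param stride keep every `stride`-th frame (>= 1).
#' @param dt_ps time between stored frames in the file (ps), used to
#'   synthesise per-frame times.
#' @return an `lu_trajectory`.
#' @export
load_trajectory <- function(topology, path, stride = 1L, dt_ps = 1) {
  stopifnot(inherits(topology, "lu_topology"))
  if (!file.exists(path)) stop("file not found: ", path)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nat_file <- ncol(xyz) / 3
  if (nat_file != topology$natoms) {
    stop("atom-count mismatch: trajectory has ", nat_file,
         " atoms, topology has ", topology$natoms)
  }
  keep <- seq(1, nrow(xyz), by = stride)
  nf <- length(keep)
  coords <- array(0, c(topology$natoms, 3, nf))
  for (k in seq_along(keep)) {
    coords[, , k] <- matrix(xyz[keep[k], ], ncol = 3, byrow = TRUE) / 10
  }
  trajectory(topology, coords,
             time_ps = (keep - 1) * dt_ps)
}

#' Write a trajectory to a DCD file
#'
#' Writes the CHARMM-flavour binary DCD format (single precision, no unit
#' cell). Coordinates are converted from nm to Angstrom.
#'
#' @param traj an `lu_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "lu_trajectory"))
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- traj$nframes
  nat <- traj$topology$natoms
  int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record: "CORD" + 20 control integers (icntrl)
  int(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf          # NSET
  icntrl[2] <- 1           # ISTART
  icntrl[3] <- 1           # NSAVC
  icntrl[4] <- nf          # NSTEP
  icntrl[20] <- 24         # CHARMM version stamp
  # icntrl[10] is DELTA as a float bit pattern; leave 0 (times live elsewhere)
  int(icntrl)
  int(84)
  # title record
  title <- sprintf("%-80s", "written by luorient")
  int(4 + 80)
  int(1)
  writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  int(4 + 80)
  # atom-count record
  int(4)
  int(nat)
  int(4)
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k] * 10  # nm -> Angstrom
    for (d in 1:3) {
      int(4 * nat)
      writeBin(as.numeric(xyz[, d]), con, size = 4, endian = "little")
      int(4 * nat)
    }
  }
  invisible(path)
}

#' Write a topology (+ one frame) to a PDB file
#'
#' @param topology an `lu_topology`.
#' @param xyz `natoms x 3` coordinates in nm.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_topology <- function(topology, xyz, path) {
  stopifnot(inherits(topology, "lu_topology"))
  at <- topology$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz * 10)),
                   type = "ATOM",
                   resno = at$resno, resid = at$resname,
                   elety = at$name, chain = at$chain,
                   elesy = at$elem)
  invisible(path)
}

# Unwrap a molecule across periodic boundaries: every atom of `idx` is shifted
# by whole box vectors into the image nearest the group's first atom. Applied
# to the protein only; membrane atoms stay wrapped.
unwrap_group <- function(xyz, idx, box) {
  if (all(box <= 0)) return(xyz)
  ref <- xyz[idx[1], ]
  for (d in 1:3) {
    if (box[d] > 0) {
      shift <- round((xyz[idx, d] - ref[d]) / box[d])
      xyz[idx, d] <- xyz[idx, d] - shift * box[d]
    }
  }
  xyz
}
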