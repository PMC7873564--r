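# Heating-trajectory container and readers. Frames follow the bio3d xyz
# convention: an F x 3N matrix with columns (x1, y1, z1, x2, ...).

#' Heating trajectory
#'
#' @param xyz F x 3N coordinate matrix (Angstrom), one row per frame.
#' @param times frame times in ns, strictly increasing, length F.
#' @param resno residue index per atom (length N, non-decreasing).
#' @param schedule a [temperature_schedule()].
#' @param atom_names optional atom names (length N).
#' @return Object of class `heating_trajectory`.
#' @export
heating_trajectory <- function(xyz, times, resno, schedule, atom_names = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("a trajectory needs at least 2 frames")
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3N columns")
  n_atoms <- ncol(xyz) / 3L
  if (length(resno) != n_atoms) stop("resno must have one entry per atom")
  if (any(diff(resno) < 0L)) stop("residue indices must be non-decreasing")
  if (length(times) != nrow(xyz)) stop("times must have one entry per frame")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  stopifnot(inherits(schedule, "temperature_schedule"))
  structure(list(xyz = xyz, times = as.numeric(times),
                 resno = as.integer(resno), atom_names = atom_names,
                 schedule = schedule),
            class = "heating_trajectory")
}

#' @export
print.heating_trajectory <- function(x, ...) {
  cat(sprintf("<heating_trajectory> %d frames, %d atoms, t = %.3g-%.3g ns\n",
              nrow(x$xyz), ncol(x$xyz) / 3L, min(x$times), max(x$times)))
  invisible(x)
}

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a [heating_trajectory()].
#' @param frame frame index.
#' @return N x 3 matrix.
#' @export
frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Read a heating trajectory from a multi-model PDB file
#'
#' Frames are the MODEL records; residue indices come from the PDB
#' residue numbers. Frame times are taken from `times` (the PDB format
#' carries none).
#'
#' @param path multi-model PDB file.
#' @param times frame times in ns.
#' @param schedule a [temperature_schedule()].
#' @return A [heating_trajectory()].
#' @export
read_trajectory_pdb <- function(path, times, schedule) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  heating_trajectory(xyz, times, pdb$atom$resno, schedule,
                     atom_names = pdb$atom$elety)
}

#' Read a heating trajectory from a plain-text coordinate table
#'
#' Whitespace-delimited columns `frame`, `atom`, `x`, `y`, `z` (header
#' optional); atoms must appear in the same order in every frame.
#' Residue indices default to one residue per atom unless given.
#'
#' @param path table file.
#' @param times frame times in ns.
#' @param schedule a [temperature_schedule()].
#' @param resno optional residue index per atom.
#' @return A [heating_trajectory()].
#' @export
read_trajectory_table <- function(path, times, schedule, resno = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header)
  if (!has_header) names(tab) <- c("frame", "atom", "x", "y", "z")[seq_len(ncol(tab))]
  tab <- tab[order(tab$frame, tab$atom), ]
  frames <- unique(tab$frame)
  n_atoms <- sum(tab$frame == frames[1])
  if (nrow(tab) != n_atoms * length(frames)) {
    stop("every frame must list the same atoms")
  }
  xyz <- matrix(0, length(frames), 3L * n_atoms)
  for (k in seq_along(frames)) {
    sub <- tab[tab$frame == frames[k], ]
    xyz[k, ] <- as.numeric(t(as.matrix(sub[, c("x", "y", "z")])))
  }
  if (is.null(resno)) resno <- seq_len(n_atoms)
  heating_trajectory(xyz, times, resno, schedule)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj a [heating_trajectory()].
#' @param path output file.
#' @return Invisibly `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  n <- length(traj$resno)
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = traj$resno,
                   resid = rep("ALA", n),
                   elety = if (is.null(traj$atom_names)) rep("CA", n) else traj$atom_names,
                   chain = rep("A", n))
  invisible(path)
}
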