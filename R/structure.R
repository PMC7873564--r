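# Light-weight structure container: an atom table in the bio3d column
# dialect (chain, resno, resid, elety, elesy, x, y, z). PDB files go
# through bio3d for reading and writing.

#' Build a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`
#'   (residue name), `elety` (atom name), `x`, `y`, `z`, and optionally
#'   `elesy` (element symbol; inferred from the first letter of `elety`
#'   when absent).
#' @return Object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("coordinates must be finite")
  }
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1L, 1L)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, atom name) triple")
  rownames(atoms) <- NULL
  structure(list(atom = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- table(x$atom$chain)
  cat(sprintf("<structure3d> %d atoms, %d chains (%s)\n",
              nrow(x$atom), length(ch),
              paste(sprintf("%s:%d", names(ch), ch), collapse = ", ")))
  invisible(x)
}

#' Select atom indices of a structure
#'
#' @param s a [structure3d()].
#' @param chain chain id(s) to keep (NULL = all).
#' @param resno residue number(s) to keep (NULL = all).
#' @param heavy_only drop hydrogens.
#' @return Integer vector of atom row indices.
#' @export
str_select <- function(s, chain = NULL, resno = NULL, heavy_only = TRUE) {
  keep <- rep(TRUE, nrow(s$atom))
  if (!is.null(chain)) keep <- keep & s$atom$chain %in% chain
  if (!is.null(resno)) keep <- keep & s$atom$resno %in% resno
  if (heavy_only) keep <- keep & s$atom$elesy != "H"
  which(keep)
}

#' Coordinates of selected atoms
#' @param s a [structure3d()].
#' @param sel atom row indices (default all).
#' @return N x 3 coordinate matrix.
#' @export
atom_coords <- function(s, sel = seq_len(nrow(s$atom))) {
  as.matrix(s$atom[sel, c("x", "y", "z")])
}

#' Read a structure from a PDB file
#' @param path PDB file.
#' @return A [structure3d()].
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  structure3d(data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                         elety = a$elety, elesy = a$elesy,
                         x = a$x, y = a$y, z = a$z,
                         stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#' @param s a [structure3d()].
#' @param path output file.
#' @return Invisibly `path`.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atom
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain)
  invisible(path)
}

#' Parse a residue reference like "C:510"
#' @param ref string `"chain:resno"`, or a list `list(chain =, resno =)`.
#' @return List with `chain` and `resno`.
#' @export
parse_residue_ref <- function(ref) {
  if (is.list(ref)) return(list(chain = ref$chain, resno = as.integer(ref$resno)))
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop(sprintf("bad residue reference '%s'", ref))
  list(chain = parts[1], resno = as.integer(parts[2]))
}
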