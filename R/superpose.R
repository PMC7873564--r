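# Rigid-body least-squares superposition (Kabsch) and tiling of docked
# receptor placements across the subunits of a pentameric ligand disc.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Least-squares proper rotation (det = +1; reflections are never
#' produced) and translation taking `mobile` onto `target`. Points are
#' row vectors; the fitted transform maps `x` to `x %*% R + t`.
#'
#' @param mobile,target N x 3 matrices with matching rows (N >= 3,
#'   non-degenerate).
#' @return Object of class `rigid_transform`: `R` (3 x 3, det +1), `t`
#'   (length 3) and `rmsd` after transformation.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  if (max(abs(P)) < 1e-12 || qr(P)$rank < 2L) {
    stop("degenerate (coincident or collinear) point set")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- ct - as.vector(cm %*% R)
  moved <- mobile %*% R + rep(1, nrow(mobile)) %o% t_vec
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  structure(list(R = R, t = t_vec, rmsd = rmsd), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> det(R) = %+.3f, RMSD = %.4g A\n",
              det(x$R), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#' @param x N x 3 matrix or [structure3d()].
#' @param transform a [kabsch_superpose()] result.
#' @return Transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "structure3d")) {
    xyz <- atom_coords(x) %*% transform$R +
      rep(1, nrow(x$atom)) %o% transform$t
    x$atom$x <- xyz[, 1]; x$atom$y <- xyz[, 2]; x$atom$z <- xyz[, 3]
    return(x)
  }
  as.matrix(x) %*% transform$R + rep(1, nrow(x)) %o% transform$t
}

subunit_ca_coords <- function(s, chains) {
  idx <- unlist(lapply(chains, function(ch) {
    i <- str_select(s, chain = ch)
    i <- i[s$atom$elety[i] == "CA"]
    i[order(s$atom$resno[i])]
  }))
  list(idx = idx, xyz = atom_coords(s, idx))
}

#' Tile docked receptor placements over all pentamer subunits
#'
#' Given a ligand disc of two-chain subunits with a docked pair of
#' receptor domains on one subunit, superposes the source subunit's
#' Calpha set onto each of the other subunits (Kabsch) and carries the
#' receptor domains along, producing one placement per receptor per
#' subunit. Each placement is scored for steric clash (against all
#' ligand chains and the other placements) and for C-terminus
#' accessibility.
#'
#' @param s complex [structure3d()] holding the ligand chains and the
#'   docked receptor chains.
#' @param subunit_chains list of chain-id pairs, one per subunit, in
#'   matching residue order (e.g. `list(c("A","B"), c("C","D"), ...)`).
#' @param source_subunit index into `subunit_chains` of the subunit that
#'   carries the docked receptors.
#' @param receptor_chains chain ids of the docked receptor domains.
#' @param clash_min_dist clash threshold in Angstrom.
#' @param access_threshold C-terminus clearance threshold in Angstrom.
#' @return Object of class `placement_set`: a list `placements` (each
#'   with `subunit`, `receptor`, `transform`, `atoms`), logical vectors
#'   `clash` and `accessible`, and `accessible_count`.
#' @export
tile_pentamer <- function(s, subunit_chains, source_subunit = 1L,
                          receptor_chains, clash_min_dist = 2.5,
                          access_threshold = 8) {
  src <- subunit_ca_coords(s, subunit_chains[[source_subunit]])
  rec_atoms <- lapply(receptor_chains, function(ch) {
    s$atom[str_select(s, chain = ch, heavy_only = FALSE), , drop = FALSE]
  })
  placements <- list()
  for (k in seq_along(subunit_chains)) {
    if (k == source_subunit) {
      tr <- structure(list(R = diag(3), t = c(0, 0, 0), rmsd = 0),
                      class = "rigid_transform")
    } else {
      tgt <- subunit_ca_coords(s, subunit_chains[[k]])
      if (nrow(tgt$xyz) != nrow(src$xyz)) {
        stop(sprintf("subunit %d residue count differs from the source", k))
      }
      tr <- kabsch_superpose(src$xyz, tgt$xyz)
    }
    for (r in seq_along(rec_atoms)) {
      a <- rec_atoms[[r]]
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% tr$R +
        rep(1, nrow(a)) %o% tr$t
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      placements <- c(placements, list(list(
        subunit = k, receptor = receptor_chains[r],
        transform = tr, atoms = a)))
    }
  }
  lig_idx <- str_select(s, chain = unlist(subunit_chains))
  lig_xyz <- atom_coords(s, lig_idx)
  n_p <- length(placements)
  clash <- logical(n_p); accessible <- logical(n_p)
  for (p in seq_len(n_p)) {
    heavy <- placements[[p]]$atoms$elesy != "H"
    pxyz <- as.matrix(placements[[p]]$atoms[heavy, c("x", "y", "z")])
    hit <- clash_check(pxyz, lig_xyz, min_dist = clash_min_dist)$clash
    if (!hit) {
      for (q in seq_len(n_p)) {
        if (q == p) next
        hq <- placements[[q]]$atoms$elesy != "H"
        qxyz <- as.matrix(placements[[q]]$atoms[hq, c("x", "y", "z")])
        if (clash_check(pxyz, qxyz, min_dist = clash_min_dist)$clash) {
          hit <- TRUE; break
        }
      }
    }
    clash[p] <- hit
    accessible[p] <- placement_cterm_accessible(
      placements[[p]]$atoms, lig_xyz, threshold = access_threshold)
  }
  structure(list(placements = placements, clash = clash,
                 accessible = accessible & !clash,
                 accessible_count = sum(accessible & !clash)),
            class = "placement_set")
}

placement_cterm_accessible <- function(atoms, env_xyz, threshold = 8) {
  heavy <- atoms$elesy != "H"
  last_res <- max(atoms$resno)
  ct_rows <- which(atoms$resno == last_res & atoms$elety == "CA")
  if (length(ct_rows) == 0L) ct_rows <- which(atoms$resno == last_res)[1]
  ct <- as.numeric(atoms[ct_rows[1], c("x", "y", "z")])
  dmin <- min(sqrt(rowSums(sweep(env_xyz, 2L, ct)^2)))
  rec_cen <- colMeans(as.matrix(atoms[heavy, c("x", "y", "z")]))
  lig_cen <- colMeans(env_xyz)
  axis <- rec_cen - lig_cen
  dmin > threshold && sum((ct - rec_cen) * axis) >= 0
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf("<placement_set> %d placement(s): %d clash-free, %d accessible\n",
              length(x$placements), sum(!x$clash), x$accessible_count))
  invisible(x)
}

#' Fit the docking-score to affinity calibration line
#'
#' Least-squares line of log10(Ka) against docking score; predictions
#' return Ka on the original scale. At least two distinct scores are
#' required.
#'
#' @param scores docking scores.
#' @param Ka association constants (M^-1, > 0).
#' @return Object of class `affinity_calibration` with `slope`,
#'   `intercept` and the calibration points.
#' @export
fit_affinity_calibration <- function(scores, Ka) {
  stopifnot(length(scores) == length(Ka), all(Ka > 0))
  if (length(unique(scores)) < 2L) {
    stop("need at least 2 distinct scores to fit")
  }
  fit <- stats::lm(log10(Ka) ~ scores)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 points = data.frame(score = scores, Ka = Ka),
                 fit = fit),
            class = "affinity_calibration")
}

#' Predict Ka from a docking score
#' @param object an [fit_affinity_calibration()] result.
#' @param score docking score(s).
#' @param ... unused.
#' @return Predicted Ka (M^-1).
#' @export
predict.affinity_calibration <- function(object, score, ...) {
  10^(object$intercept + object$slope * score)
}

#' @export
print.affinity_calibration <- function(x, ...) {
  cat(sprintf("<affinity_calibration> log10(Ka) = %.4g + %.4g * score (%d points)\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}
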