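# Synthetic pentameric ligand discs with docked receptor-domain
# placements. The geometry is a C5-symmetric toy: each subunit is a
# homodimer of two chains (Calpha models) carrying analog residues for
# the interface vocabulary (Q510, E398, the N402 glycan, the Cmu3/Cmu4
# regions), with one receptor-domain placement per chain, one on each
# face of the disc. Modes produce geometry that provably satisfies or
# violates the docking constraints, as verified by the geometry module.

#' Parameters of the synthetic pentamer complex
#'
#' @param n_subunits subunits in the disc (default 5).
#' @param ring_radius subunit distance from the disc axis (A).
#' @param placement_mode `"good_pose"` (constraints satisfied),
#'   `"constraint_violating"` (receptors lifted off the interface),
#'   `"clashing"` (one subunit fused onto its neighbour) or
#'   `"buried_cterm"` (receptor C-termini turned toward the ligand).
#' @param seed mandatory RNG seed (kept for interface uniformity; the
#'   default geometry is deterministic).
#' @return List of class `pentamer_params`.
#' @export
pentamer_params <- function(n_subunits = 5L, ring_radius = 40,
                            placement_mode = c("good_pose", "constraint_violating",
                                               "clashing", "buried_cterm"),
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  placement_mode <- match.arg(placement_mode)
  if (n_subunits < 1L) stop("n_subunits must be >= 1")
  if (placement_mode == "clashing" && n_subunits < 3L) {
    stop("clashing mode needs at least 3 subunits")
  }
  structure(list(n_subunits = as.integer(n_subunits),
                 ring_radius = ring_radius,
                 placement_mode = placement_mode, seed = as.integer(seed)),
            class = "pentamer_params")
}

# local-frame geometry of one ligand chain (top face) and its receptor.
# Cmu3-analog residues 398-427, Cmu4-analog 496-525; the receptor
# carries the domain numbering of the residues it stands in for.
.pentamer_chain_local <- function(mode) {
  grid <- expand.grid(x = seq(-7.5, 7.5, by = 3), y = seq(-6, 6, by = 3))
  lig <- rbind(
    data.frame(resno = 398L, x = 0,    y = 3,  z = 7),
    data.frame(resno = 402L, x = -7.5, y = -6, z = 1),
    data.frame(resno = 509L, x = -3.2, y = 0,  z = 6),
    data.frame(resno = 510L, x = 0,    y = 0,  z = 6),
    data.frame(resno = 511L, x = 3.2,  y = 0,  z = 6),
    data.frame(resno = 512L, x = 0,    y = -3, z = 7))
  c3_fill <- setdiff(398:427, c(398L, 402L))
  slots3 <- grid[!(grid$x == -7.5 & grid$y == -6), ][seq_along(c3_fill), ]
  lig <- rbind(lig, data.frame(resno = c3_fill, x = slots3$x, y = slots3$y, z = 1))
  c4_fill <- setdiff(496:525, 509:512)
  slots4 <- grid[seq_along(c4_fill), ]
  lig <- rbind(lig, data.frame(resno = c4_fill, x = slots4$x, y = slots4$y, z = 4))

  scaffold <- c(20L, 24L, 28L, 32L, 36L, 50L, 58L, 75L, 90L, 98L, 104L, 112L, 116L)
  rec <- rbind(
    data.frame(resno = 66L,  x = -3.2, y = 0, z = 10),
    data.frame(resno = 83L,  x = 0,    y = 0, z = 10),
    data.frame(resno = 109L, x = 3.2,  y = 0, z = 10),
    data.frame(resno = scaffold, x = seq(-6, 6, length.out = length(scaffold)),
               y = 0, z = 13),
    data.frame(resno = 41L, x = -2, y = 0, z = 16),
    data.frame(resno = 42L, x = 0,  y = 0, z = 16),
    data.frame(resno = 81L, x = 2,  y = 0, z = 16),
    data.frame(resno = 124L, x = 0, y = 0,
               z = if (mode == "buried_cterm") 9.5 else 19))
  if (mode == "constraint_violating") rec$z <- rec$z + 25
  list(lig = lig[order(lig$resno), ], rec = rec[order(rec$resno), ])
}

.as_ca_atoms <- function(tab, chain) {
  data.frame(chain = chain, resno = tab$resno, resid = "ALA", elety = "CA",
             elesy = "C", x = tab$x, y = tab$y, z = tab$z,
             stringsAsFactors = FALSE)
}

.place_subunit <- function(tab, radius, angle) {
  x <- tab$x + radius
  ca <- cos(angle); sa <- sin(angle)
  out <- tab
  out$x <- ca * x - sa * tab$y
  out$y <- sa * x + ca * tab$y
  out
}

#' Generate a synthetic pentamer complex with receptor placements
#'
#' Builds a C5-arranged disc of two-chain subunits; in `good_pose` mode
#' each chain of the source subunit carries a receptor-domain placement
#' whose 66/83/109-analog residues touch that chain's 510-analog residue
#' (with more than 75 percent of contacts in the Cmu4-analog range, the
#' 41/42/81-analog residues out of contact, and the C-terminus pointing
#' away from the disc), one placement on each face.
#'
#' @param p a [pentamer_params()].
#' @return List with `structure` (a [structure3d()]), `pairing` (chain
#'   pairs per subunit), `source_subunit`, `receptor_chains`,
#'   `constraints` (a [dock_constraints()] resolving all analog
#'   residues, for the first receptor), `regions`, and `ground_truth`.
#' @export
gen_pentamer_complex <- function(p) {
  stopifnot(inherits(p, "pentamer_params"))
  n <- p$n_subunits
  loc <- .pentamer_chain_local(p$placement_mode)
  mirror_z <- function(tab) { tab$z <- -tab$z; tab }
  source_subunit <- if (n >= 2L) 2L else 1L
  lig_chains <- LETTERS[seq_len(2L * n)]
  angles <- (seq_len(n) - 1L) * 2 * pi / n
  radii <- rep(p$ring_radius, n)
  if (p$placement_mode == "clashing") {
    # fuse subunit 3 onto subunit 2, offset 2 A radially
    angles[3] <- angles[2]
    radii[3] <- radii[2] + 2
  }
  atoms <- list()
  for (k in seq_len(n)) {
    top <- .place_subunit(loc$lig, radii[k], angles[k])
    bot <- .place_subunit(mirror_z(loc$lig), radii[k], angles[k])
    atoms <- c(atoms, list(.as_ca_atoms(top, lig_chains[2L * k - 1L]),
                           .as_ca_atoms(bot, lig_chains[2L * k])))
  }
  rec_top <- .place_subunit(loc$rec, radii[source_subunit], angles[source_subunit])
  rec_bot <- .place_subunit(mirror_z(loc$rec), radii[source_subunit],
                            angles[source_subunit])
  receptor_chains <- c("Y", "Z")
  atoms <- c(atoms, list(.as_ca_atoms(rec_top, "Y"), .as_ca_atoms(rec_bot, "Z")))
  s <- structure3d(do.call(rbind, atoms))

  pairing <- lapply(seq_len(n), function(k) lig_chains[c(2L * k - 1L, 2L * k)])
  src_chains <- pairing[[source_subunit]]
  adjacent <- character(0)
  if (n >= 3L) {
    prev <- if (source_subunit == 1L) n else source_subunit - 1L
    nxt <- if (source_subunit == n) 1L else source_subunit + 1L
    adjacent <- c(pairing[[prev]][2L], pairing[[nxt]][1L])
  }
  regions <- list(Cmu3 = c(398L, 427L), Cmu4 = c(496L, 525L))
  constraints <- dock_constraints(
    required_receptor = c(66L, 83L, 109L),
    required_ligand = paste0(src_chains[1], ":510"),
    forbidden_receptor = c(41L, 42L, 81L),
    excluded_chains = adjacent,
    regions = regions,
    min_fraction_region = c(Cmu4 = 0.75),
    glyco_site = paste0(src_chains[1], ":402"),
    glyco_radius = 6)
  list(structure = s, pairing = pairing, source_subunit = source_subunit,
       receptor_chains = receptor_chains, constraints = constraints,
       regions = regions,
       ground_truth = list(mode = p$placement_mode, seed = p$seed,
                           n_subunits = n,
                           expected_pass = p$placement_mode == "good_pose",
                           expected_placements = 2L * n,
                           params = p))
}
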