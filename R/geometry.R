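# Interface geometry: residue-residue contacts, docking-pose constraint
# evaluation, steric clash testing, glycan and C-terminus accessibility.

cross_dist <- function(xa, xb) {
  # pairwise Euclidean distances between rows of xa and xb
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
  sqrt(pmax(d2, 0))
}

#' Residue-residue contacts between two selections
#'
#' A residue pair is in contact when any heavy-atom pair across the two
#' selections is at or within `cutoff`. The report lists each contacting
#' pair with its minimum inter-atomic distance.
#'
#' @param s a [structure3d()].
#' @param a,b disjoint atom selections: index vectors from
#'   [str_select()], or lists of `str_select()` arguments
#'   (e.g. `list(chain = "C")`).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @return Object of class `interface_report`: data.frame `contacts`
#'   (`chain_a`, `resno_a`, `chain_b`, `resno_b`, `min_dist`), the
#'   per-side contacting residue tables, and `cutoff`.
#' @export
residue_contacts <- function(s, a, b, cutoff = 5) {
  if (is.list(a)) a <- do.call(str_select, c(list(s), a))
  if (is.list(b)) b <- do.call(str_select, c(list(s), b))
  if (length(a) == 0L || length(b) == 0L) stop("empty selection")
  if (length(intersect(a, b)) > 0L) stop("selections must be disjoint")
  d <- cross_dist(atom_coords(s, a), atom_coords(s, b))
  key_a <- paste(s$atom$chain[a], s$atom$resno[a], sep = ":")
  key_b <- paste(s$atom$chain[b], s$atom$resno[b], sep = ":")
  # minimum distance per residue pair
  min_d <- tapply(as.vector(d),
                  list(rep(key_a, times = length(b)),
                       rep(key_b, each = length(a))), min)
  idx <- which(min_d <= cutoff, arr.ind = TRUE)
  split_key <- function(k) {
    p <- strsplit(k, ":", fixed = TRUE)
    list(chain = vapply(p, `[`, "", 1L),
         resno = as.integer(vapply(p, `[`, "", 2L)))
  }
  ka <- split_key(rownames(min_d)[idx[, 1]])
  kb <- split_key(colnames(min_d)[idx[, 2]])
  contacts <- data.frame(chain_a = ka$chain, resno_a = ka$resno,
                         chain_b = kb$chain, resno_b = kb$resno,
                         min_dist = min_d[idx], stringsAsFactors = FALSE)
  contacts <- contacts[order(contacts$chain_a, contacts$resno_a,
                             contacts$chain_b, contacts$resno_b), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(contacts = contacts, cutoff = cutoff,
                 n_contacts = nrow(contacts)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> %d residue-pair contact(s) at cutoff %.1f A\n",
              x$n_contacts, x$cutoff))
  if (x$n_contacts > 0L) print(utils::head(x$contacts, 20), row.names = FALSE)
  invisible(x)
}

#' Docking constraint set
#'
#' The constraint vocabulary used to screen docked receptor poses:
#' required interface residues on the receptor and the ligand, forbidden
#' receptor interface residues, ligand chains that must contribute no
#' contacts, named ligand domain regions with a minimum contact fraction
#' for one of them, and a glycosylation site with an exclusion radius.
#'
#' @param required_receptor receptor residue numbers that must contact
#'   the ligand (e.g. `c(66, 83, 109)`).
#' @param required_ligand ligand residue refs (`"C:510"` form) that must
#'   contact the receptor.
#' @param forbidden_receptor receptor residue numbers that must not be at
#'   the interface (e.g. `c(41, 42, 81)`).
#' @param excluded_chains ligand chain ids that must contribute no
#'   contacts.
#' @param regions named list of ligand residue ranges
#'   (e.g. `list(Cmu3 = c(398, 427), Cmu4 = c(496, 525))`).
#' @param min_fraction_region `c(region_name = fraction)`: the named
#'   region must hold strictly more than this fraction of contacts.
#' @param glyco_site ligand residue ref of the glycosylation site.
#' @param glyco_radius exclusion radius (A) of the pseudo-glycan sphere.
#' @return Object of class `dock_constraints`.
#' @export
dock_constraints <- function(required_receptor = integer(0),
                             required_ligand = character(0),
                             forbidden_receptor = integer(0),
                             excluded_chains = character(0),
                             regions = list(),
                             min_fraction_region = c(Cmu4 = 0.75),
                             glyco_site = NULL,
                             glyco_radius = 6) {
  if (length(intersect(required_receptor, forbidden_receptor)) > 0L) {
    stop("required and forbidden receptor residues overlap")
  }
  if (length(min_fraction_region) > 0L &&
      (min_fraction_region[1] <= 0 || min_fraction_region[1] > 1)) {
    stop("min_fraction_region must be in (0, 1]")
  }
  structure(list(required_receptor = as.integer(required_receptor),
                 required_ligand = required_ligand,
                 forbidden_receptor = as.integer(forbidden_receptor),
                 excluded_chains = excluded_chains,
                 regions = regions,
                 min_fraction_region = min_fraction_region,
                 glyco_site = glyco_site, glyco_radius = glyco_radius),
            class = "dock_constraints")
}

#' Read docking constraints from YAML
#' @param path YAML file mirroring the [dock_constraints()] arguments.
#' @return A [dock_constraints()].
#' @export
read_constraints_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        names(formals(dock_constraints)))]
  if (!is.null(args$regions)) args$regions <- lapply(args$regions, unlist)
  if (!is.null(args$min_fraction_region)) {
    args$min_fraction_region <- unlist(args$min_fraction_region)
  }
  do.call(dock_constraints, args)
}

#' Evaluate interface constraints for a docked pose
#'
#' PASS requires every required receptor residue and required ligand
#' residue at the interface, no forbidden receptor residue at the
#' interface, and no contact between the receptor and any excluded
#' chain. The report lists each constraint with its status and the
#' evidence distance.
#'
#' @param s complex [structure3d()].
#' @param receptor_chain chain id(s) of the receptor domain.
#' @param ligand_chains chain id(s) of the docking-site ligand chains.
#' @param constraints a [dock_constraints()].
#' @param cutoff interface heavy-atom cutoff in Angstrom.
#' @return Object of class `constraint_report` with `pass`, per-
#'   constraint data.frame `checks`, and the underlying
#'   [residue_contacts()] report.
#' @export
check_constraints <- function(s, receptor_chain, ligand_chains, constraints,
                              cutoff = 5) {
  chains_present <- unique(s$atom$chain)
  for (ref in constraints$required_ligand) {
    r <- parse_residue_ref(ref)
    if (!any(s$atom$chain == r$chain & s$atom$resno == r$resno)) {
      stop(sprintf("required ligand residue %s not found in structure", ref))
    }
  }
  for (p in c(constraints$required_receptor, constraints$forbidden_receptor)) {
    if (!any(s$atom$chain %in% receptor_chain & s$atom$resno == p)) {
      stop(sprintf("receptor residue %d not found on chain(s) %s",
                   p, paste(receptor_chain, collapse = ",")))
    }
  }
  report <- residue_contacts(s, list(chain = receptor_chain),
                             list(chain = ligand_chains), cutoff = cutoff)
  ct <- report$contacts
  checks <- list()
  add <- function(lst, constraint, status, evidence) {
    c(lst, list(data.frame(constraint = constraint, status = status,
                           evidence = evidence, stringsAsFactors = FALSE)))
  }
  for (p in constraints$required_receptor) {
    hit <- ct[ct$resno_a == p, , drop = FALSE]
    ok <- nrow(hit) > 0L
    checks <- add(checks, sprintf("required receptor %d at interface", p),
                  ifelse(ok, "PASS", "FAIL"),
                  if (ok) sprintf("min dist %.2f A", min(hit$min_dist)) else "no contact")
  }
  for (ref in constraints$required_ligand) {
    r <- parse_residue_ref(ref)
    hit <- ct[ct$chain_b == r$chain & ct$resno_b == r$resno, , drop = FALSE]
    ok <- nrow(hit) > 0L
    checks <- add(checks, sprintf("required ligand %s at interface", ref),
                  ifelse(ok, "PASS", "FAIL"),
                  if (ok) sprintf("min dist %.2f A", min(hit$min_dist)) else "no contact")
  }
  for (p in constraints$forbidden_receptor) {
    hit <- ct[ct$resno_a == p, , drop = FALSE]
    ok <- nrow(hit) == 0L
    checks <- add(checks, sprintf("forbidden receptor %d away from interface", p),
                  ifelse(ok, "PASS", "FAIL"),
                  if (ok) "no contact" else sprintf("contact at %.2f A", min(hit$min_dist)))
  }
  for (ch in constraints$excluded_chains) {
    if (!ch %in% chains_present) {
      checks <- add(checks, sprintf("excluded chain %s contributes no contact", ch),
                    "PASS", "chain absent")
      next
    }
    rep_ex <- residue_contacts(s, list(chain = receptor_chain),
                               list(chain = ch), cutoff = cutoff)
    ok <- rep_ex$n_contacts == 0L
    checks <- add(checks, sprintf("excluded chain %s contributes no contact", ch),
                  ifelse(ok, "PASS", "FAIL"),
                  if (ok) "no contact"
                  else sprintf("%d contact(s), min %.2f A", rep_ex$n_contacts,
                               min(rep_ex$contacts$min_dist)))
  }
  checks <- do.call(rbind, checks)
  structure(list(pass = all(checks$status == "PASS"), checks = checks,
                 interface = report),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("<constraint_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Per-region fraction of interface contacts
#'
#' Assigns each contact's ligand residue to a named region range;
#' residues outside every range go to `"other"`. Fractions are over all
#' contacts and sum to 1. Note the boundary semantics of the companion
#' filter: a fraction exactly at the minimum does not satisfy a strict
#' "more than" requirement.
#'
#' @param report an [residue_contacts()] interface report (ligand on
#'   side `b`).
#' @param regions named list of `c(start, end)` ligand residue ranges.
#' @return Named numeric vector of fractions (including `other` when
#'   non-zero), with attribute `counts`.
#' @export
domain_contact_fraction <- function(report, regions) {
  ct <- report$contacts
  if (nrow(ct) == 0L) stop("no contacts in report")
  region_of <- function(resno) {
    for (nm in names(regions)) {
      if (resno >= regions[[nm]][1] && resno <= regions[[nm]][2]) return(nm)
    }
    "other"
  }
  assigned <- vapply(ct$resno_b, region_of, "")
  counts <- table(factor(assigned, levels = c(names(regions), "other")))
  counts <- counts[counts > 0 | names(counts) %in% names(regions)]
  frac <- as.numeric(counts) / nrow(ct)
  names(frac) <- names(counts)
  attr(frac, "counts") <- as.integer(counts)
  frac
}

#' Steric clash test between two atom sets
#'
#' @param xa,xb N x 3 heavy-atom coordinate matrices (or
#'   [structure3d()] objects).
#' @param min_dist clash threshold in Angstrom (default 2.5): any pair
#'   strictly closer clashes.
#' @return List with `clash` (logical) and `n_pairs` (offending pair
#'   count).
#' @export
clash_check <- function(xa, xb, min_dist = 2.5) {
  if (inherits(xa, "structure3d")) xa <- atom_coords(xa, str_select(xa))
  if (inherits(xb, "structure3d")) xb <- atom_coords(xb, str_select(xb))
  if (nrow(xa) == 0L || nrow(xb) == 0L) stop("empty coordinate set")
  d <- cross_dist(xa, xb)
  n <- sum(d < min_dist)
  list(clash = n > 0L, n_pairs = n)
}

#' Glycan interference filter
#'
#' Places a pseudo-glycan sphere at the side-chain tip atom of the
#' glycosylation site (the atom of that residue farthest from its CA;
#' falls back to CA with a warning if the residue has no side-chain
#' atoms) and passes when no receptor heavy atom lies within the radius.
#'
#' @param s complex [structure3d()].
#' @param site residue ref (`"C:402"` form) of the glycosylation site.
#' @param receptor_chain receptor chain id(s).
#' @param radius sphere radius in Angstrom (default 6).
#' @return List with `pass`, `min_dist` (closest receptor atom to the
#'   tip) and `tip` (coordinates used).
#' @export
glycan_filter <- function(s, site, receptor_chain, radius = 6) {
  r <- parse_residue_ref(site)
  idx <- str_select(s, chain = r$chain, resno = r$resno)
  if (length(idx) == 0L) stop(sprintf("glycan site %s:%d not found", r$chain, r$resno))
  names_here <- s$atom$elety[idx]
  ca <- idx[names_here == "CA"]
  side <- idx[!names_here %in% c("CA", "C", "N", "O")]
  if (length(side) == 0L || length(ca) == 0L) {
    warning("glycan site has no side-chain atoms; using CA as the sphere center")
    tip <- colMeans(atom_coords(s, idx))
  } else {
    ca_xyz <- atom_coords(s, ca)[1, ]
    sxyz <- atom_coords(s, side)
    dd <- sqrt(rowSums(sweep(sxyz, 2L, ca_xyz)^2))
    tip <- sxyz[which.max(dd), ]
  }
  rec <- atom_coords(s, str_select(s, chain = receptor_chain))
  dmin <- min(sqrt(rowSums(sweep(rec, 2L, tip)^2)))
  list(pass = dmin > radius, min_dist = dmin, tip = tip)
}

#' C-terminus accessibility of a placed receptor domain
#'
#' The receptor C-terminal residue is accessible when (i) its CA has no
#' non-receptor heavy atom within `threshold` and (ii) it lies on the
#' side of the receptor facing away from the ligand centroid (half-space
#' test on the ligand-to-receptor axis), so a stalk could connect it to
#' a membrane.
#'
#' @param s complex [structure3d()].
#' @param receptor_chain receptor chain id.
#' @param threshold clearance distance in Angstrom (default 8).
#' @return List with `accessible`, `min_dist`, `halfspace_ok`.
#' @export
cterm_accessibility <- function(s, receptor_chain, threshold = 8) {
  rec_idx <- str_select(s, chain = receptor_chain)
  if (length(rec_idx) == 0L) stop("receptor chain not found")
  other_idx <- setdiff(str_select(s), rec_idx)
  last_res <- max(s$atom$resno[rec_idx])
  ct_idx <- rec_idx[s$atom$resno[rec_idx] == last_res &
                      s$atom$elety[rec_idx] == "CA"]
  if (length(ct_idx) == 0L) {
    ct_idx <- rec_idx[s$atom$resno[rec_idx] == last_res][1]
  }
  ct <- atom_coords(s, ct_idx)[1, ]
  if (length(other_idx) == 0L) {
    return(list(accessible = TRUE, min_dist = Inf, halfspace_ok = TRUE))
  }
  env <- atom_coords(s, other_idx)
  dmin <- min(sqrt(rowSums(sweep(env, 2L, ct)^2)))
  rec_cen <- colMeans(atom_coords(s, rec_idx))
  lig_cen <- colMeans(env)
  axis <- rec_cen - lig_cen
  half_ok <- sum((ct - rec_cen) * axis) >= 0
  list(accessible = dmin > threshold && half_ok,
       min_dist = dmin, halfspace_ok = half_ok)
}
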