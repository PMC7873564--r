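test_that("residue contacts match the brute-force all-pairs oracle", {
  # chains far apart: none
  far <- structure3d(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA", elety = "CA",
    elesy = "C", x = c(0, 100), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_equal(residue_contacts(far, list(chain = "A"), list(chain = "B"))$n_contacts, 0L)
  # constructed pose: one residue pair at 3.9 A under cutoff 4.5
  pose <- structure3d(data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 2L, 7L), resid = "ALA",
    elety = "CA", elesy = "C", x = c(0, 20, 3.9), y = 0, z = 0,
    stringsAsFactors = FALSE))
  rep1 <- residue_contacts(pose, list(chain = "A"), list(chain = "B"), cutoff = 4.5)
  expect_equal(rep1$n_contacts, 1L)
  expect_equal(rep1$contacts$resno_a, 1L)
  expect_equal(rep1$contacts$min_dist, 3.9)
  # randomized fixtures against the oracle, and a/b symmetry
  for (seed in 1:10) {
    set.seed(seed)
    s <- random_two_chain_structure()
    a <- str_select(s, chain = "A"); b <- str_select(s, chain = "B")
    rep_ab <- residue_contacts(s, a, b, cutoff = 5)
    oracle <- brute_residue_contacts(s, a, b, cutoff = 5)
    got <- sort(paste(rep_ab$contacts$chain_a, rep_ab$contacts$resno_a,
                      rep_ab$contacts$chain_b, rep_ab$contacts$resno_b))
    expect_equal(got, oracle, label = sprintf("seed %d", seed))
    rep_ba <- residue_contacts(s, b, a, cutoff = 5)
    expect_equal(rep_ba$n_contacts, rep_ab$n_contacts)
  }
  expect_error(residue_contacts(pose, integer(0), list(chain = "B")), "empty selection")
})

test_that("contact and constraint verdicts are invariant under global rigid motion", {
  pent <- gen_pentamer_complex(pentamer_params(seed = 1))
  s <- pent$structure
  base <- check_constraints(s, "Y", pent$pairing[[2]], pent$constraints)
  set.seed(33)
  R <- random_rotation(); shift <- runif(3, -40, 40)
  tr <- structure(list(R = R, t = shift), class = "rigid_transform")
  s2 <- apply_transform(s, tr)
  moved <- check_constraints(s2, "Y", pent$pairing[[2]], pent$constraints)
  expect_equal(moved$pass, base$pass)
  expect_equal(moved$interface$contacts$min_dist, base$interface$contacts$min_dist,
               tolerance = 1e-9)
  expect_equal(clash_check(s2, s2)$clash, clash_check(s, s)$clash)
})

test_that("region contact fractions sum to one and the 75% boundary is strict", {
  # 3 of 4 contacts in the Cmu4-analog range: exactly 0.75, not > 0.75
  rep_toy <- structure(list(contacts = data.frame(
    chain_a = "Y", resno_a = c(66L, 83L, 109L, 83L),
    chain_b = "C", resno_b = c(500L, 505L, 510L, 400L),
    min_dist = 4), cutoff = 5, n_contacts = 4L), class = "interface_report")
  fr <- domain_contact_fraction(rep_toy, list(Cmu3 = c(398, 427), Cmu4 = c(496, 525)))
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["Cmu4"]), 0.75)
  expect_false(fr["Cmu4"] > 0.75)
  # all contacts in one region
  rep_one <- rep_toy; rep_one$contacts$resno_b <- c(500L, 505L, 510L, 496L)
  fr1 <- domain_contact_fraction(rep_one, list(Cmu4 = c(496, 525)))
  expect_equal(unname(fr1["Cmu4"]), 1)
})

test_that("Kabsch superposition is exact, proper and optimal", {
  set.seed(8)
  m <- matrix(runif(30, -10, 10), ncol = 3)
  # identity
  id <- kabsch_superpose(m, m)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  # recover random rigid motions
  for (k in 1:5) {
    R <- random_rotation(); shift <- runif(3, -20, 20)
    tgt <- m %*% R + rep(1, nrow(m)) %o% shift
    fit <- kabsch_superpose(m, tgt)
    expect_equal(fit$R, R, tolerance = 1e-6)
    expect_equal(fit$rmsd, 0, tolerance = 1e-6)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
  }
  # reflections are never produced: mirrored target keeps RMSD > 0
  mirrored <- m %*% diag(c(-1, 1, 1))
  fit_m <- kabsch_superpose(m, mirrored)
  expect_gt(fit_m$rmsd, 0.1)
  expect_equal(det(fit_m$R), 1, tolerance = 1e-9)
  # optimality: no random rotation beats the fit
  tgt <- m %*% random_rotation() + rep(1, nrow(m)) %o% runif(3)
  fit <- kabsch_superpose(m, tgt)
  cm <- colMeans(m); ct2 <- colMeans(tgt)
  for (k in 1:100) {
    R <- random_rotation()
    moved <- sweep(m, 2, cm) %*% R
    rmsd_r <- sqrt(mean(rowSums((moved - sweep(tgt, 2, ct2))^2)))
    expect_gte(rmsd_r, fit$rmsd - 1e-9)
  }
  # degenerate input errors
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("superposition agrees with an independent implementation", {
  set.seed(19)
  m <- matrix(runif(36, -8, 8), ncol = 3)
  tgt <- m %*% random_rotation() + rep(1, 12) %o% runif(3, -5, 5) +
    matrix(rnorm(36, sd = 0.3), ncol = 3)
  fit <- kabsch_superpose(m, tgt)
  ref_xyz <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(tgt)), mobile = as.vector(t(m))))
  ref_rmsd <- sqrt(mean(colSums(matrix((ref_xyz - as.vector(t(tgt)))^2, nrow = 3))))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("clash detection counts offending pairs", {
  a <- matrix(c(0, 0, 0), ncol = 3)
  expect_true(clash_check(a, a)$clash)                       # superposed copies
  b <- matrix(c(50, 0, 0), ncol = 3)
  expect_false(clash_check(a, b)$clash)                      # far apart
  c2 <- matrix(c(2, 0, 0), ncol = 3)
  res <- clash_check(a, c2, min_dist = 2.5)
  expect_true(res$clash); expect_equal(res$n_pairs, 1L)
  res2 <- clash_check(a, c2, min_dist = 1.5)                 # 2.0 A is fine at 1.5
  expect_false(res2$clash)
})

test_that("glycan and C-terminus filters read the fixture geometry", {
  pent <- gen_pentamer_complex(pentamer_params(seed = 2))
  s <- pent$structure
  gf <- suppressWarnings(glycan_filter(s, pent$constraints$glyco_site, "Y"))
  expect_true(gf$pass)
  # an atom pushed inside the sphere fails
  s_bad <- s
  tip_row <- which(s_bad$atom$chain == "C" & s_bad$atom$resno == 402L)
  rec_row <- which(s_bad$atom$chain == "Y" & s_bad$atom$resno == 124L)
  s_bad$atom[rec_row, c("x", "y", "z")] <-
    s_bad$atom[tip_row, c("x", "y", "z")] + c(1, 0, 0)
  gf_bad <- suppressWarnings(glycan_filter(s_bad, pent$constraints$glyco_site, "Y"))
  expect_false(gf_bad$pass)
  # C-termini of the good pose point away from the disc
  expect_true(cterm_accessibility(s, "Y")$accessible)
  expect_true(cterm_accessibility(s, "Z")$accessible)
  # buried mode fails the half-space test
  pent_b <- gen_pentamer_complex(pentamer_params(seed = 2, placement_mode = "buried_cterm"))
  acc <- cterm_accessibility(pent_b$structure, "Y")
  expect_false(acc$accessible)
  # a lone receptor with no environment is trivially accessible
  lone <- structure3d(data.frame(chain = "Y", resno = 1L, resid = "ALA",
                                 elety = "CA", elesy = "C", x = 0, y = 0, z = 0,
                                 stringsAsFactors = FALSE))
  expect_true(cterm_accessibility(lone, "Y")$accessible)
})

test_that("constraint evaluation passes good poses and fails broken ones", {
  pent <- gen_pentamer_complex(pentamer_params(seed = 1))
  s <- pent$structure
  verdict <- check_constraints(s, "Y", pent$pairing[[2]], pent$constraints)
  expect_true(verdict$pass)
  # a PASS implies every required receptor residue is in the contact list
  expect_true(all(pent$constraints$required_receptor %in%
                    verdict$interface$contacts$resno_a))
  # translated receptor: all required constraints unmet
  s_far <- s
  rows <- s_far$atom$chain == "Y"
  s_far$atom$z[rows] <- s_far$atom$z[rows] + 50
  far <- check_constraints(s_far, "Y", pent$pairing[[2]], pent$constraints)
  expect_false(far$pass)
  req <- grepl("^required", far$checks$constraint)
  expect_true(all(far$checks$status[req] == "FAIL"))
  # decoy chain listed as excluded and touching the receptor
  decoy <- s$atom[s$atom$chain == "C", ]
  decoy$chain <- "Q"; decoy$z <- decoy$z + 3.5   # slide up toward the receptor
  s_decoy <- structure3d(rbind(s$atom, decoy))
  cons2 <- pent$constraints; cons2$excluded_chains <- c(cons2$excluded_chains, "Q")
  dec <- check_constraints(s_decoy, "Y", pent$pairing[[2]], cons2)
  expect_false(dec$pass)
  bad_row <- dec$checks[grepl("excluded chain Q", dec$checks$constraint), ]
  expect_equal(bad_row$status, "FAIL")
  # unresolvable references are configuration errors
  cons3 <- pent$constraints; cons3$required_ligand <- "C:9999"
  expect_error(check_constraints(s, "Y", pent$pairing[[2]], cons3), "9999")
})

test_that("tiling places and scores receptors on every subunit", {
  pent <- gen_pentamer_complex(pentamer_params(seed = 1))
  ps <- tile_pentamer(pent$structure, pent$pairing, pent$source_subunit, c("Y", "Z"))
  expect_length(ps$placements, 10L)
  expect_false(any(ps$clash))
  expect_equal(ps$accessible_count, 10L)
  # transforms are proper rotations
  dets <- vapply(ps$placements, function(p) det(p$transform$R), 1)
  expect_equal(dets, rep(1, 10), tolerance = 1e-9)
  # tiling consistency: every placement superposes onto the source
  # placement (via its own subunit) to < 1e-6 RMSD
  src_top <- ps$placements[[which(vapply(ps$placements, `[[`, 1L, "subunit") ==
                                    pent$source_subunit &
                                  vapply(ps$placements, `[[`, "", "receptor") == "Y")]]
  for (p in ps$placements) {
    if (p$receptor != "Y") next
    back <- kabsch_superpose(as.matrix(p$atoms[, c("x", "y", "z")]),
                             as.matrix(src_top$atoms[, c("x", "y", "z")]))
    expect_lt(back$rmsd, 1e-6)
  }
  # fused subunits produce clashing, inaccessible placements
  pent_c <- gen_pentamer_complex(pentamer_params(seed = 1, placement_mode = "clashing"))
  ps_c <- tile_pentamer(pent_c$structure, pent_c$pairing, pent_c$source_subunit,
                        c("Y", "Z"))
  expect_gt(sum(ps_c$clash), 0L)
  expect_lt(ps_c$accessible_count, 10L)
  # a single-subunit disc yields just the two source placements
  p1 <- gen_pentamer_complex(pentamer_params(n_subunits = 1, seed = 1))
  ps1 <- tile_pentamer(p1$structure, p1$pairing, 1L, c("Y", "Z"))
  expect_length(ps1$placements, 2L)
})

test_that("affinity calibration interpolates and recovers slopes", {
  # exact line through two points: (400, 1e4), (1200, 1e10) -> predict(800) = 1e7
  cal <- fit_affinity_calibration(c(400, 1200), c(1e4, 1e10))
  expect_equal(predict(cal, 800), 1e7, tolerance = 1e-6)
  expect_equal(predict(cal, 400), 1e4, tolerance = 1e-6)
  # identical scores with different Ka cannot be fitted
  expect_error(fit_affinity_calibration(c(500, 500), c(1e5, 1e6)), "distinct")
  # noisy synthetic points recover the slope within 3 SE
  set.seed(5)
  scores <- seq(400, 1200, length.out = 12)
  true_slope <- 6 / 800
  logka <- 4 + true_slope * (scores - 400) + rnorm(12, sd = 0.3)
  cal2 <- fit_affinity_calibration(scores, 10^logka)
  se <- summary(cal2$fit)$coefficients[2, 2]
  expect_lt(abs(cal2$slope - true_slope), 3 * se)
})

test_that("PDB structure round-trip preserves atoms", {
  pent <- gen_pentamer_complex(pentamer_params(n_subunits = 2, seed = 4))
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(pent$structure, tmp)
  back <- read_structure_pdb(tmp)
  expect_equal(nrow(back$atom), nrow(pent$structure$atom))
  expect_equal(back$atom$resno, pent$structure$atom$resno)
  expect_equal(back$atom$x, pent$structure$atom$x, tolerance = 1e-3)
})
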