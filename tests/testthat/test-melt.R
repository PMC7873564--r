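make_traj <- function(xyz, times = NULL, resno = NULL,
                      schedule = fcmur_heating_schedule()) {
  if (is.null(times)) times <- seq(0, 204, length.out = nrow(xyz))
  if (is.null(resno)) resno <- seq_len(ncol(xyz) / 3L)
  heating_trajectory(xyz, times, resno, schedule)
}

test_that("the heating schedule interpolates the published ramp", {
  sch <- fcmur_heating_schedule()
  expect_equal(frame_temperature(sch, 0), 0.15)        # -273 C
  expect_equal(frame_temperature(sch, 4), 200.15)      # -73 C
  expect_equal(frame_temperature(sch, 104), 300.15)    # ramp midpoint
  expect_equal(frame_temperature(sch, 204), 400.15)    # 127 C
  expect_equal(frame_temperature(sch, 900), 400.15)    # hold
  no_hold <- temperature_schedule(sch$segments, hold_after_end = FALSE)
  expect_error(frame_temperature(no_hold, 900), "beyond schedule")
  # continuity across the segment boundary
  expect_equal(frame_temperature(sch, 4 - 1e-9), frame_temperature(sch, 4 + 1e-9),
               tolerance = 1e-6)
})

test_that("native-contact definition matches a brute-force scan", {
  # two atoms 3 A apart, 5 residues apart, cutoff 4.5 -> one pair
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  nc <- define_native_contacts(coords, resno = c(1L, 6L), cutoff = 4.5,
                               min_seq_separation = 4L)
  expect_equal(nrow(nc$pairs), 1L)
  expect_equal(nc$pairs$ref_dist, 3)
  # 10 A-spaced chain has no contacts at 4.5 A
  chain <- cbind(seq(0, 90, by = 10), 0, 0)
  expect_warning(
    nc0 <- define_native_contacts(chain, 1:10, cutoff = 4.5, min_seq_separation = 4L),
    "empty")
  expect_equal(nrow(nc0$pairs), 0L)
  # random toys equal the O(N^2) oracle
  set.seed(11)
  for (k in 1:5) {
    coords <- matrix(runif(90, 0, 12), ncol = 3)
    resno <- sort(sample(1:15, 30, replace = TRUE))
    nc <- define_native_contacts(coords, resno, cutoff = 6, min_seq_separation = 3L)
    oracle <- brute_contacts(coords, resno, cutoff = 6, min_sep = 3L)
    expect_equal(nc$pairs$i, oracle$i)
    expect_equal(nc$pairs$j, oracle$j)
    expect_equal(nc$pairs$ref_dist, oracle$ref_dist, tolerance = 1e-12)
  }
})

test_that("contact fraction is 1 at the reference, 0 when blown apart", {
  set.seed(3)
  ref <- helix_reference(20)
  nc <- define_native_contacts(ref, 1:20, cutoff = 8, min_seq_separation = 4L)
  xyz <- rbind(as.vector(t(ref)), 3 * as.vector(t(ref)))
  q <- contact_fraction_profile(make_traj(xyz), nc)
  expect_equal(q[1], 1)
  expect_equal(q[2], 0)
  # constructed half-broken frame: stretch exactly half the pairs
  p2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(50, 0, 0), c(53, 0, 0), c(50, 30, 0))
  nc2 <- define_native_contacts(p2, resno = c(1L, 6L, 11L, 16L, 21L),
                                cutoff = 4.5, min_seq_separation = 4L)
  expect_equal(nrow(nc2$pairs), 2L)
  frame2 <- p2; frame2[2, 1] <- 10   # break pair 1-2 only
  xyz <- rbind(as.vector(t(p2)), as.vector(t(frame2)))
  q <- contact_fraction_profile(make_traj(xyz), nc2)
  expect_equal(q, c(1, 0.5))
})

test_that("Q stays in [0,1] and never rises under uniform expansion", {
  g <- gen_heating_trajectory(melt_sim_params(seed = 5))
  nc <- define_native_contacts(g$reference, 1:30, cutoff = 8, min_seq_separation = 4L)
  q <- contact_fraction_profile(g$traj, nc)
  expect_true(all(q >= 0 & q <= 1))
  for (s in c(1, 1.2, 1.6, 2.5)) {
    tr <- g$traj; tr$xyz <- tr$xyz * s
    qs <- contact_fraction_profile(tr, nc)
    expect_true(all(qs <= q + 1e-12), label = sprintf("scale %.1f", s))
    q <- qs
  }
})

test_that("radius of gyration has its closed-form values", {
  sch <- fcmur_heating_schedule()
  co <- matrix(rep(c(1, 2, 3), 4), nrow = 1)          # 4 coincident atoms
  expect_equal(rg_profile(make_traj(rbind(co, co)))[1], 0)
  two <- matrix(c(0, 0, 0, 4, 0, 0), nrow = 1)        # two atoms 2d apart -> Rg = d
  expect_equal(rg_profile(make_traj(rbind(two, two)))[1], 2)
  cube <- as.vector(t(as.matrix(expand.grid(0:1, 0:1, 0:1))))
  expect_equal(rg_profile(make_traj(rbind(cube, cube)))[1], sqrt(3) / 2)
})

test_that("Rg is invariant under rigid motion of every frame", {
  set.seed(21)
  g <- gen_heating_trajectory(melt_sim_params(seed = 9, frames = 50L))
  rg <- rg_profile(g$traj)
  tr <- g$traj
  for (f in seq_len(nrow(tr$xyz))) {
    R <- random_rotation(); shift <- runif(3, -30, 30)
    m <- matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE) %*% R +
      rep(1, ncol(tr$xyz) / 3) %o% shift
    tr$xyz[f, ] <- as.vector(t(m))
  }
  expect_equal(rg_profile(tr), rg, tolerance = 1e-9)
})

test_that("moving mean handles identity, constants and edge shrinkage", {
  expect_equal(moving_mean(c(4, 9, 2), 1L), c(4, 9, 2))
  expect_equal(moving_mean(rep(3.5, 10), 5L), rep(3.5, 10))
  expect_equal(moving_mean(c(0, 1, 0), 3L), c(0.5, 1 / 3, 0.5))
  expect_error(moving_mean(1:3, 2L), "odd")
  expect_error(moving_mean(1:3, 5L), "window longer")
})

test_that("a profile crossing the threshold at a frame returns that frame's temperature", {
  sch <- fcmur_heating_schedule()
  t336 <- 4 + (336 - 200.15)  # ramp is 1 K/ns, so 336 K is reached at 139.85 ns
  times <- seq(0, 204, by = 0.05)
  traj <- heating_trajectory(matrix(1, length(times), 6), times, 1:2, sch)
  # linear profile hitting 0.8 exactly at the 139.85 ns frame
  profile <- 1 - 0.2 * times / t336
  est <- estimate_tm(profile, traj, criterion = "contacts", window = 1L)
  expect_false(est$censored)
  expect_equal(est$Tm, 336, tolerance = 1e-6)
  expect_equal(est$Tm_celsius, 336 - 273.15, tolerance = 1e-6)
  # never-crossing profile is censored
  est2 <- estimate_tm(rep(1, length(times)), traj, "contacts", window = 1L)
  expect_true(est2$censored)
  # a crossing during the hold is flagged post-ramp
  times2 <- seq(0, 400, by = 1)
  traj2 <- heating_trajectory(matrix(1, length(times2), 6), times2, 1:2, sch)
  prof2 <- ifelse(times2 < 300, 1, 0)
  est3 <- estimate_tm(prof2, traj2, "contacts", window = 1L)
  expect_true(est3$post_ramp)
  expect_equal(est3$Tm, 400.15)
})

test_that("repeat aggregation gives sample moments with censoring carried", {
  agg <- aggregate_repeats(c(336, 336, 336))
  expect_equal(agg$mean_Tm, 336); expect_equal(agg$sd_Tm, 0); expect_equal(agg$n, 3L)
  agg2 <- aggregate_repeats(c(330, 340))
  expect_equal(agg2$mean_Tm, 335)
  expect_equal(agg2$sd_Tm, sqrt(50), tolerance = 1e-9)  # 7.071
  agg3 <- aggregate_repeats(c(330, NA, 340, NA))
  expect_equal(agg3$censored, 2L); expect_equal(agg3$n, 2L)
  # independent two-pass variance check
  set.seed(14)
  x <- rnorm(9, 340, 6)
  two_pass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(aggregate_repeats(x)$sd_Tm, two_pass, tolerance = 1e-12)
  expect_error(aggregate_repeats(c(NA_real_, NA_real_)), "all repeats censored")
})

test_that("group comparison reproduces a pooled t-test from samples or summaries", {
  a <- c(330, 334, 339); b <- c(322, 327, 331)
  res <- compare_tm_groups(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  # summary form agrees with the sample form
  res2 <- compare_tm_groups(list(mean = mean(a), sd = sd(a), n = 3),
                            list(mean = mean(b), sd = sd(b), n = 3))
  expect_equal(res2$p.value, res$p.value, tolerance = 1e-12)
  # two-point toy against the closed form, df = n1 + n2 - 2
  res3 <- compare_tm_groups(c(1, 2), c(4, 6))
  expect_equal(res3$df, 2)
  expect_equal(res3$p.value, t.test(c(1, 2), c(4, 6), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # degenerate cases
  expect_equal(compare_tm_groups(c(5, 5), c(5, 5))$p.value, 1)
  deg <- compare_tm_groups(c(5, 5), c(7, 7))
  expect_equal(deg$p.value, 0); expect_true(deg$degenerate)
})

test_that("trajectory readers reproduce the coordinates", {
  g <- gen_heating_trajectory(melt_sim_params(seed = 3, frames = 5L))
  tmp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g$traj, tmp)
  back <- read_trajectory_pdb(tmp, g$traj$times, g$traj$schedule)
  expect_equal(back$xyz, unname(g$traj$xyz), tolerance = 1e-3)  # PDB has 3 decimals
  # plain-text table dialect
  tab <- tempfile(fileext = ".txt")
  df <- do.call(rbind, lapply(1:5, function(f) {
    m <- frame_coords(g$traj, f)
    data.frame(frame = f, atom = seq_len(nrow(m)), x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  write.table(df, tab, row.names = FALSE, quote = FALSE)
  back2 <- read_trajectory_table(tab, g$traj$times, g$traj$schedule)
  expect_equal(back2$xyz, unname(g$traj$xyz), tolerance = 1e-12)
})
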