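# Melting-temperature estimation from a heating trajectory by two
# criteria: the moving-mean fraction of native contacts falling to 0.8,
# and the moving-mean radius of gyration exceeding 14 Angstrom.

#' Define the native-contact set of a reference structure
#'
#' Lists every atom pair whose reference distance is within `cutoff` and
#' whose residues are at least `min_seq_separation` apart in sequence.
#' The default cutoff suits all-heavy-atom structures (4.5 A); for
#' Calpha-only models use `cutoff = 8`.
#'
#' @param ref_coords N x 3 reference coordinates (or length-3N vector).
#' @param resno residue index per atom.
#' @param cutoff contact cutoff in Angstrom.
#' @param min_seq_separation minimum residue separation.
#' @return Object of class `native_contact_set`: data.frame `pairs`
#'   (`i`, `j`, `ref_dist`) plus the parameters.
#' @export
define_native_contacts <- function(ref_coords, resno, cutoff = 4.5,
                                   min_seq_separation = 4L) {
  if (is.null(dim(ref_coords))) ref_coords <- matrix(ref_coords, ncol = 3L, byrow = TRUE)
  if (length(unique(resno)) < 2L) stop("reference must span at least 2 residues")
  d <- as.matrix(stats::dist(ref_coords))
  sep <- abs(outer(resno, resno, "-"))
  keep <- upper.tri(d) & d <= cutoff & sep >= min_seq_separation
  idx <- which(keep, arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2], ref_dist = d[keep])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L) warning("empty native-contact set")
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_seq_separation = as.integer(min_seq_separation)),
            class = "native_contact_set")
}

#' Fraction of native contacts retained per frame
#'
#' Q(frame) is the fraction of native pairs whose current distance is at
#' or below the retention threshold: the contact cutoff itself by default
#' (a contact "remains" while its distance stays within the cutoff), or
#' `lambda` times each pair's reference distance.
#'
#' @param traj a [heating_trajectory()].
#' @param contacts a [define_native_contacts()] set.
#' @param retention `"cutoff"` or `"lambda"`.
#' @param lambda multiplier for the `"lambda"` mode.
#' @return Numeric vector of Q values in `[0, 1]`, one per frame.
#' @export
contact_fraction_profile <- function(traj, contacts,
                                     retention = c("cutoff", "lambda"),
                                     lambda = 1.2) {
  retention <- match.arg(retention)
  p <- contacts$pairs
  if (nrow(p) == 0L) stop("empty native-contact set")
  thr <- switch(retention,
                cutoff = rep(contacts$cutoff, nrow(p)),
                lambda = lambda * p$ref_dist)
  ix <- 3L * (p$i - 1L); jx <- 3L * (p$j - 1L)
  d2 <- matrix(0, nrow(traj$xyz), nrow(p))
  for (k in 1:3) {
    d2 <- d2 + (traj$xyz[, ix + k, drop = FALSE] -
                  traj$xyz[, jx + k, drop = FALSE])^2
  }
  rowMeans(sweep(sqrt(d2), 2L, thr, "<="))
}

#' Radius of gyration per frame
#'
#' Unweighted by default: `Rg = sqrt(mean |r_i - centroid|^2)` over
#' atoms. Optional mass weighting takes per-atom masses.
#'
#' @param traj a [heating_trajectory()].
#' @param masses optional per-atom masses for mass weighting.
#' @return Numeric vector of Rg values (Angstrom), one per frame.
#' @export
rg_profile <- function(traj, masses = NULL) {
  n_atoms <- ncol(traj$xyz) / 3L
  w <- if (is.null(masses)) rep(1, n_atoms) else masses
  w <- w / sum(w)
  rg2 <- 0
  for (k in 1:3) {
    coord <- traj$xyz[, 3L * (seq_len(n_atoms) - 1L) + k, drop = FALSE]
    cen <- as.vector(coord %*% w)
    rg2 <- rg2 + (coord - cen)^2 %*% w
  }
  sqrt(as.vector(rg2))
}

#' Centered moving mean with shrinking edge windows
#'
#' @param x numeric series.
#' @param window odd window length in frames (>= 1); windows shrink
#'   symmetrically-truncated at the series edges.
#' @return Smoothed series of the same length.
#' @export
moving_mean <- function(x, window) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(x)
  if (window > n) stop("window longer than series")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the melting temperature from an order-parameter profile
#'
#' Smooths the profile with a centered moving mean, finds the first
#' crossing of the threshold in the stated direction, interpolates the
#' crossing time linearly between the bracketing frames, and converts it
#' to temperature through the trajectory's schedule. The built-in
#' criteria are `"contacts"` (moving-mean Q falls below 0.8) and `"rg"`
#' (moving-mean Rg exceeds 14 A).
#'
#' @param profile per-frame order parameter aligned to `traj` frames.
#' @param traj a [heating_trajectory()].
#' @param criterion `"contacts"`, `"rg"`, or a list
#'   `list(threshold =, direction = "falls_below"|"exceeds")`.
#' @param window moving-mean window in frames (odd; default 51).
#' @return Object of class `tm_estimate`: `Tm` (K, `NA` if censored),
#'   `Tm_celsius`, `censored`, `post_ramp` (crossing during the
#'   temperature hold), `t_cross` (ns) and `window_span_K` (the
#'   temperature span of one smoothing window at the crossing).
#' @export
estimate_tm <- function(profile, traj, criterion = "contacts", window = 51L) {
  if (length(profile) != nrow(traj$xyz)) {
    stop("profile must be aligned to the trajectory frames")
  }
  if (is.character(criterion)) {
    criterion <- switch(match.arg(criterion, c("contacts", "rg")),
                        contacts = list(threshold = 0.8, direction = "falls_below"),
                        rg = list(threshold = 14, direction = "exceeds"))
  }
  thr <- criterion$threshold
  dir <- match.arg(criterion$direction, c("falls_below", "exceeds"))
  sm <- moving_mean(profile, window)
  crossed <- if (dir == "falls_below") sm < thr else sm > thr
  # first frame k with the smoothed value beyond the threshold while the
  # previous frame was not
  k <- which(crossed & !c(TRUE, crossed[-length(crossed)]))
  if (!crossed[1] && length(k) == 0L) {
    return(structure(list(Tm = NA_real_, Tm_celsius = NA_real_,
                          censored = TRUE, post_ramp = FALSE,
                          t_cross = NA_real_, window_span_K = NA_real_),
                     class = "tm_estimate"))
  }
  if (crossed[1]) {
    t_cross <- traj$times[1]
  } else {
    k <- k[1]
    a <- sm[k - 1L]; b <- sm[k]
    f <- if (abs(b - a) < 1e-300) 0 else (thr - a) / (b - a)
    t_cross <- traj$times[k - 1L] + f * (traj$times[k] - traj$times[k - 1L])
  }
  seg <- traj$schedule$segments
  t_ramp_end <- seg$t_end[nrow(seg)]
  h <- (window - 1L) %/% 2L
  kk <- if (crossed[1]) 1L else k
  t_lo <- traj$times[max(kk - h, 1L)]
  t_hi <- traj$times[min(kk + h, length(traj$times))]
  span <- abs(frame_temperature(traj$schedule, t_hi) -
                frame_temperature(traj$schedule, t_lo))
  Tm <- frame_temperature(traj$schedule, t_cross)
  structure(list(Tm = Tm, Tm_celsius = kelvin_to_celsius(Tm),
                 censored = FALSE, post_ramp = t_cross > t_ramp_end + 1e-9,
                 t_cross = t_cross, window_span_K = span),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  if (x$censored) {
    cat("<tm_estimate> censored (no crossing)\n")
  } else {
    cat(sprintf("<tm_estimate> Tm = %.1f K (%.1f C) at t = %.2f ns%s; window span %.2f K\n",
                x$Tm, x$Tm_celsius, x$t_cross,
                if (x$post_ramp) " [post-ramp hold]" else "", x$window_span_K))
  }
  invisible(x)
}

#' Aggregate per-repeat melting temperatures
#'
#' Sample mean and sample SD (n - 1 denominator) over the uncensored
#' repeats; censored repeats (no crossing) are excluded from the moments
#' but counted.
#'
#' @param tms numeric vector of per-repeat Tm values (NA = censored), or
#'   a list of [estimate_tm()] results.
#' @param criterion label carried through for reporting.
#' @return Object of class `melting_estimate`: `per_repeat_Tm`,
#'   `mean_Tm`, `sd_Tm`, `n`, `censored`.
#' @export
aggregate_repeats <- function(tms, criterion = "contacts") {
  if (is.list(tms)) tms <- vapply(tms, `[[`, numeric(1), "Tm")
  ok <- tms[!is.na(tms)]
  if (length(ok) == 0L) stop("all repeats censored")
  structure(list(per_repeat_Tm = tms,
                 mean_Tm = mean(ok),
                 sd_Tm = if (length(ok) > 1L) stats::sd(ok) else 0,
                 n = length(ok),
                 censored = sum(is.na(tms)),
                 criterion = criterion),
            class = "melting_estimate")
}

#' @export
print.melting_estimate <- function(x, ...) {
  cat(sprintf("<melting_estimate> [%s] mean Tm = %.1f K (%.1f C), SD = %.1f, n = %d, censored = %d\n",
              x$criterion, x$mean_Tm, kelvin_to_celsius(x$mean_Tm),
              x$sd_Tm, x$n, x$censored))
  invisible(x)
}

#' Two-sided pooled-variance Student's t-test between two Tm groups
#'
#' Accepts either raw per-repeat samples or summary triplets
#' `list(mean =, sd =, n =)`, so published mean/SD/n rows can be compared
#' directly. Degenerate zero-pooled-variance input gives p = 1 when the
#' means are equal and p = 0 (flagged) otherwise.
#'
#' @param a,b numeric samples or `list(mean, sd, n)` summaries.
#' @return List with `statistic`, `df`, `p.value`, `degenerate`.
#' @export
compare_tm_groups <- function(a, b) {
  as_summary <- function(x) {
    if (is.numeric(x)) {
      if (length(x) < 2L) stop("samples need n >= 2")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    } else {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)), x$n >= 2L)
      x
    }
  }
  sa <- as_summary(a); sb <- as_summary(b)
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  if (se == 0) {
    equal <- isTRUE(all.equal(sa$mean, sb$mean))
    return(list(statistic = if (equal) 0 else Inf, df = df,
                p.value = if (equal) 1 else 0, degenerate = TRUE))
  }
  tstat <- (sa$mean - sb$mean) / se
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df), degenerate = FALSE)
}
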