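# The MFI index: background-corrected surface staining normalised to
# transgene (GFP) expression, computed from PE/GFP fluorescence
# summaries of mixed transductant/control populations.

#' Mean fluorescence intensity of a population
#'
#' @param events data.frame with per-event fluorescence columns and a
#'   `population` column (`"transductant"` / `"control"`).
#' @param channel fluorescence column name (e.g. `"PE"`, `"GFP"`).
#' @param population which population to summarise.
#' @param statistic arithmetic mean (default) or geometric mean
#'   (cytometry convention varies; both are provided).
#' @return The MFI value.
#' @export
compute_mfi <- function(events, channel, population,
                        statistic = c("arithmetic", "geometric")) {
  statistic <- match.arg(statistic)
  v <- events[[channel]][events$population == population]
  if (length(v) == 0L) stop(sprintf("population '%s' is empty", population))
  if (!all(is.finite(v))) stop("fluorescence values must be finite")
  switch(statistic,
         arithmetic = mean(v),
         geometric = exp(mean(log(v))))
}

#' The MFI index of a transductant/control mixture
#'
#' `[(PE MFI of the transductant) - (PE MFI of the control)] /
#'  [(GFP MFI of the transductant) - (GFP MFI of the control)]`.
#' The GFP difference must be positive: a non-positive difference means
#' the GFP gate failed to separate transductant from control, and the
#' index is undefined.
#'
#' @param pe_t,pe_c PE MFI of transductant and control, or a single
#'   list/one-row data.frame with fields `pe_t`, `pe_c`, `gfp_t`,
#'   `gfp_c` as the first argument.
#' @param gfp_t,gfp_c GFP MFI of transductant and control.
#' @return The index value (vectorised over inputs).
#' @export
mfi_index <- function(pe_t, pe_c = NULL, gfp_t = NULL, gfp_c = NULL) {
  if (is.list(pe_t)) {
    rec <- pe_t
    pe_c <- rec$pe_c; gfp_t <- rec$gfp_t; gfp_c <- rec$gfp_c; pe_t <- rec$pe_t
  }
  if (any(gfp_t <= gfp_c)) {
    stop("undefined MFI index: GFP MFI of the transductant must exceed the control (failed GFP gating)")
  }
  (pe_t - pe_c) / (gfp_t - gfp_c)
}

#' MFI indices of a record table
#'
#' @param records data.frame with columns `construct`, `probe`,
#'   `replicate`, `pe_t`, `pe_c`, `gfp_t`, `gfp_c`.
#' @return The table with an `index` column appended.
#' @export
mfi_index_table <- function(records) {
  records$index <- mfi_index(records$pe_t, records$pe_c,
                             records$gfp_t, records$gfp_c)
  records
}

#' Summarise replicate indices of one construct
#'
#' @param indices replicate MFI index values.
#' @return List with `mean`, `sd` (sample SD, n - 1; `NA` and flagged
#'   when n = 1), `n`, `single_replicate`.
#' @export
summarize_construct <- function(indices) {
  n <- length(indices)
  if (n < 1L) stop("need at least one replicate")
  list(mean = mean(indices),
       sd = if (n > 1L) stats::sd(indices) else NA_real_,
       n = n, single_replicate = n == 1L)
}

#' Significance tier of a p-value
#'
#' @param p p-value(s).
#' @param thresholds tier cutoffs for `*`, `**`, `***`.
#' @return Character tier: `ns`, `*`, `**` or `***` (p strictly below
#'   0.05, 0.01, 0.001).
#' @export
significance_tier <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  vapply(p, function(pp) {
    if (pp < thresholds[3]) "***"
    else if (pp < thresholds[2]) "**"
    else if (pp < thresholds[1]) "*"
    else "ns"
  }, "")
}

#' Compare a construct's indices with wild type
#'
#' Two-sided Student's t-test (pooled variance by default; Welch behind
#' a flag), with the significance tier at the 0.05/0.01/0.001 cutoffs.
#' Zero pooled variance is handled as a degenerate case: p = 1 for equal
#' means, p = 0 (flagged) otherwise.
#'
#' @param construct replicate indices of the construct (n >= 2).
#' @param wt replicate indices of the wild-type reference (n >= 2).
#' @param welch use the Welch (unequal-variance) form.
#' @return List with `p.value`, `statistic`, `df`, `tier`, `degenerate`.
#' @export
compare_to_wt <- function(construct, wt, welch = FALSE) {
  stopifnot(length(construct) >= 2L, length(wt) >= 2L)
  if (stats::var(construct) + stats::var(wt) == 0) {
    equal <- isTRUE(all.equal(mean(construct), mean(wt)))
    p <- if (equal) 1 else 0
    return(list(p.value = p, statistic = if (equal) 0 else Inf,
                df = length(construct) + length(wt) - 2,
                tier = significance_tier(p), degenerate = TRUE))
  }
  tt <- stats::t.test(construct, wt, var.equal = !welch)
  list(p.value = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter), tier = significance_tier(tt$p.value),
       degenerate = FALSE)
}

#' Summarise an MFI index panel against wild type
#'
#' @param records record table as in [mfi_index_table()].
#' @param wt_label construct label of the wild-type reference.
#' @param probe restrict to one probe label (NULL = all, probe-wise).
#' @return data.frame with one row per construct and probe: mean, SD,
#'   n, p-value vs WT and tier (`NA` p for the WT rows themselves).
#' @export
summarize_panel <- function(records, wt_label, probe = NULL) {
  tab <- mfi_index_table(records)
  if (!is.null(probe)) tab <- tab[tab$probe %in% probe, , drop = FALSE]
  out <- list()
  for (pr in unique(tab$probe)) {
    sub <- tab[tab$probe == pr, , drop = FALSE]
    wt_idx <- sub$index[sub$construct == wt_label]
    if (length(wt_idx) == 0L) stop(sprintf("no '%s' rows for probe %s", wt_label, pr))
    for (cs in unique(sub$construct)) {
      idx <- sub$index[sub$construct == cs]
      sm <- summarize_construct(idx)
      if (cs == wt_label || length(idx) < 2L || length(wt_idx) < 2L) {
        p <- NA_real_; tier <- NA_character_
      } else {
        cmp <- compare_to_wt(idx, wt_idx)
        p <- cmp$p.value; tier <- cmp$tier
      }
      out <- c(out, list(data.frame(
        construct = cs, probe = pr, mean = sm$mean, sd = sm$sd, n = sm$n,
        p_vs_wt = p, tier = tier, stringsAsFactors = FALSE)))
    }
  }
  do.call(rbind, out)
}
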