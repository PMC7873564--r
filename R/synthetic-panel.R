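# Synthetic flow-cytometry panels: per-construct replicate MFI records
# (and optionally log-normal event tables) with programmed index
# multipliers relative to wild type.

#' Parameters of the synthetic mutant panel
#'
#' Defaults mirror the design of a transductant screen: a wild-type
#' construct at baseline, reduced-binding constructs at 0.2x and an
#' enhanced construct at 2x, three independent replicates, 10 percent
#' replicate-to-replicate CV.
#'
#' @param constructs named numeric vector of programmed index
#'   multipliers (> 0) relative to the wild-type baseline.
#' @param baseline_index wild-type MFI index.
#' @param replicates replicates per construct.
#' @param cv replicate coefficient of variation of the index (>= 0).
#' @param gfp_t,gfp_c,pe_c fixed GFP and background PE MFIs.
#' @param sdlog log-scale SD of the event-level log-normal
#'   distributions.
#' @param n_events events per population when event tables are drawn.
#' @param seed mandatory RNG seed.
#' @return List of class `panel_params`.
#' @export
panel_params <- function(constructs = c(huWT = 1, "24-27" = 0.2, "41-42" = 2,
                                        "N66-" = 0.2, "79-83" = 0.2,
                                        "N109K" = 0.2, "Y81C" = 1),
                         baseline_index = 2, replicates = 3L, cv = 0.1,
                         gfp_t = 1000, gfp_c = 100, pe_c = 50,
                         sdlog = 0.5, n_events = 5000L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(constructs > 0), cv >= 0, replicates >= 1L, gfp_t > gfp_c)
  structure(list(constructs = constructs, baseline_index = baseline_index,
                 replicates = as.integer(replicates), cv = cv,
                 gfp_t = gfp_t, gfp_c = gfp_c, pe_c = pe_c,
                 sdlog = sdlog, n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "panel_params")
}

# log-normal sample with a programmed arithmetic mean
.rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic flow-cytometry mutant panel
#'
#' Per construct and replicate, draws the realised index as the
#' programmed value times `(1 + eps)` with `eps ~ N(0, cv)`, and builds
#' the MFI record with `pe_t = pe_c + index * (gfp_t - gfp_c)`, so the
#' expected MFI index equals the programmed multiplier times the
#' wild-type baseline. With `events = TRUE`, log-normal PE/GFP event
#' tables whose arithmetic means equal the record MFIs are drawn for
#' each record.
#'
#' @param p a [panel_params()].
#' @param events also generate event-level tables.
#' @return List with `records` (data.frame: construct, probe, replicate,
#'   pe_t, pe_c, gfp_t, gfp_c), optionally `events` (named list of
#'   event data.frames), and `ground_truth` (programmed indices).
#' @export
gen_flow_panel <- function(p, events = FALSE) {
  stopifnot(inherits(p, "panel_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)
  recs <- list(); truth <- list(); ev <- list()
  for (cs in names(p$constructs)) {
    programmed <- p$baseline_index * p$constructs[[cs]]
    for (r in seq_len(p$replicates)) {
      idx <- programmed * (1 + stats::rnorm(1, sd = p$cv))
      pe_t <- p$pe_c + idx * (p$gfp_t - p$gfp_c)
      recs <- c(recs, list(data.frame(
        construct = cs, probe = "IgM", replicate = r,
        pe_t = pe_t, pe_c = p$pe_c, gfp_t = p$gfp_t, gfp_c = p$gfp_c,
        stringsAsFactors = FALSE)))
      truth <- c(truth, list(data.frame(construct = cs, replicate = r,
                                        programmed_index = programmed,
                                        realized_index = idx)))
      if (events) {
        n <- p$n_events
        ev[[paste(cs, r, sep = "_")]] <- data.frame(
          PE = c(.rlnorm_mean(n, pe_t, p$sdlog),
                 .rlnorm_mean(n, p$pe_c, p$sdlog)),
          GFP = c(.rlnorm_mean(n, p$gfp_t, p$sdlog),
                  .rlnorm_mean(n, p$gfp_c, p$sdlog)),
          population = rep(c("transductant", "control"), each = n),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(records = do.call(rbind, recs),
              ground_truth = list(per_replicate = do.call(rbind, truth),
                                  multipliers = p$constructs,
                                  baseline_index = p$baseline_index,
                                  seed = p$seed, params = p))
  if (events) out$events <- ev
  out
}
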