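# Goodness-of-fit tables and the prediction-corrected visual predictive
# check (pcVPC) with a BLQ-fraction panel. All outputs are numeric tables;
# plotting is left to the user.

#' Goodness-of-fit table
#'
#' One row per non-BLQ observation with the population prediction (random
#' effects at zero), the individual prediction (MAP random effects) and
#' the conditional weighted residual.
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param pop A `pop_params` object (typically `fit$estimates`).
#' @return data.frame: `subject_id`, `time`, `dv`, `pred`, `ipred`,
#'   `cwres`.
#' @export
gof_table <- function(x, pop) {
  cwres(x, pop)
}

# population predictions and time-after-dose for every observation of the
# cohort, as one flat table
.obs_table <- function(x, pop) {
  rows <- lapply(x$subjects, function(s) {
    if (!nrow(s$obs)) return(NULL)
    k <- 1 + length(obs_occasions(s))
    pred <- subject_predictions(s, pop, rep(0, k))
    idx <- findInterval(s$obs$time, s$doses$time)
    idx[idx == 0] <- 1L
    data.frame(subject_id = s$subject_id, time = s$obs$time,
               tad = s$obs$time - s$doses$time[idx],
               dv = s$obs$value, blq = s$obs$blq, lloq = s$obs$lloq,
               occasion = s$obs$occasion, pred = pred, row.names = NULL)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)], list(make.row.names = FALSE)))
}

# simulate one replicate of the cohort's observation vector under pop
# (new etas per subject/occasion + residual error); returns value and blq
.simulate_replicate <- function(x, pop, lloq = 1) {
  out <- lapply(x$subjects, function(s) {
    if (!nrow(s$obs)) return(NULL)
    occs <- obs_occasions(s)
    etas <- c(stats::rnorm(1, 0, sqrt(pop$omega2_bsv)),
              stats::rnorm(length(occs), 0, sqrt(pop$omega2_bov)))
    f <- subject_predictions(s, pop, etas)
    y <- f + stats::rnorm(length(f)) * residual_sd(f, pop$sigma_prop, pop$sigma_add)
    data.frame(value = y, blq = y < lloq)
  })
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)], list(make.row.names = FALSE)))
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are normalized by
#' `bin-median population prediction / own population prediction`
#' (standard prediction correction), binned by quantiles of time after the
#' most recent dose. Per bin, the 5th/50th/95th percentiles of the
#' corrected observations are compared with 95% confidence intervals of
#' the same percentiles across model-simulated replicates; a second panel
#' compares observed and simulated BLQ fractions (censoring at the LLOQ).
#' Percentile statistics use non-BLQ records; BLQ fractions use all
#' records. Bins with fewer than 3 observations are merged with their
#' neighbor (logged in the result).
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param pop A `pop_params` object.
#' @param n_sim Number of simulated replicates (default 500).
#' @param n_bins Number of time-after-dose bins requested (default 8).
#' @param seed Integer seed.
#' @param lloq Censoring limit for the simulated values, mg/L.
#' @return A `vpc_result`: `bins` (per-bin table with observed percentiles,
#'   simulated CIs, and BLQ fractions with CIs), `n_sim`, `merged_bins`.
#' @export
pcvpc <- function(x, pop, n_sim = 500, n_bins = 8, seed = 1L, lloq = 1) {
  stopifnot(inherits(x, "vanc_cohort"), inherits(pop, "pop_params"))
  obs <- .obs_table(x, pop)
  if (is.null(obs) || !nrow(obs)) stop("no observations to check")
  # quantile binning on time after dose
  qs <- unique(stats::quantile(obs$tad, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  bin <- findInterval(obs$tad, qs, rightmost.closed = TRUE, all.inside = TRUE)
  # merge undersized bins (count of non-BLQ records) into the left neighbor
  merged <- 0L
  repeat {
    counts <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(counts)[counts < 3]
    if (!length(small) || length(counts) == 1) break
    b <- as.integer(small[1])
    lv <- sort(unique(bin))
    tgt <- if (b == lv[1]) lv[2] else lv[which(lv == b) - 1]
    bin[bin == b] <- tgt
    merged <- merged + 1L
  }
  bin <- as.integer(factor(bin))
  nb <- max(bin)
  binmed <- vapply(split(obs$pred, bin), stats::median, 0)
  corr <- binmed[bin] / obs$pred
  pc_obs <- obs$dv * corr
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(seq_len(nb), function(b) {
    sel <- bin == b & !obs$blq
    if (!any(sel)) rep(NA_real_, 3) else stats::quantile(pc_obs[sel], probs, names = FALSE)
  }, numeric(3)))
  sim_pct <- array(NA_real_, c(n_sim, nb, 3))
  sim_blq <- matrix(NA_real_, n_sim, nb)
  with_seed(seed, for (r in seq_len(n_sim)) {
    rep_df <- .simulate_replicate(x, pop, lloq = lloq)
    pc_sim <- rep_df$value * corr
    for (b in seq_len(nb)) {
      sel <- bin == b & !rep_df$blq
      if (any(sel)) sim_pct[r, b, ] <- stats::quantile(pc_sim[sel], probs, names = FALSE)
      sim_blq[r, b] <- mean(rep_df$blq[bin == b])
    }
  })
  ci <- function(mat) {
    mat <- matrix(mat, nrow = n_sim) # guard against dropped dimensions
    apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  lo <- ci(sim_pct[, , 1]); md <- ci(sim_pct[, , 2]); hi <- ci(sim_pct[, , 3])
  blq_ci <- ci(sim_blq)
  bins_df <- data.frame(
    bin = seq_len(nb),
    tad_lo = vapply(split(obs$tad, bin), min, 0),
    tad_hi = vapply(split(obs$tad, bin), max, 0),
    n = as.integer(table(bin)),
    obs_p05 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
    sim_p05_lo = lo[1, ], sim_p05_hi = lo[2, ],
    sim_p50_lo = md[1, ], sim_p50_hi = md[2, ],
    sim_p95_lo = hi[1, ], sim_p95_hi = hi[2, ],
    blq_obs = vapply(seq_len(nb), function(b) mean(obs$blq[bin == b]), 0),
    blq_sim_lo = blq_ci[1, ], blq_sim_hi = blq_ci[2, ],
    row.names = NULL)
  structure(list(bins = bins_df, n_sim = n_sim, merged_bins = merged,
                 probs = probs), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("pcVPC: %d bins, %d simulated replicates (%d bins merged)\n",
              nrow(x$bins), x$n_sim, x$merged_bins))
  print(x$bins, digits = 3)
  invisible(x)
}
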