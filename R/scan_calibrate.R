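# Simulation-based significance thresholds, peak calling, QC masking,
# power/ROC evaluation and neutral z-scores.

#' Neutral genome-wide significance threshold
#'
#' The threshold is an upper order statistic of neutral-simulation G12
#' values: with the reference design of 58,350 neutral replicates (10x the
#' number of independent analysis windows) the fifth highest value is used.
#' For other replicate counts the rank scales proportionally,
#' `k = max(1, round(5 * n / 58350))`, unless `k` is given explicitly.
#'
#' @param neutral_values per-replicate neutral G12 values (one 201-SNP window
#'   per replicate).
#' @param k order-statistic rank (k-th highest); default scales from the
#'   reference design.
#' @param k_reference,n_reference the reference design (5 and 58,350).
#' @return The threshold (a G12 value).
#' @export
neutral_threshold <- function(neutral_values, k = NULL,
                              k_reference = 5L, n_reference = 58350L) {
  n <- length(neutral_values)
  if (n < 1) stop("need at least one neutral value")
  if (is.null(k)) k <- max(1L, as.integer(round(k_reference * n / n_reference)))
  if (k > n) stop("order-statistic rank k = ", k, " exceeds n = ", n)
  sort(neutral_values, decreasing = TRUE)[k]
}

#' QC mask parameters
#'
#' @param recomb_percentile windows whose mean recombination rate falls in
#'   this lowest percentile genome-wide are masked (default 5).
#' @param missing_iqr_mult missingness rule: mask windows with mean missing
#'   fraction above `Q3 + missing_iqr_mult * IQR` (default 0.75).
#' @param cross_pop_top_k windows inside a top-k peak in *every* supplied
#'   population are masked (default 20).
#' @return An object of class `QcMaskParams`.
#' @export
qc_mask_params <- function(recomb_percentile = 5, missing_iqr_mult = 0.75,
                           cross_pop_top_k = 20L) {
  if (recomb_percentile <= 0 || recomb_percentile >= 100)
    stop("recomb_percentile must lie in (0, 100)")
  structure(list(recomb_percentile = recomb_percentile,
                 missing_iqr_mult = missing_iqr_mult,
                 cross_pop_top_k = as.integer(cross_pop_top_k)),
            class = "QcMaskParams")
}

#' Apply quality-control masks to a scan track
#'
#' Three masks against spurious sweep signals, flagged separately and
#' combined: (a) mean per-window recombination rate in the lowest
#' `recomb_percentile` of all windows (type-1 empirical quantile, boundary
#' included); (b) mean missing fraction above `Q3 + 0.75 * IQR` of all
#' windows; (c) the window lies within a top-`cross_pop_top_k` peak (ranked
#' by representative G12) in **every** supplied population -- a signal shared
#' across populations of very different ancestry and age is almost certainly
#' a data artifact.  Rule (c) needs at least two populations and is skipped
#' with a warning otherwise; rule (a) is skipped with a warning when the
#' track has no recombination rates.
#'
#' @param track a [scan_g12()] track.
#' @param params a [qc_mask_params()].
#' @param cross_pop_peaks optional list (length >= 2) of peak tables from
#'   [call_peaks()], one per comparison population.
#' @return The track with `mask_recomb`, `mask_missing`, `mask_crosspop` and
#'   `masked` filled in.
#' @export
qc_masks <- function(track, params = qc_mask_params(), cross_pop_peaks = NULL) {
  if (all(is.na(track$mean_recomb))) {
    if (params$recomb_percentile > 0)
      warning("track has no recombination rates; low-recombination mask skipped")
    track$mask_recomb <- FALSE
  } else {
    cut <- quantile(track$mean_recomb, params$recomb_percentile / 100,
                    type = 1, na.rm = TRUE)
    track$mask_recomb <- !is.na(track$mean_recomb) & track$mean_recomb <= cut
  }
  q3 <- quantile(track$mean_missing, 0.75)
  iqr <- q3 - quantile(track$mean_missing, 0.25)
  track$mask_missing <- track$mean_missing > q3 + params$missing_iqr_mult * iqr

  track$mask_crosspop <- FALSE
  if (!is.null(cross_pop_peaks)) {
    if (length(cross_pop_peaks) < 2) {
      warning("cross-population mask skipped: fewer than 2 peak sets supplied")
    } else {
      inside_all <- rep(TRUE, nrow(track))
      for (pk in cross_pop_peaks) {
        top <- head(pk[order(-pk$representative_g12), , drop = FALSE],
                    params$cross_pop_top_k)
        inside <- rep(FALSE, nrow(track))
        for (i in seq_len(nrow(top))) {
          inside <- inside | (track$chromosome == top$chromosome[i] &
                              track$focal_pos >= top$bp_first[i] &
                              track$focal_pos <= top$bp_last[i])
        }
        inside_all <- inside_all & inside
      }
      track$mask_crosspop <- inside_all
    }
  }
  track$masked <- track$mask_recomb | track$mask_missing | track$mask_crosspop
  track
}

#' Call peaks from a scan track
#'
#' Maximal runs of consecutive super-threshold focal SNPs form one peak each
#' ("consecutive" in focal-index space: adjacent track rows of the same
#' chromosome; masked windows break runs).  Implemented as seed-and-extend: a
#' greedy clumping that repeatedly takes the highest unconsumed
#' super-threshold window and extends it upstream and downstream over
#' contiguous super-threshold neighbors -- equivalent to maximal-run merging.
#' The representative G12 of a peak is the maximum over its member windows.
#'
#' @param track a [scan_g12()] track (apply [qc_masks()] first).
#' @param threshold the neutral threshold; windows strictly above it count.
#' @return data.frame with one row per peak: chromosome, first/last focal SNP
#'   index and bp, member window count, representative G12.  Zero rows when
#'   nothing exceeds the threshold.
#' @export
call_peaks <- function(track, threshold) {
  res <- list()
  for (chr in unique(track$chromosome)) {
    d <- track[track$chromosome == chr, , drop = FALSE]
    above <- !d$masked & d$g12 > threshold
    consumed <- rep(FALSE, nrow(d))
    g <- ifelse(above, d$g12, -Inf)
    while (any(above & !consumed)) {
      cand <- which(above & !consumed)
      seed <- cand[which.max(g[cand])]
      lo <- seed
      while (lo > 1 && above[lo - 1]) lo <- lo - 1
      hi <- seed
      while (hi < nrow(d) && above[hi + 1]) hi <- hi + 1
      consumed[lo:hi] <- TRUE
      res[[length(res) + 1]] <- data.frame(
        chromosome = chr,
        idx_first = d$focal_index[lo], idx_last = d$focal_index[hi],
        bp_first = d$focal_pos[lo], bp_last = d$focal_pos[hi],
        n_windows = hi - lo + 1L,
        representative_g12 = max(d$g12[lo:hi]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(chromosome = character(0), idx_first = integer(0),
                      idx_last = integer(0), bp_first = integer(0),
                      bp_last = integer(0), n_windows = integer(0),
                      representative_g12 = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$chromosome, out$bp_first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Power and ROC of sweep detection
#'
#' The detection threshold is the `1 - fdr` empirical quantile (inverse ECDF,
#' type 1) of the neutral values; the true positive rate is the fraction of
#' sweep values strictly above it, with a Wilson 95% confidence interval.
#' The ROC curve sweeps the threshold over the pooled values; AUC is the
#' trapezoid integral.
#'
#' @param sweep_values G12 values from sweep simulations.
#' @param neutral_values G12 values from neutral simulations.
#' @param fdr nominal false discovery rate (default 0.01).
#' @return List: `threshold`, `tpr`, `ci95`, `roc` (data.frame of fpr/tpr),
#'   `auc`.
#' @export
power_and_roc <- function(sweep_values, neutral_values, fdr = 0.01) {
  if (length(sweep_values) == 0 || length(neutral_values) == 0)
    stop("both value lists must be non-empty")
  if (length(neutral_values) < 1 / fdr)
    warning("fewer than ", ceiling(1 / fdr),
            " neutral values: the FDR quantile is unstable")
  thr <- quantile(neutral_values, 1 - fdr, type = 1, names = FALSE)
  x <- sum(sweep_values > thr)
  n <- length(sweep_values)
  tpr <- x / n
  z <- qnorm(0.975)
  ctr <- (tpr + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(tpr * (1 - tpr) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  ts <- c(Inf, sort(unique(c(sweep_values, neutral_values)), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(ts, function(t) mean(neutral_values > t), 0),
    tpr = vapply(ts, function(t) mean(sweep_values > t), 0))
  roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(threshold = thr, tpr = tpr, ci95 = c(max(0, ctr - hw), min(1, ctr + hw)),
       roc = roc, auc = auc)
}

#' Z-scores and p-values against the neutral G12 distribution
#'
#' Standardizes G12 values by the mean and standard deviation of
#' neutral-simulation values and converts to one-sided upper-tail Gaussian
#' p-values, the input for downstream enrichment analysis.
#'
#' @param g12 numeric G12 values, or a [scan_g12()] track (columns `z` and
#'   `p` are appended).
#' @param neutral_values neutral G12 values (>= 2, non-constant).
#' @return data.frame with `g12`, `z`, `p` (or the augmented track).
#' @export
neutral_zscores <- function(g12, neutral_values) {
  if (length(neutral_values) < 2) stop("need at least 2 neutral values")
  mu <- mean(neutral_values)
  sdv <- sd(neutral_values)
  if (sdv == 0) stop("neutral values have zero variance")
  if (is.data.frame(g12)) {
    g12$z <- (g12$g12 - mu) / sdv
    g12$p <- pnorm(g12$z, lower.tail = FALSE)
    return(g12)
  }
  z <- (g12 - mu) / sdv
  data.frame(g12 = g12, z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Variance explained by window covariates
#'
#' Regresses G12 on physical window span, mean missing fraction and mean
#' recombination rate over the unmasked windows; after QC these covariates
#' should jointly explain little of the variance (under 5% in a well-behaved
#' scan).  All-NA covariates are dropped with a warning.
#'
#' @param track a [scan_g12()] track (masked windows are excluded).
#' @return The joint R-squared.
#' @export
variance_explained_diagnostic <- function(track) {
  d <- track[!track$masked, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 unmasked windows")
  d$span <- d$win_end_bp - d$win_start_bp + 1
  covs <- c("span", "mean_missing", "mean_recomb")
  drop <- vapply(covs, function(v) all(is.na(d[[v]])), TRUE)
  if (any(drop)) {
    warning("dropping all-NA covariate(s): ", paste(covs[drop], collapse = ", "))
    covs <- covs[!drop]
  }
  if (length(covs) == 0) stop("no usable covariates")
  fit <- lm(stats::reformulate(covs, response = "g12"), data = d)
  summary(fit)$r.squared
}
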