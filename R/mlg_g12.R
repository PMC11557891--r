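# Clustering of multi-site genotypes / pseudo-haplotypes within SNP windows
# and the G12 statistic.

#' Clustering parameters
#'
#' @param singleton_missing_threshold fraction in `[0, 1]`; an individual whose
#'   missing fraction within the analysis window exceeds this threshold is
#'   never clustered with others and counts as its own singleton.  The default
#'   0.9 guards against the G12 inflation produced when heavily missing rows
#'   all cluster together.  Setting it to 1 disables the rule (entirely
#'   missing rows still remain singletons: they carry no genotype to match).
#' @return An object of class `ClusteringParams`.
#' @export
clustering_params <- function(singleton_missing_threshold = 0.9) {
  m <- singleton_missing_threshold
  if (!is.numeric(m) || length(m) != 1 || m < 0 || m > 1)
    stop("singleton_missing_threshold must be a single value in [0, 1]")
  structure(list(singleton_missing_threshold = m), class = "ClusteringParams")
}

#' Scan parameters
#'
#' @param window SNPs per analysis window (default 201, odd so the focal SNP
#'   is the exact center).
#' @param jump SNPs between consecutive focal SNPs (default 1).
#' @return An object of class `ScanParams`.
#' @export
scan_params <- function(window = 201L, jump = 1L) {
  window <- as.integer(window); jump <- as.integer(jump)
  if (window < 2L) stop("window must be at least 2 SNPs")
  if (jump < 1L) stop("jump must be at least 1")
  if (window %% 2L == 0L)
    warning("even window size: the focal SNP is left of center")
  structure(list(window = window, jump = jump), class = "ScanParams")
}

#' Cluster the multi-site genotypes of one analysis window
#'
#' Greedy first-fit clustering in fixed row order: an individual joins the
#' first existing cluster whose founding row matches it at every position
#' where both calls are non-missing (missing calls are ignored for matching).
#' Individuals with a missing fraction above the singleton threshold never
#' merge and are never founded upon.  This order-dependent rule, with the
#' input row order fixed, makes the resulting cluster spectrum deterministic.
#'
#' @param window_calls integer matrix (individuals x window SNPs) over
#'   `{0,1,NA}` (pseudo-haploid) or `{0,1,2,NA}` (diploid MLG), or an
#'   `AlleleCallMatrix` whose full width is one window.
#' @param params a [clustering_params()] object.
#' @return An object of class `ClusterSpectrum`: descending cluster
#'   frequencies `q` (ties broken by cluster creation index), cluster count
#'   `n`, `sample_count`, and the per-row cluster `assignment`.
#' @export
cluster_window <- function(window_calls, params = clustering_params()) {
  if (inherits(window_calls, "AlleleCallMatrix")) window_calls <- window_calls$calls
  window_calls <- as.matrix(window_calls)
  storage.mode(window_calls) <- "integer"
  if (ncol(window_calls) == 0) stop("analysis window has zero SNPs")
  res <- cluster_window_cpp(window_calls, params$singleton_missing_threshold)
  sizes <- res$sizes
  ord <- order(-sizes, seq_along(sizes))
  q <- sizes[ord] / nrow(window_calls)
  structure(list(q = q, n = length(q), sample_count = nrow(window_calls),
                 assignment = res$assignment,
                 forced_singleton = res$forced_singleton),
            class = "ClusterSpectrum")
}

#' @export
print.ClusterSpectrum <- function(x, ...) {
  cat("ClusterSpectrum:", x$n, "clusters over", x$sample_count, "individuals\n")
  cat("  q:", paste(sprintf("%.4g", head(x$q, 8)), collapse = " "),
      if (x$n > 8) "..." else "", "\n")
  invisible(x)
}

#' G12 from a cluster spectrum
#'
#' G12 pools the two most frequent multi-site genotype clusters:
#' \deqn{G12 = (q_1 + q_2)^2 + q_3^2 + \dots + q_n^2}
#' with frequencies ranked from most common to most rare.  For a single
#' cluster (n = 1), G12 = q1^2 = 1.
#'
#' @param spectrum a [cluster_window()] result, or a numeric vector of
#'   cluster frequencies summing to 1 (sorted internally).
#' @return G12, a value in `(0, 1]`.
#' @export
g12_from_spectrum <- function(spectrum) {
  q <- if (inherits(spectrum, "ClusterSpectrum")) spectrum$q else as.numeric(spectrum)
  if (length(q) == 0 || any(q <= 0))
    stop("cluster frequencies must be positive")
  if (abs(sum(q) - 1) > 1e-8)
    stop("cluster frequencies must sum to 1 (got ", format(sum(q)), ")")
  q <- sort(q, decreasing = TRUE)
  if (length(q) == 1) return(q[1]^2)
  (q[1] + q[2])^2 + sum(q[-(1:2)]^2)
}

#' G12 of one full matrix treated as a single window
#'
#' Convenience wrapper: clusters all columns of `calls` as one analysis
#' window and returns its G12.
#'
#' @inheritParams cluster_window
#' @return G12 value.
#' @export
g12_window <- function(window_calls, params = clustering_params()) {
  g12_from_spectrum(cluster_window(window_calls, params))
}

#' Genome-wide G12 scan
#'
#' Slides a fixed-SNP-count window along each chromosome, advancing the focal
#' SNP by `jump` SNPs.  Windows are centered on the focal SNP and never
#' truncated: focal SNPs whose window would extend past either chromosome end
#' are not scanned, so every G12 is computed over exactly `window` SNPs.
#' Chromosomes with fewer SNPs than one window are skipped with a message.
#'
#' Per window the track records the mean missing fraction (mean over window
#' SNPs of the fraction of missing individuals at that SNP) and, when a
#' recombination map is supplied, the mean per-SNP recombination rate; both
#' feed the QC masks of [qc_masks()].
#'
#' @param x an [allele_call_matrix()].
#' @param params a [scan_params()] object.
#' @param clustering a [clustering_params()] object.
#' @param recomb_map optional [read_recombination_map()] result.
#' @return A `ScanTrack` data.frame, one row per focal SNP, with scan
#'   parameters stored as attributes.
#' @export
scan_g12 <- function(x, params = scan_params(),
                     clustering = clustering_params(), recomb_map = NULL) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  w <- params$window
  half <- (w - 1L) %/% 2L
  out <- list()
  for (chr in unique(x$snps$chromosome)) {
    cols <- which(x$snps$chromosome == chr)
    n <- length(cols)
    if (n < w) {
      message("chromosome ", chr, " has ", n, " SNPs (< window of ", w, "); skipped")
      next
    }
    calls <- x$calls[, cols, drop = FALSE]
    pos <- x$snps$physical_pos[cols]
    miss_frac <- colMeans(is.na(calls))
    rate <- if (!is.null(recomb_map)) recomb_rate_at(recomb_map, chr, pos)
            else rep(NA_real_, n)
    focal <- seq.int(half + 1L, n - (w - 1L - half), by = params$jump)
    g12 <- numeric(length(focal))
    mm <- numeric(length(focal))
    mr <- numeric(length(focal))
    for (k in seq_along(focal)) {
      f <- focal[k]
      idx <- (f - half):(f - half + w - 1L)
      g12[k] <- g12_window(calls[, idx, drop = FALSE], clustering)
      mm[k] <- mean(miss_frac[idx])
      mr[k] <- mean(rate[idx])
    }
    out[[chr]] <- data.frame(
      chromosome = chr, focal_index = focal, focal_pos = pos[focal],
      win_start_idx = focal - half, win_end_idx = focal - half + w - 1L,
      win_start_bp = pos[focal - half], win_end_bp = pos[focal - half + w - 1L],
      g12 = g12, mean_missing = mm, mean_recomb = mr,
      mask_recomb = FALSE, mask_missing = FALSE, mask_crosspop = FALSE,
      masked = FALSE, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no chromosome had at least one full window")
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "window") <- w
  attr(track, "jump") <- params$jump
  attr(track, "singleton_missing_threshold") <- clustering$singleton_missing_threshold
  class(track) <- c("ScanTrack", "data.frame")
  track
}
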