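# Forward Wright-Fisher simulation of neutral and sweep scenarios under
# piecewise demography, with sweep-softness bookkeeping and aDNA-style
# sampling.  The generation-by-generation engines live in src/wf.cpp; this
# file provides demography, configuration and orchestration.

#' Build a demographic model
#'
#' `"tennessen_european"` is the published European model of Tennessen et al.:
#' an ancestral size of 7310 diploids until 5920 generations before present,
#' an expansion to 14,474 (5920-2040), an out-of-Africa bottleneck of 1861
#' (2040-920), a European founder size of 1032 growing at 0.307%/generation
#' until 205 generations ago, then accelerated growth at 1.95%/generation to
#' the present (~505,000).  `"constant"` is a single epoch of size `N`.
#'
#' Rescaling by `lambda` divides sizes and times by `lambda` and multiplies
#' per-generation rates (mu, r, s, growth) by `lambda`, keeping the
#' population-scaled parameters (theta = 4*N*mu, rho, 2*N*s) invariant; it is
#' the standard device for making forward simulation tractable.
#'
#' @param model_name `"tennessen_european"` or `"constant"`.
#' @param lambda rescaling factor (>= 1).
#' @param N diploid size for the constant model.
#' @return An object of class `Demography` with an epoch table (unscaled
#'   units) and the rescaling factor.
#' @export
build_demography <- function(model_name = c("tennessen_european", "constant"),
                             lambda = 1, N = 10000) {
  model_name <- match.arg(model_name)
  if (lambda < 1) stop("lambda must be >= 1")
  if (model_name == "tennessen_european") {
    n205 <- 1032 * exp(0.00307 * (920 - 205))
    epochs <- data.frame(
      start_gen = c(Inf, 5920, 2040, 920, 205),
      end_gen = c(5920, 2040, 920, 205, 0),
      N_start = c(7310, 14474, 1861, 1032, n205),
      N_end = c(7310, 14474, 1861, n205, n205 * exp(0.0195 * 205)),
      growth_rate = c(0, 0, 0, 0.00307, 0.0195))
    anc <- 7310
    oldest <- 5920
  } else {
    if (N <= 0) stop("constant model needs N > 0")
    epochs <- data.frame(start_gen = Inf, end_gen = 0, N_start = N, N_end = N,
                         growth_rate = 0)
    anc <- N
    oldest <- 0
  }
  structure(list(model = model_name, lambda = lambda, N0 = N, epochs = epochs,
                 N_ancestral = anc / lambda,
                 oldest_gen = as.integer(ceiling(oldest / lambda))),
            class = "Demography")
}

#' Diploid population size at a (rescaled) time
#'
#' @param demography a [build_demography()] result.
#' @param t generations before present, in rescaled units.
#' @return Rescaled diploid sizes (not rounded).
#' @export
demog_size <- function(demography, t) {
  stopifnot(inherits(demography, "Demography"))
  tu <- t * demography$lambda   # unscaled generations BP
  if (demography$model == "constant") {
    n <- rep(demography$N0, length(tu))
  } else {
    n205 <- 1032 * exp(0.00307 * (920 - 205))
    n <- ifelse(tu >= 5920, 7310,
         ifelse(tu >= 2040, 14474,
         ifelse(tu >= 920, 1861,
         ifelse(tu >= 205, 1032 * exp(0.00307 * (920 - tu)),
                n205 * exp(0.0195 * (205 - tu))))))
  }
  n / demography$lambda
}

#' Configure one forward simulation
#'
#' All times and rates are given in unscaled (real-population) units; the
#' demography's `lambda` is applied internally.  The defaults reproduce the
#' simulation design used throughout the package's calibration: a 500 kb
#' chromosome with mu = 1.25e-8/bp and r = 1e-8 events/bp under the rescaled
#' (lambda = 10) European demographic model, sampling 177 diploids.
#'
#' @param mode `"neutral"`, `"hard_de_novo"` (single beneficial mutation at
#'   the chromosome center), `"recurrent"` (adaptive mutations recur at
#'   population rate theta_A/2 per generation) or `"sgv"` (a neutral central
#'   mutation introduced at `t_onset` becomes beneficial at the first
#'   generation its frequency reaches `f_init`).
#' @param s selection coefficient (additive: fitness 1, 1+s/2, 1+s).
#' @param theta_A population-scaled adaptive mutation rate (recurrent mode);
#'   held constant through time by recomputing the per-copy rate from the
#'   current population size each generation.
#' @param f_init standing-variation threshold frequency (sgv mode).
#' @param t_onset generations before present at which the (to-be-)adaptive
#'   mutation is introduced.
#' @param t_sample generations before present at which 177 diploids are drawn.
#' @param mu,r,L mutation rate per bp, recombination rate per bp, chromosome
#'   length in bp.
#' @param sample_n diploid sample size.
#' @param demography a [build_demography()] result (carries `lambda`).
#' @param burn_in `"coalescent"` (default): the population at the start of
#'   the selective phase is drawn from an exact backward Wright-Fisher
#'   coalescent with recombination under the same demography; `"forward"`:
#'   a literal neutral burn-in of 10 * N_ancestral forward generations from a
#'   monomorphic population, then neutral forward evolution to the start.
#' @param max_restarts conditioning cap: simulations restart from the
#'   initialized population when the adaptive allele is lost (or, in sgv
#'   mode, never reaches `f_init`); exceeding the cap is an error.
#' @return An object of class `SweepConfig`.
#' @export
sweep_config <- function(mode = c("neutral", "hard_de_novo", "recurrent", "sgv"),
                         s = 0.05, theta_A = 1, f_init = 0.01,
                         t_onset = 1000, t_sample = 250,
                         mu = 1.25e-8, r = 1e-8, L = 5e5, sample_n = 177,
                         demography = build_demography("tennessen_european", lambda = 10),
                         burn_in = c("coalescent", "forward"),
                         max_restarts = 1000L) {
  mode <- match.arg(mode)
  burn_in <- match.arg(burn_in)
  if (s < 0) stop("s must be >= 0")
  if (mode != "neutral" && t_sample >= t_onset)
    stop("t_sample must be earlier than t_onset (t_sample < t_onset)")
  if (mode == "sgv" && (f_init <= 0 || f_init >= 1))
    stop("f_init must lie in (0, 1)")
  structure(list(mode = mode, s = s, theta_A = theta_A, f_init = f_init,
                 t_onset = t_onset, t_sample = t_sample, mu = mu, r = r, L = L,
                 sample_n = as.integer(sample_n), demography = demography,
                 burn_in = burn_in, max_restarts = as.integer(max_restarts)),
            class = "SweepConfig")
}

new_simulated_sample <- function(hap, pos, config, adaptive_index = 0L,
                                 sampled_origins = integer(0),
                                 pop_origins = integer(0),
                                 pop_adaptive_freq = 0,
                                 onset_gen = -1L, carriers_at_onset = 0L,
                                 distinct_at_onset = 0L, attempts = 1L) {
  structure(list(haplotypes = hap, positions = pos,
                 adaptive_index = if (adaptive_index > 0) adaptive_index else NA_integer_,
                 adaptive_pos = config$L / 2,
                 sampled_origins = sampled_origins, pop_origins = pop_origins,
                 final_adaptive_freq = pop_adaptive_freq,
                 onset_gen = onset_gen, carriers_at_onset = carriers_at_onset,
                 distinct_at_onset = distinct_at_onset, attempts = attempts,
                 config = config),
            class = "SimulatedSample")
}

#' @export
print.SimulatedSample <- function(x, ...) {
  cat("SimulatedSample (", x$config$mode, "): ", nrow(x$haplotypes),
      " chromosomes x ", length(x$positions), " segregating sites\n", sep = "")
  if (x$config$mode != "neutral")
    cat("  adaptive frequency at sampling:",
        sprintf("%.3f", x$final_adaptive_freq),
        " restarts:", x$attempts - 1L, "\n")
  invisible(x)
}

#' Run one forward simulation
#'
#' Conditioning follows the simulation design the scan is calibrated for:
#' non-neutral runs restart (from the initialized population, with fresh
#' randomness) whenever the adaptive mutation is lost before the sampling
#' time, so every accepted run carries it at sampling.  Uses R's RNG
#' throughout: `set.seed()` makes runs bit-reproducible.
#'
#' @param config a [sweep_config()].
#' @return A `SimulatedSample`: a 2*sample_n x S binary haplotype matrix
#'   (consecutive row pairs are the sampled diploids), site positions in bp,
#'   the adaptive site, surviving origin labels, the standing-variation
#'   carrier snapshot at selection onset, and the restart count.
#' @export
simulate_sweep <- function(config) {
  stopifnot(inherits(config, "SweepConfig"))
  d <- config$demography
  lam <- d$lambda
  mu <- config$mu * lam
  rr <- config$r * lam
  s <- config$s * lam
  L <- config$L
  ns <- config$sample_n
  neutral <- config$mode == "neutral"
  t_smp <- as.integer(round(config$t_sample / lam))
  t_int <- as.integer(round(config$t_onset / lam))
  if (!neutral && t_int <= t_smp)
    stop("after rescaling, onset time must remain later than sampling time")
  mode_int <- match(config$mode,
                    c("neutral", "hard_de_novo", "recurrent", "sgv")) - 1L
  n2_at <- function(t) as.integer(2L * pmax(1, round(demog_size(d, t))))
  t0 <- if (neutral) t_smp else t_int

  if (config$burn_in == "coalescent") {
    n_init <- if (neutral) 2L * ns else n2_at(t0)
    back_len <- max(0L, d$oldest_gen - t0)
    n2_back <- n2_at(t0 + 0:back_len)   # index g = 2N at t0 + g generations BP
    n2_anc <- as.integer(2L * max(1, round(d$N_ancestral)))
    max_gen <- 2000 * n2_anc + back_len + 1e5
    cs <- coalescent_sample_cpp(n_init, n2_back, n2_anc, mu, rr, L, max_gen)
    ord <- order(cs$positions)
    hap <- cs$haplotypes[, ord, drop = FALSE]
    pos <- cs$positions[ord]
    if (neutral)
      return(new_simulated_sample(hap, pos, config))
    init <- lapply(seq_len(n_init), function(i) which(hap[i, ] == 1L) - 1L)
  } else {
    n2_anc <- as.integer(2L * max(1, round(d$N_ancestral)))
    burn <- as.integer(10 * round(d$N_ancestral))
    t_top <- max(d$oldest_gen, t0)
    n2A <- c(rep(n2_anc, burn), n2_at(seq(t_top, t0)))
    empty <- replicate(n2_anc, integer(0), simplify = FALSE)
    keepA <- if (neutral) ns else n2_at(t0) %/% 2L
    fwA <- forward_sim_cpp(empty, numeric(0), integer(0), n2A, mu, rr, L,
                           0L, 0, 0, 0, keepA, 1L)
    if (neutral)
      return(new_simulated_sample(fwA$haplotypes, fwA$positions, config))
    hap <- fwA$haplotypes
    pos <- fwA$positions
    n_init <- nrow(hap)
    init <- lapply(seq_len(n_init), function(i) which(hap[i, ] == 1L) - 1L)
  }

  n2_fwd <- n2_at(seq(t0, t_smp))
  fw <- forward_sim_cpp(init, pos, rep(-1L, length(pos)), n2_fwd, mu, rr, L,
                        mode_int, s, config$theta_A, config$f_init, ns,
                        config$max_restarts)
  new_simulated_sample(fw$haplotypes, fw$positions, config,
                       adaptive_index = fw$adaptive_index,
                       sampled_origins = fw$sampled_origins,
                       pop_origins = fw$pop_origins,
                       pop_adaptive_freq = fw$pop_adaptive_freq,
                       onset_gen = fw$onset_gen,
                       carriers_at_onset = fw$carriers_at_onset,
                       distinct_at_onset = fw$distinct_at_onset,
                       attempts = fw$attempts)
}

#' Classify sweep softness
#'
#' Recurrent-mutation sweeps are soft when two or more independent mutational
#' origins of the adaptive allele survive at sampling; standing-variation
#' sweeps are soft when two or more distinct haplotypes carried the adaptive
#' mutation at the onset of selection; single-introduction (hard de novo)
#' sweeps are hard by construction.  Origins are counted among the sampled
#' adaptive copies, falling back to the whole population when the sample
#' happens to carry none.
#'
#' @param sample a non-neutral [simulate_sweep()] result.
#' @return List with `origins_at_sampling`,
#'   `distinct_carrier_haplotypes_at_onset` (NA outside sgv mode) and
#'   `label` (`"hard"` or `"soft"`).
#' @export
classify_softness <- function(sample) {
  stopifnot(inherits(sample, "SimulatedSample"))
  mode <- sample$config$mode
  if (mode == "neutral")
    stop("softness is undefined for neutral simulations")
  origins <- length(sample$sampled_origins)
  if (origins == 0L) origins <- length(sample$pop_origins)
  distinct <- if (mode == "sgv") sample$distinct_at_onset else NA_integer_
  label <- switch(mode,
                  hard_de_novo = "hard",
                  recurrent = if (origins >= 2L) "soft" else "hard",
                  sgv = if (isTRUE(distinct >= 2L)) "soft" else "hard")
  list(origins_at_sampling = origins,
       distinct_carrier_haplotypes_at_onset = distinct,
       label = label)
}

#' Turn a simulated sample into a pseudo-haploid analysis window
#'
#' Pairs the sampled chromosomes into `sample_n` diploids, optionally
#' pseudo-haploidizes them, and uniformly subsamples `n_snps` segregating
#' sites without replacement (genomic order preserved) to emulate the SNP
#' sparsity of capture-array aDNA data; per-SNP missingness can then be
#' injected.  Sites whose continuous simulated positions fall in the same
#' integer bp after discretization are collapsed to the first.
#'
#' @param sample a [simulate_sweep()] result.
#' @param n_snps SNPs to retain (default 201, one analysis window).
#' @param pseudo pseudo-haploidize? (set FALSE to keep the diploid MLG
#'   window, e.g. to compare both representations).
#' @param missingness optional [fit_missingness_model()] to inject.
#' @return An [allele_call_matrix()] of `sample_n` individuals x `n_snps`
#'   sites.
#' @export
sample_to_pseudohap_window <- function(sample, n_snps = 201L, pseudo = TRUE,
                                       missingness = NULL) {
  stopifnot(inherits(sample, "SimulatedSample"))
  hap <- sample$haplotypes
  np <- nrow(hap) %/% 2L
  geno <- hap[seq.int(1L, 2L * np, 2L), , drop = FALSE] +
          hap[seq.int(2L, 2L * np, 2L), , drop = FALSE]
  bp <- as.integer(floor(sample$positions)) + 1L
  keep <- !duplicated(bp)
  geno <- geno[, keep, drop = FALSE]
  bp <- bp[keep]
  S <- length(bp)
  if (S < n_snps)
    stop("only ", S, " segregating sites (< ", n_snps,
         "); increase L or the mutation rate")
  idx <- sort(sample.int(S, n_snps))
  geno <- geno[, idx, drop = FALSE]
  bp <- bp[idx]
  snps <- data.frame(snp_id = paste0("sim_", bp), chromosome = "sim1",
                     genetic_pos = bp * sample$config$r,
                     physical_pos = bp,
                     allele_ref = "G", allele_alt = "A",  # placeholder letters
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("ind", seq_len(np)),
                        group_label = "sim", stringsAsFactors = FALSE)
  acm <- allele_call_matrix(geno, snps, samples, "diploid_mlg")
  if (pseudo) acm <- pseudo_haploidize(acm)
  if (!is.null(missingness)) acm <- inject_missingness(acm, missingness)
  acm
}

#' Expected physical footprint of a hard sweep
#'
#' The genomic extent over which a hard selective sweep depresses diversity,
#' `s / (ln(Ne * s) * r)` base pairs (natural log, as in the classical
#' hitchhiking literature).  With 201-SNP windows spanning roughly 490 kb,
#' sweeps with s >= 0.04 are expected to be detectable.
#'
#' @param s selection coefficient.
#' @param N_e effective population size.
#' @param r recombination rate per bp per generation.
#' @return Extent in bp.
#' @export
expected_footprint <- function(s, N_e, r) {
  if (N_e * s <= 1) stop("N_e * s must exceed 1 (log non-positive)")
  s / (log(N_e * s) * r)
}
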