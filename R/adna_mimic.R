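# Transforms that make modern diploid genotype matrices mimic ancient DNA:
# panel ascertainment (geno_io), deamination damage, beta-distributed per-SNP
# missingness, and pseudo-haploidization, plus a missingness diagnostic.

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Emulates ancient-DNA genotype calling, where one read mapping to a
#' position is chosen at random and its allele used as the genotype: a
#' homozygote keeps its allele (0 -> 0 copies of the counted allele, 2 -> 1),
#' a heterozygote draws one of its two alleles with probability 1/2, and
#' missing stays missing.  Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param x a diploid-MLG [allele_call_matrix()].
#' @return A pseudo-haploid [allele_call_matrix()].
#' @export
pseudo_haploidize <- function(x) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  if (x$ploidy_mode == "pseudo_haploid")
    stop("matrix is already pseudo-haploid; refusing to haploidize twice")
  m <- x$calls
  out <- m
  out[m == 2L] <- 1L
  het <- which(m == 1L)
  if (length(het))
    out[het] <- as.integer(runif(length(het)) < 0.5)
  allele_call_matrix(out, x$snps, x$samples, "pseudo_haploid")
}

#' Fit the beta missingness model by the method of moments
#'
#' Per-SNP missing-data fractions are modeled as Beta(alpha, beta) with the
#' given mean and standard deviation (defaults follow the per-SNP missingness
#' observed in large ancient-DNA compilations: mean 0.55, sd 0.23).  Method
#' of moments: `alpha + beta = mu(1-mu)/sigma^2 - 1`, `alpha = mu(alpha+beta)`.
#' A zero mean yields a degenerate no-missingness model; a near-zero sd is
#' capped (shapes at 1e6) with a warning.
#'
#' @param mean mean per-SNP missing fraction in `[0, 1)`.
#' @param sd standard deviation; must satisfy `sd^2 < mean(1-mean)`.
#' @return An object of class `MissingnessModel`.
#' @export
fit_missingness_model <- function(mean = 0.55, sd = 0.23) {
  if (mean == 0) {
    return(structure(list(mean = 0, sd = 0, alpha = NA_real_, beta = NA_real_,
                          none = TRUE), class = "MissingnessModel"))
  }
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)")
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible moments: sd^2 = ", sd^2, " must be < mean(1-mean) = ",
         mean * (1 - mean))
  ab <- mean * (1 - mean) / sd^2 - 1
  alpha <- mean * ab
  beta <- ab - alpha
  if (alpha > 1e6 || beta > 1e6) {
    warning("near-degenerate sd: beta shapes capped at 1e6")
    scl <- 1e6 / max(alpha, beta)
    alpha <- alpha * scl
    beta <- beta * scl
  }
  structure(list(mean = mean, sd = sd, alpha = alpha, beta = beta, none = FALSE),
            class = "MissingnessModel")
}

#' Draw per-SNP missing fractions from a fitted missingness model
#'
#' Beta draws truncated to `[1e-6, 1 - 1e-6]` so no SNP is deterministically
#' all-missing or all-called.
#'
#' @param model a [fit_missingness_model()] result.
#' @param n number of SNPs.
#' @return Numeric vector of per-SNP missing fractions.
#' @export
draw_missing_fractions <- function(model, n) {
  stopifnot(inherits(model, "MissingnessModel"))
  if (isTRUE(model$none)) return(rep(0, n))
  pmin(pmax(rbeta(n, model$alpha, model$beta), 1e-6), 1 - 1e-6)
}

#' Inject per-SNP missingness
#'
#' For each SNP a missing fraction is drawn from the beta model; each
#' individual's call at that SNP is then set to missing independently with
#' that probability.  Already-missing calls remain missing.  The drawn
#' per-SNP fractions are attached as attribute `"missing_fractions"` for
#' diagnostics such as [missingness_autocorrelation()].
#'
#' @param x an [allele_call_matrix()] (any ploidy mode).
#' @param model a [fit_missingness_model()] result.
#' @return The matrix with added missingness.
#' @export
inject_missingness <- function(x, model) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  p <- draw_missing_fractions(model, ncol(x$calls))
  m <- x$calls
  if (!isTRUE(model$none)) {
    u <- matrix(runif(length(m)), nrow = nrow(m))
    m[u < rep(p, each = nrow(m))] <- NA_integer_
  }
  out <- allele_call_matrix(m, x$snps, x$samples, x$ploidy_mode)
  attr(out, "missing_fractions") <- p
  out
}

#' Damage scheme
#'
#' @param stride positions between modified sites (default 100).
#' @return An object of class `DamageScheme`.
#' @export
damage_scheme <- function(stride = 100L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(stride = stride, substitution = "C>T"), class = "DamageScheme")
}

#' Apply cytosine-deamination damage
#'
#' Emulates the dominant post-mortem aDNA substitution, C to T.  For each
#' individual, that individual's non-missing called positions are walked in
#' genomic order and every `stride`-th one (ranks stride, 2*stride, ...) is
#' inspected: if the call includes a C allele and the SNP's other allele is T,
#' the call is flipped to the all-T genotype; otherwise it is left unchanged.
#' The per-individual flip counts are attached as attribute `"damage_flips"`.
#'
#' @param x an [allele_call_matrix()] whose SNP table carries allele letters.
#' @param scheme a [damage_scheme()].
#' @return The damaged matrix.
#' @export
apply_damage <- function(x, scheme = damage_scheme()) {
  stopifnot(inherits(x, "AlleleCallMatrix"))
  ref <- x$snps$allele_ref
  alt <- x$snps$allele_alt
  if (any(is.na(ref)) || any(is.na(alt)))
    stop("SNP table lacks allele letters; cannot resolve calls to nucleotides")
  full <- if (x$ploidy_mode == "diploid_mlg") 2L else 1L
  m <- x$calls
  flips <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    called <- which(!is.na(m[i, ]))
    ranks <- seq.int(scheme$stride, length(called), by = scheme$stride)
    for (j in called[ranks]) {
      v <- m[i, j]
      has_c <- (ref[j] == "C" && v > 0L) || (alt[j] == "C" && v < full)
      if (!has_c) next
      if (ref[j] == "T") {
        if (v != full) { m[i, j] <- full; flips[i] <- flips[i] + 1L }
      } else if (alt[j] == "T") {
        if (v != 0L) { m[i, j] <- 0L; flips[i] <- flips[i] + 1L }
      }
    }
  }
  out <- allele_call_matrix(m, x$snps, x$samples, x$ploidy_mode)
  attr(out, "damage_flips") <- flips
  out
}

#' Positional autocorrelation of per-SNP missingness
#'
#' Standard sample autocorrelation of the per-SNP missing-individual
#' fractions at lags 1..`max_lag`, used to check that missingness along the
#' genome behaves like an uncorrelated random process (values below ~0.2 in
#' the data motivate the i.i.d. beta model).
#'
#' @param per_snp_fractions numeric vector of per-SNP missing fractions, in
#'   genomic order.
#' @param max_lag largest lag.
#' @return Numeric vector of autocorrelations at lags 1..`max_lag`; NaN with
#'   a warning for a constant series.
#' @export
missingness_autocorrelation <- function(per_snp_fractions, max_lag = 10L) {
  n <- length(per_snp_fractions)
  if (n < max_lag + 2) stop("need at least max_lag + 2 SNPs")
  if (var(per_snp_fractions) == 0) {
    warning("constant missingness series: autocorrelation undefined")
    return(rep(NaN, max_lag))
  }
  a <- acf(per_snp_fractions, lag.max = max_lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf)[2:(max_lag + 1)]
}

#' Full ancient-DNA mimicking pipeline
#'
#' Applies, in a fixed order, the transforms that turn a modern diploid
#' matrix into aDNA-like pseudo-haploid data: panel ascertainment (optional),
#' deamination damage, beta missingness, pseudo-haploidization.  With a fixed
#' seed the pipeline is bit-exactly reproducible.
#'
#' @param x a diploid-MLG [allele_call_matrix()].
#' @param panel optional panel data.frame for [ascertain_to_panel()].
#' @param missingness a [fit_missingness_model()] result.
#' @param damage a [damage_scheme()], or NULL to skip damage.
#' @param seed optional master seed for the stochastic stages.
#' @return A pseudo-haploid [allele_call_matrix()].
#' @export
mimic_adna <- function(x, panel = NULL, missingness = fit_missingness_model(),
                       damage = damage_scheme(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(panel)) x <- ascertain_to_panel(x, panel)
  if (!is.null(damage)) x <- apply_damage(x, damage)
  x <- inject_missingness(x, missingness)
  pseudo_haploidize(x)
}
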