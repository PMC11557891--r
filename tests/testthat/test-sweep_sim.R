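test_that("demography builder: constant epoch, rescaling identities, published shape", {
  d <- build_demography("constant", lambda = 1, N = 1000)
  expect_equal(nrow(d$epochs), 1)
  expect_equal(demog_size(d, c(0, 100, 1e6)), rep(1000, 3))

  # rescaling: sizes and times / lambda, so theta = 4 N mu is invariant
  d10 <- build_demography("tennessen_european", lambda = 10)
  d1 <- build_demography("tennessen_european", lambda = 1)
  expect_equal(demog_size(d10, 592), demog_size(d1, 5920) / 10)
  expect_equal(demog_size(d10, 50), demog_size(d1, 500) / 10)
  expect_equal(4 * demog_size(d10, 50) * (1.25e-8 * 10),
               4 * demog_size(d1, 500) * 1.25e-8)

  # epoch table is ordered old -> young and ends with recent growth
  ep <- d1$epochs
  expect_true(all(diff(ep$end_gen) < 0))
  expect_gt(ep$growth_rate[nrow(ep)], 0)
  expect_gt(ep$N_end[nrow(ep)], 4e5)        # strong recent expansion
  expect_equal(demog_size(d1, 5921), 7310)  # ancestral size
  expect_equal(demog_size(d1, 1000), 1861)  # out-of-Africa bottleneck
  # continuity at the growth-phase boundary
  expect_equal(demog_size(d1, 205.0001), demog_size(d1, 204.9999),
               tolerance = 1e-3)
  expect_error(build_demography("unknown_model"), "arg")
})

test_that("expected sweep footprint follows s / (ln(Ne s) r)", {
  expect_equal(expected_footprint(0.04, 1e5, 1e-8), 0.04 / (log(4000) * 1e-8))
  expect_equal(expected_footprint(0.04, 1e5, 1e-8) / 1e5, 4.82, tolerance = 0.01)
  expect_equal(expected_footprint(0.05, 1e4, 1e-8), 804554, tolerance = 1e-4)
  expect_error(expected_footprint(1e-4, 1e4, 1e-8), "exceed 1")
})

test_that("neutral segregating sites match Watterson's expectation", {
  set.seed(301)
  d <- build_demography("constant", lambda = 1, N = 500)
  cfg <- sweep_config("neutral", demography = d, sample_n = 25, t_sample = 0)
  S <- replicate(60, length(simulate_sweep(cfg)$positions))
  n <- 50
  theta <- 4 * 500 * 1.25e-8 * 5e5
  ES <- theta * sum(1 / (1:(n - 1)))
  varS <- ES + theta^2 * sum(1 / (1:(n - 1))^2)
  z <- (mean(S) - ES) / sqrt(varS / 60)
  expect_lt(abs(z), 3.5)
})

test_that("coalescent and literal forward burn-in give equivalent diversity", {
  pi_of <- function(s) {
    h <- s$haplotypes
    f <- colMeans(h)
    n <- nrow(h)
    sum(2 * f * (1 - f)) * n / (n - 1)
  }
  d <- build_demography("constant", lambda = 1, N = 100)
  cfgC <- sweep_config("neutral", demography = d, sample_n = 20, t_sample = 0,
                       burn_in = "coalescent")
  cfgF <- sweep_config("neutral", demography = d, sample_n = 20, t_sample = 0,
                       burn_in = "forward")
  set.seed(302)
  piC <- replicate(60, pi_of(simulate_sweep(cfgC)))
  piF <- replicate(60, pi_of(simulate_sweep(cfgF)))
  se <- sqrt(var(piC) / 60 + var(piF) / 60)
  expect_lt(abs(mean(piC) - mean(piF)), 4 * se)
  # both near the theoretical theta_pi = 4 N mu L
  expect_lt(abs(mean(piC) - 2.5), 0.5)
  expect_lt(abs(mean(piF) - 2.5), 0.5)
})

test_that("neutral diversity is invariant under rescaling (theta preserved)", {
  pi_of <- function(s) {
    h <- s$haplotypes
    f <- colMeans(h)
    sum(2 * f * (1 - f)) * nrow(h) / (nrow(h) - 1)
  }
  set.seed(303)
  c1 <- sweep_config("neutral", demography = build_demography("constant", 1, N = 200),
                     sample_n = 15, t_sample = 0)
  c5 <- sweep_config("neutral", demography = build_demography("constant", 5, N = 200),
                     sample_n = 15, t_sample = 0)
  pi1 <- replicate(200, pi_of(simulate_sweep(c1)))
  pi5 <- replicate(200, pi_of(simulate_sweep(c5)))
  ks <- suppressWarnings(stats::ks.test(pi1, pi5))
  expect_gt(ks$p.value, 0.05)
})

test_that("hard sweeps are conditioned on establishment and fix under strong selection", {
  set.seed(304)
  d <- build_demography("constant", lambda = 1, N = 1000)
  cfg <- sweep_config("hard_de_novo", s = 0.1, t_onset = 1000, t_sample = 5,
                      demography = d, sample_n = 30)
  x <- simulate_sweep(cfg)
  expect_gt(x$final_adaptive_freq, 0)     # conditioning contract
  expect_gt(x$final_adaptive_freq, 0.99)  # 2 N s >> 1, long duration: fixation
  expect_gte(x$attempts, 1)
  sf <- classify_softness(x)
  expect_equal(sf$label, "hard")
  expect_equal(sf$origins_at_sampling, 1)
})

test_that("softness classification follows origin and carrier-haplotype counts", {
  d <- build_demography("constant", lambda = 1, N = 300)
  set.seed(305)
  neutral <- simulate_sweep(sweep_config("neutral", demography = d,
                                         sample_n = 20, t_sample = 0))
  expect_error(classify_softness(neutral), "undefined")

  # sgv with f_init below 1/2N: onset at introduction, single carrier -> hard
  cfg <- sweep_config("sgv", s = 0.2, f_init = 1e-4, t_onset = 100,
                      t_sample = 5, demography = d, sample_n = 20)
  x <- simulate_sweep(cfg)
  expect_equal(x$carriers_at_onset, 1L)
  expect_equal(x$distinct_at_onset, 1L)
  expect_equal(classify_softness(x)$label, "hard")

  # recurrent mode with high theta_A: multiple surviving origins -> soft
  set.seed(306)
  cfg2 <- sweep_config("recurrent", s = 0.2, theta_A = 10, t_onset = 200,
                       t_sample = 5, demography = d, sample_n = 20)
  x2 <- simulate_sweep(cfg2)
  sf2 <- classify_softness(x2)
  expect_gte(sf2$origins_at_sampling, 2)
  expect_equal(sf2$label, "soft")
})

test_that("the fraction of soft sweeps rises with theta_A and with f_init", {
  d <- build_demography("constant", lambda = 1, N = 300)
  soft_frac <- function(cfg, n, seed) {
    set.seed(seed)
    mean(replicate(n, classify_softness(simulate_sweep(cfg))$label == "soft"))
  }
  fr <- vapply(c(0.1, 1, 10), function(th) {
    soft_frac(sweep_config("recurrent", s = 0.2, theta_A = th, t_onset = 200,
                           t_sample = 5, demography = d, sample_n = 20),
              40, 307)
  }, 0)
  expect_true(all(diff(fr) >= 0))
  expect_lt(fr[1], fr[3])

  fm <- vapply(c(1e-4, 0.05), function(f) {
    soft_frac(sweep_config("sgv", s = 0.2, f_init = f, t_onset = 200,
                           t_sample = 5, demography = d, sample_n = 20,
                           max_restarts = 5000), 30, 308)
  }, 0)
  expect_true(all(diff(fm) >= 0))
  expect_lt(fm[1], fm[2])
})

test_that("simulated samples convert to 177 x 201 pseudo-haploid windows", {
  set.seed(309)
  s <- simulate_sweep(sweep_config("neutral", t_sample = 40))
  w <- sample_to_pseudohap_window(s, 201)
  expect_equal(dim(w$calls), c(177L, 201L))
  expect_equal(w$ploidy_mode, "pseudo_haploid")
  expect_true(all(diff(w$snps$physical_pos) > 0))

  # without pseudo-haploidization, retained sites keep their exact frequencies
  set.seed(310)
  dip <- sample_to_pseudohap_window(s, 201, pseudo = FALSE)
  full_dose <- s$haplotypes[seq(1, 353, 2), ] + s$haplotypes[seq(2, 354, 2), ]
  full_bp <- as.integer(floor(s$positions)) + 1L
  for (j in c(1, 50, 201)) {
    col <- match(dip$snps$physical_pos[j], full_bp)
    expect_equal(mean(dip$calls[, j]), mean(full_dose[, col]))
  }

  # fixed seed reproducibility of the subsample and haploidization
  set.seed(311); a <- sample_to_pseudohap_window(s, 201)
  set.seed(311); b <- sample_to_pseudohap_window(s, 201)
  expect_identical(a$calls, b$calls)

  # too few segregating sites is an error suggesting larger L
  tiny <- s
  tiny$haplotypes <- s$haplotypes[, 1:50]
  tiny$positions <- s$positions[1:50]
  expect_error(sample_to_pseudohap_window(tiny, 201), "increase L")
})

test_that("sweep configuration validates its invariants", {
  expect_error(sweep_config("hard_de_novo", t_onset = 100, t_sample = 200),
               "earlier")
  expect_error(sweep_config("hard_de_novo", s = -0.1), "s must")
  expect_error(sweep_config("sgv", f_init = 0), "f_init")
  expect_error(build_demography("constant", lambda = 0.5), "lambda")
})
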