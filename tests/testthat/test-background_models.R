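test_that("pmf matches the closed form and sums to one", {
  for (pars in list(c(2, 0.4), c(0.5, 0.7), c(10, 0.1), c(1, 0.5))) {
    m <- nb_params(pars[1], pars[2], "mle", 0)
    # pmf equals the explicit binomial-coefficient form
    x <- 0:50
    expect_equal(nb_pmf(x, m), oracle_nb_pmf(x, pars[1], pars[2]),
                 tolerance = 1e-12)
    # sums to 1 over the support up to the (1 - 1e-12) quantile
    hi <- stats::qnbinom(1 - 1e-12, size = pars[1], prob = 1 - pars[2])
    expect_lt(abs(sum(nb_pmf(0:hi, m)) - 1), 1e-9)
    # moment identities of the parameterization
    expect_equal(m$mu, pars[1] * pars[2] / (1 - pars[2]))
    expect_equal(m$var_mean_ratio, 1 / (1 - pars[2]))
  }
})

test_that("fit_nb recovers known parameters and agrees with a grid-search
           oracle", {
  counts <- with_seed(101, rnbinom(20000, size = 2, prob = 1 - 0.4))
  fit <- fit_nb(counts)
  expect_equal(fit$fit_method, "mle")
  expect_lt(abs(fit$r - 2) / 2, 0.05)
  expect_lt(abs(fit$p - 0.4) / 0.4, 0.05)
  expect_gt(fit$var_mean_ratio, 1)
  # independent coarse grid-search MLE lands at the same optimum
  g <- oracle_grid_mle(counts, r_range = c(0.5, 8), p_range = c(0.1, 0.7))
  expect_lte(abs(g$ll - fit$loglik), 0.05)
  expect_lt(abs(g$r - fit$r) / fit$r, 0.10)
  # fitted likelihood is never below the moments estimate's
  mom <- capture3c:::nb_moments(mean(counts), var(counts))
  ll_mom <- sum(dnbinom(counts, size = mom$r, prob = 1 - mom$p, log = TRUE))
  expect_gte(fit$loglik, ll_mom)
})

test_that("fit_nb error shrinks with sample size (consistency)", {
  err <- vapply(c(1e3, 1e5), function(n) {
    f <- fit_nb(with_seed(7, rnbinom(n, size = 2, prob = 0.6)))
    abs(f$r - 2)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("degenerate and underdispersed samples use fallbacks", {
  expect_warning(z <- fit_nb(rep(0L, 100)), "degenerate")
  expect_equal(z$fit_method, "degenerate")
  # Poisson data: var ~ mean -> fallback with Poisson semantics
  pois <- with_seed(5, rpois(5000, 0.01))
  f <- fit_nb(pois)
  expect_true(f$fit_method %in% c("poisson_fallback", "mle"))
  if (f$fit_method == "poisson_fallback") {
    expect_equal(f$mu, mean(pois))
    expect_equal(nb_cdf(3, f), ppois(3, mean(pois)))
  }
  expect_error(fit_nb(c(1L, 2L)), "at least")
  expect_error(fit_nb(c(rep(0L, 30), -1L)), "non-negative")
})

test_that("sample_intra_pairs is seeded, excludes the bait, handles
           empty background", {
  sim <- default_sim()
  cl <- classify_pets(sim$pets, sim$truth$bait)
  g <- bin_grid(sim$config$chrom_sizes, sim$truth$bait)
  a <- sample_intra_pairs(cl$pets, g, d = 1, n = 2000, seed = 3)
  b <- sample_intra_pairs(cl$pets, g, d = 1, n = 2000, seed = 3)
  expect_identical(a, b)                       # byte-identical under seed
  expect_false(identical(a, sample_intra_pairs(cl$pets, g, 1, 2000, 4)))
  # no background PETs -> all-zero counts
  none <- cl$pets[category == "self_ligated"]
  z <- sample_intra_pairs(none, g, d = 2, n = 500, seed = 1)
  expect_equal(z, integer(500))
  # chromosome shorter than (d+1) bins -> empty sample
  tiny <- bait_region("chr1", 0, 2500)
  gt <- bin_grid(c(chr1 = 10000, chr2 = 1e7), tiny)
  expect_length(sample_intra_pairs(cl$pets, gt, d = 10, n = 100, seed = 1), 0)
})

test_that("intra background has one stratum per d up to the cutoff and
           decaying means", {
  sim <- default_sim()
  # backgrounds are fitted on deduplicated PETs (the pipeline contract);
  # duplicates would inflate both mean and dispersion
  cl <- classify_pets(dedup_pets(sim$pets), sim$truth$bait)
  g <- bin_grid(sim$config$chrom_sizes, sim$truth$bait)
  bg <- build_intra_background(cl$pets, g, n = 5000, seed = 17)
  # l = 2500: strata at d in 1..8 (8 * 2500 = 20000 <= D_max inclusive)
  expect_setequal(names(bg$models), as.character(1:8))
  expect_false(is.null(bg$pooled))
  mus <- vapply(bg$models, `[[`, 0, "mu")
  # decreasing trend with distance (the distance-decay the model encodes)
  expect_lt(cor(as.numeric(names(mus)), mus, method = "spearman"), 0)
  # overdispersion identity on every non-degenerate stratum
  for (m in bg$models)
    if (m$fit_method == "mle") {
      expect_gt(m$var_mean_ratio, 1)
      expect_equal(m$var_mean_ratio, 1 / (1 - m$p))
    }
  # recovery: informative strata within 10% of the generator truth
  truth <- sim$truth$params
  for (d in 1:2) {
    m <- bg$models[[as.character(d)]]
    expect_lt(abs(m$mu - truth$mu_d[d]) / truth$mu_d[d], 0.10)
    expect_lt(abs(m$r - truth$r_d[d]) / truth$r_d[d], 0.25)
  }
})

test_that("mean-variance relationship across strata is linear with
           slope > 1", {
  sim <- default_sim()
  cl <- classify_pets(dedup_pets(sim$pets), sim$truth$bait)
  g <- bin_grid(sim$config$chrom_sizes, sim$truth$bait)
  mv <- t(vapply(1:8, function(d) {
    cnt <- sample_intra_pairs(cl$pets, g, d, n = 5000, seed = 100 + d)
    c(m = mean(cnt), v = var(cnt))
  }, c(m = 0, v = 0)))
  fitlm <- lm(v ~ m, data = as.data.frame(mv))
  expect_gt(coef(fitlm)[["m"]], 1)
  expect_gt(summary(fitlm)$r.squared, 0.9)
})

test_that("inter background fits per chromosome and orders means by the
           true trans rates", {
  cfg <- sim_config(seed = 88, lambda_inter = c(chr2 = 3, chr3 = 0.5))
  sim <- simulate_pets(cfg)
  cl <- classify_pets(dedup_pets(sim$pets), sim$truth$bait)
  bg <- build_inter_background(cl$pets, cfg$chrom_sizes, sim$truth$bait,
                               n = 5000, seed = 21)
  expect_setequal(names(bg$models), c("chr2", "chr3"))
  expect_gt(bg$models$chr2$mu, bg$models$chr3$mu)
  # zero trans background -> degenerate models everywhere
  none <- cl$pets[category != "background_inter"]
  ws <- capture_warnings(
    bg0 <- build_inter_background(none, cfg$chrom_sizes, sim$truth$bait,
                                  n = 200, seed = 21))
  expect_true(all(grepl("degenerate", ws)) && length(ws) == 2L)
  expect_true(all(vapply(bg0$models, `[[`, "", "fit_method") == "degenerate"))
  # seeded reproducibility
  bg2 <- build_inter_background(cl$pets, cfg$chrom_sizes, sim$truth$bait,
                                n = 5000, seed = 21)
  expect_equal(bg2$models$chr2$r, bg$models$chr2$r)
})

test_that("background JSON serialization round-trips the models", {
  sim <- default_sim()
  cl <- classify_pets(sim$pets, sim$truth$bait)
  g <- bin_grid(sim$config$chrom_sizes, sim$truth$bait)
  intra <- build_intra_background(cl$pets, g, n = 1000, seed = 2)
  inter <- build_inter_background(cl$pets, sim$config$chrom_sizes,
                                  sim$truth$bait, n = 1000, seed = 2)
  f <- tempfile(fileext = ".json")
  background_to_json(intra, inter, f)
  back <- background_from_json(f)
  expect_equal(back$intra$models[["1"]]$r, intra$models[["1"]]$r)
  expect_equal(back$intra$pooled$mu, intra$pooled$mu)
  expect_equal(back$inter$models$chr2$p, inter$models$chr2$p)
  expect_equal(back$intra$l, intra$l)
  # revived models compute identical tail probabilities
  expect_equal(left_tail_p(5, back$intra$models[["1"]]),
               left_tail_p(5, intra$models[["1"]]))
})
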