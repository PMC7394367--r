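## background_models: negative-binomial noise models over random bin-pair
## contact counts. Intra-chromosomal noise is stratified by the distance
## multiplier d (one model per d with d*l <= 20 kb, one pooled model
## beyond); inter-chromosomal noise gets one model per partner
## chromosome on a 1 Mb grid.
##
## Parameterization (used everywhere in this package): the pmf is
##   P(X = x) = C(x + r - 1, x) (1 - p)^r p^x,
## i.e. stats::dnbinom(x, size = r, prob = 1 - p). Mean = r p/(1-p),
## variance = r p/(1-p)^2, so variance/mean = 1/(1-p) > 1 whenever
## p in (0,1) — the overdispersion identity the model rests on.

#' Construct a negative-binomial parameter object
#'
#' @param r positive dispersion parameter ("number of unknown failures").
#' @param p success probability in (0,1) on the count term.
#' @param fit_method one of "mle", "moments", "poisson_fallback",
#'   "degenerate".
#' @param n_obs sample size behind the fit.
#' @param mu mean (required for the Poisson fallback; derived otherwise).
#' @param loglik achieved log-likelihood (optional).
#' @return object of class `nb_params`.
#' @export
nb_params <- function(r, p, fit_method = "mle", n_obs = NA_integer_,
                      mu = NULL, loglik = NA_real_) {
  if (fit_method == "poisson_fallback") {
    assert_that(!is.null(mu) && mu >= 0, "poisson fallback needs a mean")
    r <- Inf; p <- 0
  } else if (fit_method == "degenerate") {
    mu <- 0; r <- NA_real_; p <- NA_real_
  } else {
    assert_that(r > 0 && p > 0 && p < 1, "need r > 0 and p in (0,1)")
    mu <- r * p / (1 - p)
  }
  structure(list(r = r, p = p, mu = mu, fit_method = fit_method,
                 n_obs = as.integer(n_obs), loglik = loglik,
                 var_mean_ratio = if (fit_method %in% c("mle", "moments"))
                   1 / (1 - p) else 1),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("<nb_params> %s: r=%.4g p=%.4g mu=%.4g var/mean=%.4g (n=%s)\n",
              x$fit_method, x$r, x$p, x$mu, x$var_mean_ratio, x$n_obs))
  invisible(x)
}

#' NB pmf / CDF in the package parameterization
#'
#' Thin wrappers around [stats::dnbinom()]/[stats::pnbinom()] with
#' `size = r`, `prob = 1 - p`; the Poisson fallback and degenerate cases
#' are dispatched on `fit_method`.
#'
#' @param x non-negative count(s).
#' @param model an [nb_params()].
#' @param log,lower.tail,log.p as in the stats functions.
#' @export
nb_pmf <- function(x, model, log = FALSE) {
  switch(model$fit_method,
         poisson_fallback = stats::dpois(x, model$mu, log = log),
         degenerate = if (log) ifelse(x == 0, 0, -Inf) else as.numeric(x == 0),
         stats::dnbinom(x, size = model$r, prob = 1 - model$p, log = log))
}

#' @rdname nb_pmf
#' @param q quantile.
#' @export
nb_cdf <- function(q, model, lower.tail = TRUE, log.p = FALSE) {
  switch(model$fit_method,
         poisson_fallback = stats::ppois(q, model$mu, lower.tail = lower.tail,
                                         log.p = log.p),
         degenerate = {
           v <- as.numeric(q >= 0)
           if (!lower.tail) v <- 1 - v
           if (log.p) log(v) else v
         },
         stats::pnbinom(q, size = model$r, prob = 1 - model$p,
                        lower.tail = lower.tail, log.p = log.p))
}

## method-of-moments estimate in (r, p); NULL when not overdispersed
#' @noRd
nb_moments <- function(m, v) {
  if (v <= m || m <= 0) return(NULL)
  p <- 1 - m / v
  list(r = m * (1 - p) / p, p = p)
}

## NB log-likelihood from a tabulated sample (unique values + counts)
#' @noRd
nb_loglik_tab <- function(vals, wts, r, p) {
  sum(wts * stats::dnbinom(vals, size = r, prob = 1 - p, log = TRUE))
}

#' Fit a negative-binomial background model by maximum likelihood
#'
#' Maximizes the NB log-likelihood in the (r, p) parameterization.
#' For fixed r the MLE of p is closed form (p = S / (n r + S) with
#' S = sum of counts), so the fit is a 1-D profile optimization over
#' log r, initialized from the method-of-moments bracket and converged to
#' 1e-8 on the log-likelihood. Samples without overdispersion (variance
#' <= mean) return a Poisson fallback (the p -> 0 limit of the family);
#' all-zero samples return a degenerate model under which any positive
#' count has left-tail probability 1, flagged loudly because it usually
#' signals an under-sampled background.
#'
#' @param counts non-negative integer sample.
#' @param min_obs minimum sample size.
#' @return an [nb_params()].
#' @export
fit_nb <- function(counts, min_obs = 30L) {
  counts <- as.numeric(counts)
  assert_that(length(counts) >= min_obs,
              sprintf("need at least %d observations to fit a background; sample more pairs", min_obs))
  assert_that(all(counts >= 0 & counts == floor(counts)),
              "counts must be non-negative integers")
  n <- length(counts)
  m <- mean(counts); v <- stats::var(counts)
  if (m == 0) {
    warning("all-zero background sample: degenerate model")
    return(nb_params(NA, NA, "degenerate", n))
  }
  if (v <= m) {
    return(nb_params(NA, NA, "poisson_fallback", n, mu = m,
                     loglik = sum(stats::dpois(counts, m, log = TRUE))))
  }
  tab <- table(counts)
  vals <- as.numeric(names(tab)); wts <- as.numeric(tab)
  S <- sum(counts)
  prof <- function(logr) {
    r <- exp(logr)
    p <- S / (n * r + S)
    nb_loglik_tab(vals, wts, r, p)
  }
  r0 <- nb_moments(m, v)$r
  opt <- stats::optimize(prof, interval = log(c(r0 / 1e4, r0 * 1e4)),
                         maximum = TRUE, tol = 1e-10)
  r_hat <- exp(opt$maximum)
  p_hat <- S / (n * r_hat + S)
  nb_params(r_hat, p_hat, "mle", n, loglik = opt$objective)
}

## -- bin-pair count machinery ------------------------------------------

## Tabulate background PETs by ideal-tiling bin index pair on one
## chromosome. Returns environment-free lookup: data.table keyed by
## (i1, i2) with i1 <= i2.
#' @noRd
intra_pair_counts <- function(pets, chrom, l) {
  dt <- data.table::as.data.table(pets)[
    category == "background_intra" & chrom1 == chrom]
  if (!nrow(dt)) return(data.table(i1 = integer(), i2 = integer(),
                                   N = integer()))
  i1 <- floor(dt$pos1 / l); i2 <- floor(dt$pos2 / l)
  data.table(i1 = as.integer(pmin(i1, i2)),
             i2 = as.integer(pmax(i1, i2)))[, .N, by = .(i1, i2)]
}

#' Sample background contact counts for bin pairs at one distance
#'
#' Uniformly samples `n` ordered bin pairs (b, b + d) on the bait
#' chromosome over the ideal `l`-tiling, excluding every pair touching a
#' bait-overlapping bin, and counts the background-intra PETs linking the
#' two bins of each pair. Sampling is without replacement when at least
#' `n` candidate pairs exist, with replacement otherwise.
#'
#' @param pets classified PET data.table (only `background_intra` rows
#'   on the bait chromosome are used).
#' @param grid a [bin_grid()].
#' @param d distance multiplier (>= 1).
#' @param n number of pairs to sample.
#' @param seed RNG seed.
#' @return integer vector of `n` counts (length 0 when the chromosome is
#'   too short to host any pair at distance d).
#' @export
sample_intra_pairs <- function(pets, grid, d, n = 10000L, seed = 1L) {
  pc <- intra_pair_counts(pets, grid$bait$chrom, grid$bin_size)
  sample_pairs_counts(pc, grid, d, n, seed)
}

## core of sample_intra_pairs with the pair-count table precomputed
#' @noRd
sample_pairs_counts <- function(pc, grid, d, n, seed) {
  bait <- grid$bait
  l <- grid$bin_size
  K <- floor(as.numeric(grid$chrom_sizes[[bait$chrom]]) / l)
  bait_bins <- floor(bait$start / l):floor((bait$end - 1) / l)
  if (K - d < 1) return(integer(0))
  b <- 0:(K - 1 - d)
  b <- b[!(b %in% bait_bins) & !((b + d) %in% bait_bins)]
  if (!length(b)) return(integer(0))
  with_seed(seed, {
    sel <- b[sample.int(length(b), n, replace = length(b) < n)]
    lookup_pair_counts(pc, sel, sel + d)
  })
}

#' @noRd
lookup_pair_counts <- function(pc, i1, i2) {
  q <- data.table(i1 = as.integer(i1), i2 = as.integer(i2))
  cnt <- pc[q, on = c("i1", "i2")]$N
  cnt[is.na(cnt)] <- 0L
  as.integer(cnt)
}

#' Build the distance-stratified intra-chromosomal background
#'
#' One NB fit per distance multiplier d with d*l <= `D_max` (inclusive:
#' d*l = 20 kb gets its own model) from counts over `n` randomly sampled
#' bin pairs at that exact distance, plus one pooled model for pairs
#' farther than `D_max`, sampled by drawing d uniformly over the valid
#' far multipliers and then a pair at that d. Strata whose sample comes
#' back smaller than `min_obs` fall back to the pooled model (flagged in
#' `fallback_d`).
#'
#' @param pets classified PET data.table.
#' @param grid a [bin_grid()].
#' @param D_max distance cutoff in bp (20 kb).
#' @param n sampled pairs per stratum.
#' @param seed RNG seed (sub-seeds are derived per stratum; fits are
#'   cached with the seed by serializing, not resampled per call).
#' @param min_obs minimum stratum sample size before pooling.
#' @return object of class `intra_background`: `l`, `D_max`, `models`
#'   (list indexed by as.character(d)), `pooled`, `fallback_d`, `seed`.
#' @export
build_intra_background <- function(pets, grid, D_max = 20000L, n = 10000L,
                                   seed = 1L, min_obs = 30L) {
  l <- grid$bin_size
  d_max_strat <- floor(D_max / l)
  K <- floor(as.numeric(grid$chrom_sizes[[grid$bait$chrom]]) / l)
  bait_bins <- floor(grid$bait$start / l):floor((grid$bait$end - 1) / l)
  pc <- intra_pair_counts(pets, grid$bait$chrom, l)
  models <- list()
  fallback_d <- integer(0)
  for (d in seq_len(d_max_strat)) {
    cnt <- sample_pairs_counts(pc, grid, d, n, derive_seed(seed, d))
    if (length(cnt) < min_obs) { fallback_d <- c(fallback_d, d); next }
    models[[as.character(d)]] <- fit_nb(cnt, min_obs)
  }
  # pooled model beyond D_max: uniform d over the far range, then a pair
  far_lo <- d_max_strat + 1L
  far_hi <- K - 2L
  pooled <- NULL
  if (far_hi >= far_lo) {
    far_range <- far_lo:far_hi
    cnt <- with_seed(derive_seed(seed, 0L), {
      ds <- far_range[sample.int(length(far_range), n, replace = TRUE)]
      bs <- floor(runif(n) * (K - ds))
      bad <- bs %in% bait_bins | (bs + ds) %in% bait_bins
      while (any(bad)) {
        bs[bad] <- floor(runif(sum(bad)) * (K - ds[bad]))
        bad <- bs %in% bait_bins | (bs + ds) %in% bait_bins
      }
      lookup_pair_counts(pc, bs, bs + ds)
    })
    if (length(cnt) >= min_obs) pooled <- fit_nb(cnt, min_obs)
  }
  structure(list(l = l, D_max = as.numeric(D_max), models = models,
                 pooled = pooled, fallback_d = fallback_d, n = n,
                 seed = seed),
            class = "intra_background")
}

#' Build the per-chromosome inter-chromosomal background
#'
#' The bait region is notionally extended to 1 Mb and all chromosomes
#' split into 1 Mb bins. For each partner chromosome, `n` random bin
#' pairs (one bin on the bait chromosome excluding the bait-containing
#' bin, one on the partner) are sampled and the background-inter PETs
#' linking each pair are counted; the counts are fitted as an NB (or its
#' Poisson/degenerate fallback).
#'
#' @param pets classified PET data.table.
#' @param chrom_sizes named vector of chromosome lengths (>= 2 entries).
#' @param bait a [bait_region()].
#' @param bin_size trans bin width (1 Mb).
#' @param n sampled pairs per chromosome.
#' @param seed RNG seed.
#' @param min_obs minimum sample size per fit.
#' @return object of class `inter_background`: `models` (list indexed by
#'   chromosome), `bin_size`, `seed`.
#' @export
build_inter_background <- function(pets, chrom_sizes, bait, bin_size = 1e6,
                                   n = 10000L, seed = 1L, min_obs = 30L) {
  assert_that(length(chrom_sizes) >= 2, "need at least two chromosomes")
  others <- setdiff(names(chrom_sizes), bait$chrom)
  dt <- data.table::as.data.table(pets)[category == "background_inter"]
  # orient: end on bait chromosome first
  if (nrow(dt)) {
    onb1 <- dt$chrom1 == bait$chrom
    bpos <- data.table::fifelse(onb1, dt$pos1, dt$pos2)
    opos <- data.table::fifelse(onb1, dt$pos2, dt$pos1)
    ochr <- data.table::fifelse(onb1, dt$chrom2, dt$chrom1)
    keep <- onb1 | dt$chrom2 == bait$chrom
    tabs <- data.table(chrom = ochr[keep],
                       i = as.integer(floor(bpos[keep] / bin_size)),
                       j = as.integer(floor(opos[keep] / bin_size)))[
                         , .N, by = .(chrom, i, j)]
  } else {
    tabs <- data.table(chrom = character(), i = integer(), j = integer(),
                       N = integer())
  }
  bait_bin <- floor(bait$start / bin_size)
  Kb <- ceiling(as.numeric(chrom_sizes[[bait$chrom]]) / bin_size)
  ib <- setdiff(0:(Kb - 1), bait_bin)
  models <- list()
  for (k in seq_along(others)) {
    chr <- others[k]
    Kc <- ceiling(as.numeric(chrom_sizes[[chr]]) / bin_size)
    cnt <- with_seed(derive_seed(seed, 2000L + k), {
      i <- ib[sample.int(length(ib), n, replace = TRUE)]
      j <- sample.int(Kc, n, replace = TRUE) - 1L
      q <- data.table(chrom = chr, i = as.integer(i), j = as.integer(j))
      v <- tabs[q, on = c("chrom", "i", "j")]$N
      v[is.na(v)] <- 0L
      as.integer(v)
    })
    models[[chr]] <- fit_nb(cnt, min_obs)
  }
  structure(list(models = models, bin_size = as.numeric(bin_size),
                 bait_chrom = bait$chrom, n = n, seed = seed),
            class = "inter_background")
}

## -- serialization ------------------------------------------------------

#' Serialize fitted backgrounds to JSON (and back)
#'
#' Background models are cached with their seed so a calling run can be
#' repeated without resampling.
#'
#' @param intra_bg an `intra_background` (or NULL).
#' @param inter_bg an `inter_background` (or NULL).
#' @param path JSON path.
#' @export
background_to_json <- function(intra_bg = NULL, inter_bg = NULL, path) {
  strip <- function(m) m[c("r", "p", "mu", "fit_method", "n_obs",
                           "var_mean_ratio")]
  x <- list()
  if (!is.null(intra_bg))
    x$intra <- list(l = intra_bg$l, D_max = intra_bg$D_max,
                    seed = intra_bg$seed, n = intra_bg$n,
                    fallback_d = intra_bg$fallback_d,
                    models = lapply(intra_bg$models, strip),
                    pooled = if (!is.null(intra_bg$pooled))
                      strip(intra_bg$pooled))
  if (!is.null(inter_bg))
    x$inter <- list(bin_size = inter_bg$bin_size, seed = inter_bg$seed,
                    n = inter_bg$n, bait_chrom = inter_bg$bait_chrom,
                    models = lapply(inter_bg$models, strip))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname background_to_json
#' @export
background_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  revive <- function(m) {
    out <- nb_params(
      r = if (m$fit_method %in% c("mle", "moments")) m$r else NA,
      p = if (m$fit_method %in% c("mle", "moments")) m$p else NA,
      fit_method = m$fit_method, n_obs = m$n_obs,
      mu = m$mu)
    out
  }
  res <- list()
  if (!is.null(x$intra)) {
    res$intra <- structure(list(
      l = x$intra$l, D_max = x$intra$D_max, seed = x$intra$seed,
      n = x$intra$n, fallback_d = unlist(x$intra$fallback_d) %||% integer(0),
      models = lapply(x$intra$models, revive),
      pooled = if (!is.null(x$intra$pooled)) revive(x$intra$pooled)),
      class = "intra_background")
  }
  if (!is.null(x$inter)) {
    res$inter <- structure(list(
      bin_size = x$inter$bin_size, seed = x$inter$seed, n = x$inter$n,
      bait_chrom = x$inter$bait_chrom,
      models = lapply(x$inter$models, revive)),
      class = "inter_background")
  }
  res
}
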