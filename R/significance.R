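## significance: left-tail P-values under the fitted backgrounds and
## Bayes factors for bait-to-bin contacts.
##
## Note on orientation: the pipeline's "P-value" is the LEFT tail
## P(X_d < x_d) — larger is more significant, inverted relative to
## convention. It is preserved verbatim as p_left; the conventional
## survival probability P(X_d >= x_d) is reported alongside as
## p_survival.

#' Calling configuration
#'
#' @param prior_odds prior odds P(H1)/P(H0) that a random collision
#'   exceeds a true interaction; 0.001 marks it a rare event.
#' @param bf_threshold Bayes-factor cutoff for high-confidence calls
#'   (BF > 20).
#' @param min_count minimum observed PET count for a bin to be
#'   evaluated; zero-count bins are never called.
#' @export
calling_config <- function(prior_odds = 0.001, bf_threshold = 20,
                           min_count = 1L) {
  assert_that(prior_odds > 0 && prior_odds <= 1, "prior_odds must be in (0,1]")
  assert_that(bf_threshold > 0, "bf_threshold must be > 0")
  structure(list(prior_odds = prior_odds, bf_threshold = bf_threshold,
                 min_count = as.integer(min_count)),
            class = "calling_config")
}

#' Left-tail probability of an observed contact count
#'
#' p_left = P(X < x) = CDF(x - 1) under the background model; x = 0
#' gives 0 (the empty event). Under a degenerate (all-zero) background
#' any positive count has p_left = 1. Computed through the stats
#' distribution functions, which accumulate in log space for small
#' tails.
#'
#' @param x observed count(s), >= 0.
#' @param model an [nb_params()].
#' @return p_left in [0,1], vectorized over `x`.
#' @export
left_tail_p <- function(x, model) {
  assert_that(all(x >= 0), "counts must be >= 0")
  ifelse(x == 0, 0, nb_cdf(x - 1, model))
}

## survival P(X >= x) computed from the upper tail for precision
#' @noRd
survival_p <- function(x, model) {
  ifelse(x == 0, 1, nb_cdf(x - 1, model, lower.tail = FALSE))
}

#' Bayes factor for an interaction hypothesis
#'
#' BF = prior_odds * p_left / (1 - p_left): the posterior-style odds of
#' an interaction over a random collision, discounted by the prior odds
#' P(H1)/P(H0) = 0.001 that noise outruns signal. With the defaults,
#' BF > 20 is equivalent to p_survival < 1/20001 (about 5e-5), making the
#' high-confidence threshold a stringent tail criterion. p_left = 1 maps
#' to a large sentinel (1e12) rather than +Inf.
#'
#' @param p_left left-tail probability in [0,1] (alternatively supply
#'   `p_survival = 1 - p_left` for precision deep in the tail).
#' @param config a [calling_config()].
#' @param p_survival optional survival probability; overrides `p_left`.
#' @export
bayes_factor <- function(p_left = NULL, config = calling_config(),
                         p_survival = NULL) {
  if (is.null(p_survival)) {
    assert_that(all(p_left >= 0 & p_left <= 1), "p_left must be in [0,1]")
    p_survival <- 1 - p_left
  }
  bf <- config$prior_odds * (1 - p_survival) / p_survival
  bf[p_survival <= 0] <- 1e12
  pmin(bf, 1e12)
}

#' Call significant interactions from a contact vector
#'
#' Every bin with at least `min_count` PETs is evaluated: intra bins
#' against the d-specific background (pooled model when d*l > D_max or
#' the stratum fell back), inter bins against the partner-chromosome
#' model. Bins with no applicable model yield a call with NA statistics
#' and a warning. Calls are sorted by Bayes factor, descending. The bait
#' bin itself (d = 0) is never called.
#'
#' @param contacts contact vector from [bin_contacts()].
#' @param intra_bg an `intra_background` (or NULL to skip intra).
#' @param inter_bg an `inter_background` (or NULL to skip inter).
#' @param bait the [bait_region()] (for output coordinates).
#' @param config a [calling_config()].
#' @return data.table of calls: bait/target intervals, kind, d, count,
#'   p_left, p_survival, bayes_factor, significant, background_ref.
#' @export
call_interactions <- function(contacts, intra_bg = NULL, inter_bg = NULL,
                              bait, config = calling_config()) {
  dt <- data.table::as.data.table(contacts)
  dt <- dt[count >= config$min_count & !(kind == "intra" & d == 0L)]
  empty <- data.table(
    bait_chrom = character(), bait_start = numeric(), bait_end = numeric(),
    target_chrom = character(), target_start = numeric(),
    target_end = numeric(), kind = character(), d = integer(),
    count = integer(), p_left = numeric(), p_survival = numeric(),
    bayes_factor = numeric(), significant = logical(),
    background_ref = character())
  if (!nrow(dt)) return(empty)
  pick_model <- function(kind, d, chrom) {
    if (kind == "intra") {
      if (is.null(intra_bg)) return(NULL)
      key <- as.character(d)
      if (d * intra_bg$l <= intra_bg$D_max && !is.null(intra_bg$models[[key]]))
        return(list(m = intra_bg$models[[key]], ref = paste0("intra_d", key)))
      if (!is.null(intra_bg$pooled))
        return(list(m = intra_bg$pooled, ref = "intra_pooled"))
      return(NULL)
    }
    if (is.null(inter_bg) || is.null(inter_bg$models[[chrom]])) return(NULL)
    list(m = inter_bg$models[[chrom]], ref = paste0("inter_", chrom))
  }
  n <- nrow(dt)
  p_left <- p_surv <- rep(NA_real_, n)
  refs <- rep(NA_character_, n)
  missing_model <- FALSE
  for (i in seq_len(n)) {
    mm <- pick_model(dt$kind[i], dt$d[i], dt$chrom[i])
    if (is.null(mm)) { missing_model <- TRUE; next }
    p_left[i] <- left_tail_p(dt$count[i], mm$m)
    p_surv[i] <- survival_p(dt$count[i], mm$m)
    refs[i] <- mm$ref
  }
  if (missing_model)
    warning("some bins had no applicable background model; ",
            "their statistics are NA")
  bf <- ifelse(is.na(p_surv), NA_real_,
               bayes_factor(config = config, p_survival = p_surv))
  out <- data.table(
    bait_chrom = bait$chrom, bait_start = bait$start, bait_end = bait$end,
    target_chrom = dt$chrom, target_start = dt$start, target_end = dt$end,
    kind = dt$kind, d = dt$d, count = dt$count,
    p_left = p_left, p_survival = p_surv, bayes_factor = bf,
    significant = !is.na(bf) & bf > config$bf_threshold,
    background_ref = refs)
  data.table::setorder(out, -bayes_factor, na.last = TRUE)
  out[]
}

#' Run classification, backgrounds and calling in one step
#'
#' Convenience wrapper over [classify_pets()], [bin_grid()],
#' [bin_contacts()], [build_intra_background()],
#' [build_inter_background()] and [call_interactions()].
#'
#' @param pets deduplicated PET table.
#' @param bait a [bait_region()].
#' @param chrom_sizes named chromosome lengths.
#' @param seed RNG seed for background pair sampling.
#' @param config a [calling_config()].
#' @param n_pairs sampled pairs per background stratum.
#' @param D_max intra distance cutoff (bp).
#' @return list: calls, contacts, qc, intra_bg, inter_bg, grid, tally.
#' @export
c3s_call <- function(pets, bait, chrom_sizes, seed = 1L,
                     config = calling_config(), n_pairs = 10000L,
                     D_max = 20000L) {
  grid <- bin_grid(chrom_sizes, bait)
  cl <- classify_pets(pets, bait)
  contacts <- bin_contacts(cl$pets, grid)
  intra_bg <- build_intra_background(cl$pets, grid, D_max = D_max,
                                     n = n_pairs, seed = seed)
  inter_bg <- build_inter_background(cl$pets, chrom_sizes, bait,
                                     n = n_pairs,
                                     seed = derive_seed(seed, 7L))
  calls <- call_interactions(contacts, intra_bg, inter_bg, bait, config)
  qc <- qc_summary(pets = cl$pets, bait = bait)
  list(calls = calls, contacts = contacts, qc = qc, intra_bg = intra_bg,
       inter_bg = inter_bg, grid = grid, tally = cl$tally)
}
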