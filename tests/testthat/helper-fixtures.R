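## Shared fixtures: one default simulated library (with spikes) reused
## across test files, plus small builders. Everything is generated in
## code at test time -- no stored data.

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 424)
      cfg$spikes <- default_spikes(cfg)
      cache <<- simulate_pets(cfg)
    }
    cache
  }
})

## a tiny aligned-ends table builder
make_ends <- function(ids, chrom = "chr1", pos = seq_along(ids) * 100,
                      strand = "+", mapq = 42L) {
  data.table::data.table(read_id = ids, chrom = chrom, pos = pos,
                         strand = strand, mapq = mapq)
}

## brute-force oracle: split a read at every GATC occurrence and return
## the longest fragment by direct enumeration (independent of the
## implementation's split logic)
oracle_trim <- function(seq) {
  if (!nzchar(seq)) return(list(fragment = "", kept = FALSE))
  starts <- c()
  for (i in seq_len(max(nchar(seq) - 3, 0)))
    if (substr(seq, i, i + 3) == "GATC") starts <- c(starts, i)
  bounds <- unique(c(1, starts, nchar(seq) + 1))
  bounds <- sort(bounds)
  frags <- character(0)
  for (k in seq_len(length(bounds) - 1))
    frags <- c(frags, substr(seq, bounds[k], bounds[k + 1] - 1))
  if (length(bounds) == 1) frags <- seq
  best <- frags[which.max(nchar(frags))]
  list(fragment = best, kept = nchar(best) > 20)
}

## random DNA string possibly containing planted GATC motifs
random_read <- function(len, n_gatc = 0) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s <- paste(s, collapse = "")
  if (n_gatc > 0) {
    at <- sample(seq_len(max(len - 4, 1)), n_gatc)
    for (p in at) substr(s, p, p + 3) <- "GATC"
  }
  s
}

## brute-force NB pmf in the package's (r, p) parameterization
oracle_nb_pmf <- function(x, r, p) {
  exp(lchoose(x + r - 1, x) + r * log(1 - p) + x * log(p))
}

## brute-force left tail P(X < x) by direct summation
oracle_left_tail <- function(x, r, p) {
  if (x == 0) return(0)
  sum(oracle_nb_pmf(0:(x - 1), r, p))
}

## independent grid-search MLE over (r, p) for the NB fit oracle:
## coarse pass over the stated ranges, then a refining pass around the
## coarse optimum
oracle_grid_mle <- function(counts, r_range, p_range, steps = 40) {
  scan <- function(rs, ps) {
    best <- list(ll = -Inf)
    for (r in rs) for (p in ps) {
      ll <- sum(stats::dnbinom(counts, size = r, prob = 1 - p, log = TRUE))
      if (ll > best$ll) best <- list(r = r, p = p, ll = ll)
    }
    best
  }
  b <- scan(exp(seq(log(r_range[1]), log(r_range[2]), length.out = steps)),
            seq(p_range[1], p_range[2], length.out = steps))
  scan(seq(b$r * 0.8, b$r * 1.25, length.out = steps),
       seq(max(1e-4, b$p - 0.05), min(0.999, b$p + 0.05),
           length.out = steps))
}
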