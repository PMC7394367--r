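## synthetic_data: generates capture-3C-like libraries with the exact
## statistical structure the model assumes -- a toy genome, a bait peak
## dominated by self-ligation, distance-decaying overdispersed
## intra-chromosomal noise, per-chromosome trans noise, spiked true
## interactions and chimeric GATC-junction reads -- plus a truth table,
## so every module is testable without downloads.

#' Simulation configuration
#'
#' The defaults are the generator's stated world: a 3 x 10 Mb genome, a
#' 2.5 kb bait at the centre of chr1, a bait-associated library of
#' 11,692 PETs dominated by self-ligation (98.5%), intra-chromosomal
#' bin-pair noise NB(r_d, p) with geometrically decaying means
#' mu_d = mu1 * decay^(d-1) over the distance strata below 20 kb
#' (variance/mean = 1/(1-p) = 1.5), a sparse uniform far/cis noise floor
#' the decay runs into smoothly (so noise really is flat beyond the
#' cutoff, which is what the pooled background model assumes), Poisson
#' trans noise per 1 Mb bin pair, and two-point MAPQ {42: 0.9, 10: 0.1}
#' exercising the strict MAPQ > 30 filter.
#'
#' Two modes place the bait-anchored noise:
#' * `"background"` (default): bait-to-bin noise counts are drawn from
#'   the same NB/Poisson truth as random bin pairs, which is exactly the
#'   null hypothesis of the calling model — used for calibration
#'   (false-positive rate) and recovery tests.
#' * `"fractions"`: the self/intra/inter category totals are drawn from a
#'   multinomial over (`self_fraction`, `intra_fraction`,
#'   `inter_fraction`) and intra PETs are placed by an empirical
#'   distance profile — used to emulate published library composition
#'   for QC.
#'
#' @param seed mandatory RNG seed.
#' @param chrom_sizes named chromosome lengths.
#' @param bait_chrom,bait_start,bait_width true bait locus; the default
#'   start is a multiple of the width so the bait is its own tiling bin.
#' @param n_pets bait-associated library size.
#' @param self_fraction,intra_fraction,inter_fraction category fractions
#'   (must sum to <= 1).
#' @param bait_pet_mode "background" or "fractions" (see above).
#' @param mu1 mean background contacts per bin pair at distance d = 1.
#' @param decay geometric decay factor of the per-stratum mean
#'   (mu_d = mu1 * decay^(d-1), floored at `lambda_far`).
#' @param p_intra NB success probability of the intra noise (sets
#'   variance/mean = 1/(1-p)).
#' @param D_max distance cutoff of the stratified regime (bp).
#' @param lambda_far mean contacts per far (> D_max) cis bin pair.
#' @param lambda_inter mean contacts per 1 Mb trans bin pair; either a
#'   scalar or a named vector with one rate per non-bait chromosome.
#' @param spikes data.table of true interactions (chrom, pos, count,
#'   kind); `NULL` for none — see [default_spikes()].
#' @param spike_halfwidth spiked PETs land within +/- this of the spike
#'   anchor (loop anchors are sharp, not bin-wide).
#' @param dup_rate fraction of extra PCR-duplicate records injected.
#' @param chimera_fraction fraction of PETs whose mate-2 read is emitted
#'   unmapped with a GATC junction chimera (SAM output only).
#' @param read_len read length (bp).
#' @param mapq_vals,mapq_probs two-point MAPQ distribution per end.
#' @param frac_within_1mb,frac_downstream intra placement profile used
#'   in "fractions" mode.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                       bait_chrom = "chr1", bait_start = 5e6,
                       bait_width = 2500,
                       n_pets = 11692, self_fraction = 0.985,
                       intra_fraction = 0.010, inter_fraction = 0.005,
                       bait_pet_mode = c("background", "fractions"),
                       mu1 = 3, decay = 0.5, p_intra = 1/3, D_max = 20000,
                       lambda_far = 1e-3, lambda_inter = 2,
                       spikes = NULL, spike_halfwidth = 50,
                       dup_rate = 0.1, chimera_fraction = 0.02,
                       read_len = 36L,
                       mapq_vals = c(42L, 10L), mapq_probs = c(0.9, 0.1),
                       frac_within_1mb = 96 / 118,
                       frac_downstream = 80 / 118) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  bait_pet_mode <- match.arg(bait_pet_mode)
  assert_that(self_fraction >= 0 && intra_fraction >= 0 &&
                inter_fraction >= 0 &&
                self_fraction + intra_fraction + inter_fraction <= 1 + 1e-12,
              "category fractions must be in [0,1] and sum to <= 1")
  assert_that(bait_chrom %in% names(chrom_sizes), "unknown bait chromosome")
  assert_that(p_intra > 0 && p_intra < 1, "p_intra must be in (0,1)")
  cfg <- as.list(environment())
  if (!is.null(spikes)) {
    spikes <- data.table::as.data.table(spikes)
    bad <- spikes$chrom == bait_chrom &
      spikes$pos >= bait_start - spike_halfwidth &
      spikes$pos < bait_start + bait_width + spike_halfwidth
    assert_that(!any(bad), "a spiked bin overlaps the bait region")
    cfg$spikes <- spikes
  }
  structure(cfg, class = "sim_config")
}

#' Default spiked true interactions at a given strength
#'
#' Places loops where real calls live: two cis anchors on each side of
#' the bait at distance multipliers 1 and 2 (inside the stratified,
#' TAD-scale regime) and one trans anchor on the first other chromosome.
#' Spike counts are `fold` times the corresponding background mean,
#' rounded up — the "10 x background" scenario by default.
#'
#' @param config a [sim_config()].
#' @param fold spike strength as a multiple of the background mean.
#' @export
default_spikes <- function(config, fold = 10) {
  l <- config$bait_width
  centre <- config$bait_start + l / 2
  mk <- function(d, side) {
    data.table(chrom = config$bait_chrom,
               pos = centre + side * d * l, kind = "intra",
               count = as.integer(ceiling(
                 fold * config$mu1 * config$decay^(d - 1))))
  }
  cis <- data.table::rbindlist(list(mk(1, +1), mk(1, -1), mk(2, +1), mk(2, -1)))
  other <- setdiff(names(config$chrom_sizes), config$bait_chrom)[1]
  lam <- if (length(config$lambda_inter) > 1) config$lambda_inter[[other]]
  else config$lambda_inter
  trans <- data.table(chrom = other,
                      pos = floor(config$chrom_sizes[[other]] / 2e6) * 1e6 + 5e5,
                      kind = "inter",
                      count = as.integer(ceiling(fold * lam)))
  rbind(cis, trans)
}

## rnbinom that tolerates size = 0 (degenerate at zero, e.g. noise off)
#' @noRd
rnb0 <- function(n, size, prob) {
  size <- rep(size, length.out = n)
  if (all(size > 0)) return(stats::rnbinom(n, size = size, prob = prob))
  out <- integer(n)
  pos <- size > 0
  if (any(pos)) out[pos] <- stats::rnbinom(sum(pos), size = size[pos],
                                           prob = prob)
  out
}

## uniform integer positions in [lo, hi), clamped so a read fits
#' @noRd
runif_pos <- function(n, lo, hi, chrom_len, read_len) {
  p <- lo + floor(runif(n) * (hi - lo))
  pmin(p, chrom_len - read_len)
}

#' Simulate a PET library with truth table
#'
#' Draws PETs per category (see [sim_config()]): self-ligated pairs with
#' both ends inside the bait; bait-anchored cis noise per bin (NB truth
#' below `D_max`, Poisson floor beyond); bait-anchored trans noise per
#' 1 Mb bin; background (neither-end-in-bait) cis bin-pair noise on the
#' bait chromosome and trans noise between all 1 Mb bin pairs; spiked
#' true interactions; finally PCR duplicates at `dup_rate`. Everything
#' is deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `pets` (canonically ordered data.table with read_id,
#'   ends, strands, MAPQs, category), `truth` (list: `pets` per-read
#'   category/duplicate/spike flags, `bins` spiked-bin table, `params`
#'   true background parameters, `bait` the true [bait_region()]),
#'   `config`.
#' @export
simulate_pets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$chrom_sizes
  L <- as.numeric(cs[[config$bait_chrom]])
  l <- config$bait_width
  bs <- config$bait_start; be <- bs + l
  centre <- (bs + be) / 2
  K <- floor(L / l)
  d_strat <- floor(config$D_max / l)
  mu_d <- function(d) pmax(config$mu1 * config$decay^(d - 1),
                           config$lambda_far)
  r_d <- function(d) mu_d(d) * (1 - config$p_intra) / config$p_intra
  lam_inter <- function(chr) {
    if (length(config$lambda_inter) > 1) config$lambda_inter[[chr]]
    else config$lambda_inter
  }
  bait_bins <- floor(bs / l):floor((be - 1) / l)
  rl <- config$read_len
  parts <- list()
  add <- function(chrom1, pos1, chrom2, pos2, category, spike = FALSE) {
    n <- length(pos1)
    if (n == 0) return(NULL)
    data.table(chrom1 = chrom1, pos1 = as.numeric(pos1),
               chrom2 = chrom2, pos2 = as.numeric(pos2),
               category = category, spike = spike)
  }
  with_seed(config$seed, {
    mode <- config$bait_pet_mode
    if (mode == "fractions") {
      tot <- as.vector(stats::rmultinom(1, config$n_pets,
        c(config$self_fraction, config$intra_fraction,
          config$inter_fraction)))
      n_self <- tot[1]; n_ia <- tot[2]; n_ie <- tot[3]
    } else {
      n_self <- round(config$n_pets * config$self_fraction)
    }
    ## 1. self-ligated bulk: both ends inside the bait
    parts$self <- add(config$bait_chrom,
                      runif_pos(n_self, bs, be, L, rl),
                      config$bait_chrom,
                      runif_pos(n_self, bs, be, L, rl), "self_ligated")
    ## 2. bait-anchored cis PETs
    if (mode == "background") {
      bins <- setdiff(0:(K - 1), bait_bins)
      dd <- pmax(1, abs(bins - bait_bins[1]))
      near <- dd <= d_strat
      cnt <- integer(length(bins))
      if (any(near))
        cnt[near] <- rnb0(sum(near), r_d(dd[near]), 1 - config$p_intra)
      cnt[!near] <- stats::rpois(sum(!near), config$lambda_far)
      j <- rep(bins, cnt)
      n_ia_noise <- length(j)
      parts$bait_intra <- add(
        config$bait_chrom, runif_pos(n_ia_noise, bs, be, L, rl),
        config$bait_chrom,
        runif_pos(n_ia_noise, j * l, (j + 1) * l, L, rl), "bait_intra")
    } else {
      down <- runif(n_ia) < config$frac_downstream
      nearm <- runif(n_ia) < config$frac_within_1mb
      mag <- ifelse(nearm,
                    l + runif(n_ia) * (1e6 - l),
                    1e6 + runif(n_ia) * (min(centre, L - centre) - 1e6 - l))
      p2 <- pmin(pmax(centre + ifelse(down, mag, -mag), 0), L - rl)
      parts$bait_intra <- add(
        config$bait_chrom, runif_pos(n_ia, bs, be, L, rl),
        config$bait_chrom, floor(p2), "bait_intra")
    }
    ## 3. bait-anchored trans PETs
    others <- setdiff(names(cs), config$bait_chrom)
    if (mode == "background") {
      tr <- lapply(others, function(chr) {
        Kc <- floor(as.numeric(cs[[chr]]) / 1e6)
        cnt <- stats::rpois(Kc, lam_inter(chr))
        j <- rep(0:(Kc - 1), cnt)
        add(config$bait_chrom, runif_pos(length(j), bs, be, L, rl),
            chr, runif_pos(length(j), j * 1e6, (j + 1) * 1e6,
                           as.numeric(cs[[chr]]), rl), "bait_inter")
      })
      parts$bait_inter <- data.table::rbindlist(tr)
    } else {
      chr <- others[sample.int(length(others), n_ie, replace = TRUE)]
      lens <- as.numeric(cs[chr])
      parts$bait_inter <- add(
        config$bait_chrom, runif_pos(n_ie, bs, be, L, rl),
        chr, floor(runif(n_ie) * (lens - rl)), "bait_inter")
    }
    ## 4. background cis noise: per-pair NB at d <= d_strat, Poisson floor
    ##    beyond (pairs sampled proportional to multiplicity so every far
    ##    pair has the same rate)
    bg <- list()
    for (d in seq_len(d_strat)) {
      b <- 0:(K - 1 - d)
      b <- b[!(b %in% bait_bins) & !((b + d) %in% bait_bins)]
      cnt <- rnb0(length(b), r_d(d), 1 - config$p_intra)
      bb <- rep(b, cnt)
      bg[[d]] <- data.table(b = bb, j = bb + d)
    }
    far_d <- if (K - 2 > d_strat) (d_strat + 1):(K - 2) else integer(0)
    mult <- K - far_d
    n_far <- if (length(far_d))
      stats::rpois(1, config$lambda_far * sum(mult)) else 0L
    if (n_far > 0) {
      dsel <- far_d[sample.int(length(far_d), n_far, replace = TRUE,
                               prob = mult)]
      bsel <- floor(runif(n_far) * (K - dsel))
      ok <- !(bsel %in% bait_bins) & !((bsel + dsel) %in% bait_bins)
      bg[[length(bg) + 1L]] <- data.table(b = bsel[ok], j = bsel[ok] + dsel[ok])
    }
    bgdt <- data.table::rbindlist(bg)
    parts$background_intra <- add(
      config$bait_chrom, runif_pos(nrow(bgdt), bgdt$b * l, (bgdt$b + 1) * l, L, rl),
      config$bait_chrom, runif_pos(nrow(bgdt), bgdt$j * l, (bgdt$j + 1) * l, L, rl),
      "background_intra")
    ## 5. background trans noise, uniform per 1 Mb bin pair
    tr <- lapply(others, function(chr) {
      Lc <- as.numeric(cs[[chr]])
      npair <- floor(L / 1e6) * floor(Lc / 1e6)
      nc <- stats::rpois(1, lam_inter(chr) * npair)
      if (nc == 0) return(NULL)
      p1 <- floor(runif(nc) * (L - rl))
      # the bait-chromosome end must fall outside the bait proper
      inb <- p1 >= bs - rl & p1 < be
      while (any(inb)) {
        p1[inb] <- floor(runif(sum(inb)) * (L - rl))
        inb <- p1 >= bs - rl & p1 < be
      }
      add(config$bait_chrom, p1, chr, floor(runif(nc) * (Lc - rl)),
          "background_inter")
    })
    parts$background_inter <- data.table::rbindlist(tr)
    ## 6. spiked true interactions
    spikes <- config$spikes
    if (!is.null(spikes) && nrow(spikes)) {
      sp <- lapply(seq_len(nrow(spikes)), function(i) {
        s <- spikes[i]
        Lc <- as.numeric(cs[[s$chrom]])
        add(config$bait_chrom, runif_pos(s$count, bs, be, L, rl),
            s$chrom,
            runif_pos(s$count, s$pos - config$spike_halfwidth,
                      s$pos + config$spike_halfwidth, Lc, rl),
            if (s$chrom == config$bait_chrom) "bait_intra" else "bait_inter",
            spike = TRUE)
      })
      parts$spikes <- data.table::rbindlist(sp)
    }
    pets <- data.table::rbindlist(parts[!vapply(parts, is.null, TRUE)])
    n <- nrow(pets)
    pets[, is_duplicate := FALSE]
    ## 7. PCR duplicates: copies of existing PETs (same positions and
    ##    strands, new read ids)
    n_dup <- round(config$dup_rate * n)
    pets[, `:=`(strand1 = c("+", "-")[1 + (runif(n) < 0.5)],
                strand2 = c("+", "-")[1 + (runif(n) < 0.5)])]
    if (n_dup > 0) {
      dup <- pets[sample.int(n, n_dup, replace = TRUE)]
      dup[, is_duplicate := TRUE]
      pets <- rbind(pets, dup)
    }
    N <- nrow(pets)
    pets[, `:=`(
      mapq1 = config$mapq_vals[1 + (runif(N) >= config$mapq_probs[1])],
      mapq2 = config$mapq_vals[1 + (runif(N) >= config$mapq_probs[1])])]
    pets <- pets[sample.int(N)]
    pets[, read_id := sprintf("r%07d", seq_len(N))]
    data.table::setcolorder(pets, c("read_id", "chrom1", "pos1", "strand1",
                                    "mapq1", "chrom2", "pos2", "strand2",
                                    "mapq2", "category"))
    truth_pets <- pets[, .(read_id, category, is_duplicate, spike)]
    out_pets <- canonicalize_pets(
      pets[, .(read_id, chrom1, pos1, strand1, mapq1,
               chrom2, pos2, strand2, mapq2, category)])
    truth_bins <- if (!is.null(spikes) && nrow(spikes)) {
      data.table::copy(spikes)[, halfwidth := config$spike_halfwidth][, `:=`(
        bin_start = data.table::fifelse(kind == "intra",
                                        floor(pos / l) * l,
                                        floor(pos / 1e6) * 1e6),
        bin_end = data.table::fifelse(kind == "intra",
                                      floor(pos / l) * l + l,
                                      floor(pos / 1e6) * 1e6 + 1e6))]
    } else data.table(chrom = character(), pos = numeric(),
                      kind = character(), count = integer(),
                      halfwidth = numeric(),
                      bin_start = numeric(), bin_end = numeric())
    list(pets = out_pets,
         truth = list(
           pets = truth_pets, bins = truth_bins,
           params = list(mu_d = mu_d(seq_len(d_strat)),
                         r_d = r_d(seq_len(d_strat)),
                         p_intra = config$p_intra,
                         lambda_far = config$lambda_far,
                         lambda_inter = config$lambda_inter),
           bait = bait_region(config$bait_chrom, bs, be,
                              source = "heuristic")),
         config = config)
  })
}

## random DNA with no internal occurrence of `avoid`
#' @noRd
random_seq <- function(n, len, avoid = "GATC") {
  out <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  bad <- grepl(avoid, out, fixed = TRUE)
  while (any(bad)) {
    out[bad] <- vapply(seq_len(sum(bad)), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      "")
    bad <- grepl(avoid, out, fixed = TRUE)
  }
  out
}

#' Emit a simulated library as a pair of SAM files
#'
#' Each PET end becomes one mapped single-end SAM record (mate 1 in
#' `path1`, mate 2 in `path2`). A `chimera_fraction` of PETs instead have
#' their mate-2 record emitted unmapped with sequence
#' `fragmentA + GATC + fragmentB`, where the longer, GATC-leading
#' fragment corresponds to the true mate-2 locus; the truth table
#' carries that fragment and the "remapped" coordinates so the rescue
#' path can be tested end to end without an aligner. A chrom.sizes file
#' is written alongside.
#'
#' @param sim result of [simulate_pets()].
#' @param dir output directory (created if needed).
#' @return list of paths: `sam1`, `sam2`, `chrom_sizes`, plus
#'   `chimeras` (data.table: read_id, seq, expected fragment, true
#'   chrom/pos/strand/mapq of the rescuable end).
#' @export
simulate_sam <- function(sim, dir = tempfile("c3s_sim_")) {
  config <- sim$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pets <- sim$pets
  n <- nrow(pets)
  rl <- config$read_len
  chim_idx <- integer(0)
  if (config$chimera_fraction > 0 && n > 0)
    chim_idx <- with_seed(derive_seed(config$seed, 4242L),
                          which(runif(n) < config$chimera_fraction))
  chim <- data.table(read_id = character(), seq = character(),
                     expected_fragment = character(), chrom = character(),
                     pos = numeric(), strand = character(), mapq = integer())
  if (length(chim_idx)) {
    nc <- length(chim_idx)
    chim_seqs <- with_seed(derive_seed(config$seed, 4243L), {
      fragA <- random_seq(nc, 15L)
      fragB <- paste0("GATC", random_seq(nc, 26L))
      list(seq = paste0(fragA, fragB), frag = fragB)
    })
    chim <- data.table(read_id = pets$read_id[chim_idx],
                       seq = chim_seqs$seq,
                       expected_fragment = chim_seqs$frag,
                       chrom = pets$chrom2[chim_idx],
                       pos = pets$pos2[chim_idx],
                       strand = pets$strand2[chim_idx],
                       mapq = pets$mapq2[chim_idx])
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(config$chrom_sizes),
                   as.integer(config$chrom_sizes)))
  sam_line <- function(id, chrom, pos, strand, mapq, seq = "*") {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            id, ifelse(strand == "-", 16L, 0L), chrom,
            as.integer(pos) + 1L, as.integer(mapq),
            paste0(rl, "M"), seq)
  }
  unmapped_line <- function(id, seq)
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", id, seq)
  l1 <- sam_line(pets$read_id, pets$chrom1, pets$pos1, pets$strand1,
                 pets$mapq1)
  l2 <- sam_line(pets$read_id, pets$chrom2, pets$pos2, pets$strand2,
                 pets$mapq2)
  if (length(chim_idx))
    l2[chim_idx] <- unmapped_line(pets$read_id[chim_idx], chim$seq)
  sam1 <- file.path(dir, "mate1.sam"); sam2 <- file.path(dir, "mate2.sam")
  writeLines(c(hdr, l1), sam1)
  writeLines(c(hdr, l2), sam2)
  sizes <- file.path(dir, "genome.chrom.sizes")
  write_chrom_sizes(config$chrom_sizes, sizes)
  list(sam1 = sam1, sam2 = sam2, chrom_sizes = sizes, chimeras = chim)
}

#' Score calls against the simulation truth
#'
#' Sensitivity is the fraction of spiked anchors whose containing bin is
#' called significant; the false-positive rate is the fraction of
#' evaluated non-spiked ("noise") bins called significant. A bin
#' overlapping a spike's +/- halfwidth footprint is not a noise bin (a
#' grid boundary may split a spike's PETs across two bins), and bins
#' overlapping the true bait interval are excluded from scoring
#' altogether: when the estimated bait is a few bases narrower than the
#' true one, self-ligated mass leaks into the flanking partial bin,
#' which is a bait-edge artifact rather than a true or false contact.
#'
#' @param calls call table from [call_interactions()].
#' @param truth truth list from [simulate_pets()].
#' @return list: sensitivity, fpr, n_spikes, n_detected, n_noise_bins,
#'   n_false_positives.
#' @export
evaluate_calls <- function(calls, truth) {
  sp <- truth$bins
  dt <- data.table::as.data.table(calls)
  tb <- truth$bait
  if (!is.null(tb) && nrow(dt))
    dt <- dt[!(target_chrom == tb$chrom & target_start < tb$end &
                 target_end > tb$start)]
  hw <- if (nrow(sp)) sp$halfwidth %||% 0 else 0
  hit_spike <- function(chrom, s, e, kind)
    any(sp$chrom == chrom & sp$pos + hw > s & sp$pos - hw < e &
          sp$kind == kind)
  if (nrow(dt)) {
    dt[, spike := mapply(hit_spike, target_chrom, target_start, target_end,
                         kind)]
  } else dt[, spike := logical(0)]
  detected <- vapply(seq_len(nrow(sp)), function(i) {
    any(dt$spike & dt$significant & dt$target_chrom == sp$chrom[i] &
          dt$target_start <= sp$pos[i] & dt$target_end > sp$pos[i])
  }, TRUE)
  noise <- dt[spike == FALSE]
  list(sensitivity = if (nrow(sp)) mean(detected) else NA_real_,
       fpr = if (nrow(noise)) mean(noise$significant) else 0,
       n_spikes = nrow(sp), n_detected = sum(detected),
       n_noise_bins = nrow(noise),
       n_false_positives = sum(noise$significant))
}
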