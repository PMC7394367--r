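## pet_classification: genome binning at bait resolution, PET category
## assignment, per-bin contact counting and the QC report.

#' Build the bin grid induced by a bait region
#'
#' The bait chromosome is tiled from coordinate 0 in steps of the bait
#' size `l`; the bait interval replaces the bins it overlaps (it is its
#' own bin) and the clipped remainders of the replaced bins are retained
#' as partial bins, so no genomic base belongs to two bins. All other
#' chromosomes are tiled at `inter_bin_size` (1 Mb) for trans contacts.
#' The distance multiplier `d` of an intra bin is the bin-centre to
#' bait-centre distance divided by `l`, rounded to the nearest integer
#' and floored at 1; bait-adjacent partial bins get d = 1.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bait a [bait_region()]; `bait$chrom` must be in `chrom_sizes`.
#' @param inter_bin_size trans bin width in bp (1 Mb).
#' @return object of class `bin_grid`: `intra` (data.table of bins on the
#'   bait chromosome: start, end, is_bait, d), `bin_size`,
#'   `inter_bin_size`, `bait`, `chrom_sizes`.
#' @export
bin_grid <- function(chrom_sizes, bait, inter_bin_size = 1e6) {
  assert_that(bait$chrom %in% names(chrom_sizes),
              "bait chromosome absent from chrom sizes")
  L <- as.numeric(chrom_sizes[[bait$chrom]])
  assert_that(bait$end <= L, "bait extends past chromosome end")
  l <- bait$size_l
  edges <- sort(unique(c(seq(0, L, by = l), L, bait$start, bait$end)))
  bins <- data.table(start = edges[-length(edges)], end = edges[-1])
  bins <- bins[start < end]
  # merge every tile inside the bait into the single bait bin
  inside <- bins$start >= bait$start & bins$end <= bait$end
  bins <- rbind(bins[!inside], data.table(start = bait$start, end = bait$end))
  data.table::setorder(bins, start)
  bins[, is_bait := start == bait$start & end == bait$end]
  centre_b <- (bait$start + bait$end) / 2
  bins[, d := pmax(1, round(abs((start + end) / 2 - centre_b) / l))]
  bins[is_bait == TRUE, d := 0L]
  # clipped partial bins flanking the bait count as the first neighbour
  bins[!is_bait & (end == bait$start | start == bait$end) & (end - start) < l,
       d := 1L]
  structure(list(intra = bins[], bin_size = l,
                 inter_bin_size = as.numeric(inter_bin_size),
                 bait = bait, chrom_sizes = chrom_sizes),
            class = "bin_grid")
}

## index of the intra bin containing each 0-based position
#' @noRd
intra_bin_index <- function(grid, pos) {
  findInterval(pos, grid$intra$start)
}

#' Classify deduplicated PETs against the bait region
#'
#' Membership is the read's stored 5' mapped position lying within the
#' bait interval (half-open); `overlap = TRUE` instead counts any overlap
#' of the aligned span (needs a `width1`/`width2` column).
#'
#' Categories: both ends in bait -> `self_ligated` (capture-efficiency
#' evidence, discarded from calling); exactly one end in bait ->
#' `bait_intra` / `bait_inter` by the other end's chromosome; neither
#' end in bait -> `background_intra` / `background_inter` (the noise
#' observations the background models are fitted on).
#'
#' @param pets deduplicated PET data.table.
#' @param bait a [bait_region()].
#' @param overlap use span overlap instead of 5' position membership.
#' @return list: `pets` (with `category` filled) and `tally` (named
#'   counts per category).
#' @export
classify_pets <- function(pets, bait, overlap = FALSE) {
  dt <- data.table::as.data.table(pets)
  in_bait <- function(chr, p, w) {
    if (overlap) chr == bait$chrom & p < bait$end & (p + w) > bait$start
    else chr == bait$chrom & p >= bait$start & p < bait$end
  }
  w1 <- dt$width1 %||% 0; w2 <- dt$width2 %||% 0
  b1 <- in_bait(dt$chrom1, dt$pos1, w1)
  b2 <- in_bait(dt$chrom2, dt$pos2, w2)
  same <- dt$chrom1 == dt$chrom2
  dt[, category := data.table::fifelse(
    b1 & b2, "self_ligated",
    data.table::fifelse(xor(b1, b2),
      data.table::fifelse(same, "bait_intra", "bait_inter"),
      data.table::fifelse(same, "background_intra", "background_inter")))]
  lv <- c("self_ligated", "bait_intra", "bait_inter",
          "background_intra", "background_inter")
  tally <- vapply(lv, function(k) sum(dt$category == k), 0L)
  list(pets = dt[], tally = tally)
}

#' Count bait-anchored PETs per genomic bin
#'
#' Each `bait_intra` PET increments the intra bin containing its
#' non-bait end; each `bait_inter` PET increments its 1 Mb bin on the
#' other chromosome. PETs whose non-bait end lies on a chromosome absent
#' from the grid's chrom sizes are dropped with a warning.
#'
#' @param pets classified PET data.table.
#' @param grid a [bin_grid()].
#' @return data.table contact vector: kind ("intra"/"inter"), chrom,
#'   start, end, d (NA for inter), count.
#' @export
bin_contacts <- function(pets, grid) {
  dt <- data.table::as.data.table(pets)
  bait <- grid$bait
  out <- list()
  ia <- dt[category == "bait_intra"]
  if (nrow(ia)) {
    in1 <- ia$chrom1 == bait$chrom & ia$pos1 >= bait$start & ia$pos1 < bait$end
    other_pos <- data.table::fifelse(in1, ia$pos2, ia$pos1)
    idx <- intra_bin_index(grid, other_pos)
    cnt <- ia[, .(pos = other_pos)][, .N, by = .(bin = idx)]
    bins <- grid$intra[cnt$bin]
    out$intra <- data.table(kind = "intra", chrom = bait$chrom,
                            start = bins$start, end = bins$end,
                            d = bins$d, count = cnt$N)
  }
  ie <- dt[category == "bait_inter"]
  if (nrow(ie)) {
    in1 <- ie$chrom1 == bait$chrom & ie$pos1 >= bait$start & ie$pos1 < bait$end
    oc <- data.table::fifelse(in1, ie$chrom2, ie$chrom1)
    op <- data.table::fifelse(in1, ie$pos2, ie$pos1)
    known <- oc %in% names(grid$chrom_sizes)
    if (!all(known)) {
      warning(sum(!known), " inter PET(s) on chromosomes absent from ",
              "chrom sizes; dropped")
      oc <- oc[known]; op <- op[known]
    }
    if (length(oc)) {
      B <- grid$inter_bin_size
      j <- floor(op / B)
      cnt <- data.table(chrom = oc, bin = j)[, .N, by = .(chrom, bin)]
      cnt[, `:=`(start = bin * B,
                 end = pmin((bin + 1) * B, grid$chrom_sizes[chrom]))]
      out$inter <- cnt[, .(kind = "inter", chrom, start, end,
                           d = NA_integer_, count = N)]
    }
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  if (!nrow(res))
    res <- data.table(kind = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      d = integer(), count = integer())
  data.table::setorder(res, kind, chrom, start)
  res[]
}

#' Library-level QC report
#'
#' Assembles the quality metrics reported for a capture 3C library:
#' alignment mapping ratio and post-filter retention, PET category
#' counts with percentages of the bait-associated total (1-decimal
#' rounding), the fraction of intra PETs within +/-1 Mb of the bait, the
#' 3' downstream / 5' upstream split of intra PETs with fold ratio, a
#' distance histogram, and per-chromosome inter PET counts.
#'
#' Can be driven either by a classified PET table (`pets` + `bait`) or by
#' pre-computed counts (`counts = list(total, intra, inter,
#' intra_within_1mb, downstream, upstream)`), e.g. from a published
#' tally.
#'
#' @param pets classified PET data.table (optional when `counts` given).
#' @param bait a [bait_region()] (needed with `pets`).
#' @param counts pre-computed tallies (optional).
#' @param aln_stats alignment statistics list from [process_reads()]
#'   (optional).
#' @param hist_breaks distance histogram breaks in bp.
#' @return list of class `c3s_qc`.
#' @export
qc_summary <- function(pets = NULL, bait = NULL, counts = NULL,
                       aln_stats = NULL,
                       hist_breaks = c(seq(-1e6, 1e6, by = 1e5), Inf)) {
  rep <- list()
  if (is.null(counts)) {
    assert_that(!is.null(pets) && !is.null(bait),
                "qc_summary needs either counts or pets + bait")
    dt <- data.table::as.data.table(pets)
    n_self <- sum(dt$category == "self_ligated")
    ia <- dt[category == "bait_intra"]
    ie <- dt[category == "bait_inter"]
    centre <- (bait$start + bait$end) / 2
    other_pos <- function(x) {
      in1 <- x$chrom1 == bait$chrom & x$pos1 >= bait$start & x$pos1 < bait$end
      data.table::fifelse(in1, x$pos2, x$pos1)
    }
    dist_signed <- if (nrow(ia)) other_pos(ia) - centre else numeric()
    counts <- list(total = n_self + nrow(ia) + nrow(ie),
                   intra = nrow(ia), inter = nrow(ie),
                   intra_within_1mb = sum(abs(dist_signed) <= 1e6),
                   downstream = sum(dist_signed > 0),
                   upstream = sum(dist_signed < 0))
    if (nrow(ia))
      rep$intra_distance_hist <- as.list(table(cut(dist_signed,
                                                   breaks = hist_breaks)))
    if (nrow(ie)) {
      oc <- data.table::fifelse(
        ie$chrom1 == bait$chrom & ie$pos1 >= bait$start & ie$pos1 < bait$end,
        ie$chrom2, ie$chrom1)
      rep$inter_per_chrom <- as.list(table(oc))
    }
    rep$background_intra <- sum(dt$category == "background_intra")
    rep$background_inter <- sum(dt$category == "background_inter")
  }
  total <- counts$total
  n_self <- total - counts$intra - counts$inter
  if (is.null(total) || total == 0) {
    warning("zero total PETs; QC percentages are null")
    pct <- list(self_ligated = NULL, intra = NULL, inter = NULL)
  } else {
    pct <- list(self_ligated = round(100 * n_self / total, 1),
                intra = round(100 * counts$intra / total, 1),
                inter = round(100 * counts$inter / total, 1))
  }
  rep$pet_counts <- list(total = total, self_ligated = n_self,
                         intra = counts$intra, inter = counts$inter)
  rep$pet_percent <- pct
  if (!is.null(counts$intra_within_1mb) && counts$intra > 0)
    rep$intra_within_1mb <- list(
      count = counts$intra_within_1mb,
      percent = round(100 * counts$intra_within_1mb / counts$intra, 2))
  if (!is.null(counts$downstream) && !is.null(counts$upstream)) {
    fold <- if (counts$upstream > 0)
      round(counts$downstream / counts$upstream, 2) else NULL
    rep$direction <- list(downstream_3p = counts$downstream,
                          upstream_5p = counts$upstream, fold = fold)
  }
  if (!is.null(aln_stats)) {
    rep$alignment <- list(
      mapping_ratio1 = round(100 * aln_stats$n_mapped1 / aln_stats$n_records1, 2),
      mapping_ratio2 = round(100 * aln_stats$n_mapped2 / aln_stats$n_records2, 2),
      retention1 = round(100 * aln_stats$n_postfilter1 / aln_stats$n_records1, 2),
      retention2 = round(100 * aln_stats$n_postfilter2 / aln_stats$n_records2, 2),
      n_orphans = aln_stats$n_orphans,
      n_duplicates = aln_stats$n_duplicates,
      rescue = aln_stats$rescue)
  }
  class(rep) <- "c3s_qc"
  rep
}

#' @export
print.c3s_qc <- function(x, ...) {
  pc <- x$pet_counts; pp <- x$pet_percent
  cat("<capture3c QC>\n")
  cat(sprintf("  PETs: %s total | self-ligated %s (%s%%) | intra %s (%s%%) | inter %s (%s%%)\n",
              pc$total, pc$self_ligated, pp$self_ligated, pc$intra,
              pp$intra, pc$inter, pp$inter))
  if (!is.null(x$intra_within_1mb))
    cat(sprintf("  intra within +/-1Mb: %d (%.2f%%)\n",
                x$intra_within_1mb$count, x$intra_within_1mb$percent))
  if (!is.null(x$direction))
    cat(sprintf("  direction: %d downstream / %d upstream (%.2f fold)\n",
                x$direction$downstream_3p, x$direction$upstream_5p,
                x$direction$fold))
  invisible(x)
}
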