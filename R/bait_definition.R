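## bait_definition: locate the dCas9/sgRNA-captured interval from the
## read-depth signal around the sgRNA target site. The bait width is the
## intra-chromosomal bin size l used by all downstream modelling.

#' Construct a bait region
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param target_site 0-based sgRNA target position (defaults to the
#'   interval midpoint); must lie inside the interval.
#' @param source one of "heuristic", "external_bed", "fixed".
#' @return object of class `bait_region` with fields chrom, start, end,
#'   size_l (= end - start), target_site, source.
#' @export
bait_region <- function(chrom, start, end, target_site = NULL,
                        source = "heuristic") {
  assert_that(start >= 0 && start < end, "bait requires 0 <= start < end")
  target_site <- target_site %||% floor((start + end) / 2)
  assert_that(target_site >= start && target_site < end,
              "target_site must lie inside the bait interval")
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), size_l = as.numeric(end - start),
                 target_site = as.numeric(target_site), source = source),
            class = "bait_region")
}

#' @export
print.bait_region <- function(x, ...) {
  cat(sprintf("<bait_region> %s:%d-%d (l = %d bp, target %d, source %s)\n",
              x$chrom, x$start, x$end, x$size_l, x$target_site, x$source))
  invisible(x)
}

#' Bait region from an external peak BED
#'
#' Picks the BED interval containing the sgRNA target site (external
#' peak callers such as MACS2 are accepted as input, never run here).
#'
#' @param bed data.table from [read_bed()].
#' @param chrom,target_site sgRNA target coordinate.
#' @export
bait_from_bed <- function(bed, chrom, target_site) {
  hit <- bed[bed$chrom == chrom & bed$start <= target_site &
               bed$end > target_site]
  assert_that(nrow(hit) >= 1, "no BED peak contains the sgRNA target site")
  bait_region(chrom, hit$start[1], hit$end[1], target_site,
              source = "external_bed")
}

#' Build a per-base read-depth track over a window
#'
#' depth[i] is the number of reads whose aligned span covers base
#' origin + i - 1 (0-based genomic coordinates). Reads are extended to
#' `frag_len` when given, otherwise their aligned width is used.
#'
#' @param ends data.table of aligned ends on the bait chromosome
#'   (chrom, pos, width).
#' @param chrom chromosome of the window.
#' @param window_start,window_end 0-based half-open window; must lie
#'   within the chromosome.
#' @param chrom_len chromosome length for bounds checking (optional).
#' @param frag_len fixed fragment extension length (optional).
#' @return list of class `depth_track`: chrom, origin, depth (integer
#'   vector of length window_end - window_start).
#' @export
build_depth_track <- function(ends, chrom, window_start, window_end,
                              chrom_len = NULL, frag_len = NULL) {
  assert_that(window_start >= 0 && window_start < window_end,
              "invalid window")
  if (!is.null(chrom_len))
    assert_that(window_end <= chrom_len, "window outside chromosome")
  n <- as.integer(window_end - window_start)
  dt <- data.table::as.data.table(ends)[chrom, on = "chrom", nomatch = NULL]
  depth <- integer(n)
  if (nrow(dt)) {
    w <- if (!is.null(frag_len)) rep(as.integer(frag_len), nrow(dt))
    else as.integer(dt$width %||% 36L)
    s <- pmax(as.integer(dt$pos) - as.integer(window_start), 0L)
    e <- pmin(as.integer(dt$pos) + w - as.integer(window_start), n)
    ok <- s < n & e > 0L & e > s
    # difference-array coverage: +1 at span starts, -1 past span ends
    diffv <- integer(n + 1L)
    if (any(ok)) {
      tab_s <- tabulate(s[ok] + 1L, nbins = n + 1L)
      tab_e <- tabulate(e[ok] + 1L, nbins = n + 1L)
      diffv <- tab_s - tab_e
    }
    depth <- cumsum(diffv)[seq_len(n)]
  }
  structure(list(chrom = chrom, origin = as.numeric(window_start),
                 depth = depth), class = "depth_track")
}

## cumulative-sum mean of depth over clipped [lo, hi] (0-based genomic,
## inclusive); vectorized over positions.
#' @noRd
window_mean <- function(track, lo, hi) {
  n <- length(track$depth)
  cs <- c(0, cumsum(as.numeric(track$depth)))
  i0 <- pmax(as.integer(lo - track$origin), 0L)
  i1 <- pmin(as.integer(hi - track$origin), n - 1L)
  (cs[i1 + 2L] - cs[i0 + 1L]) / (i1 - i0 + 1L)
}

#' Local background depth around the sgRNA target site
#'
#' Arithmetic mean of per-base depth over a `window`-bp region centred on
#' the target site, clipped to the available track (hence to chromosome
#' bounds). 100 kb by default.
#'
#' @param track depth track from [build_depth_track()].
#' @param target_site 0-based position within the track.
#' @param window total window width in bp.
#' @export
local_background <- function(track, target_site, window = 100000L) {
  assert_that(target_site >= track$origin &&
                target_site < track$origin + length(track$depth),
              "target_site outside depth track")
  half <- floor(window / 2)
  window_mean(track, target_site - half, target_site + half - 1)
}

#' Smoothed read depth at a position
#'
#' Mean depth over the position's up- and downstream `halfwin` bp
#' (a 2*halfwin + 1 window, clipped at track edges).
#'
#' @param track depth track.
#' @param pos 0-based position(s) within the track (vectorized).
#' @param halfwin half-window in bp (50 by default).
#' @export
smoothed_depth <- function(track, pos, halfwin = 50L) {
  assert_that(all(pos >= track$origin &
                    pos < track$origin + length(track$depth)),
              "pos outside depth track")
  window_mean(track, pos - halfwin, pos + halfwin)
}

#' Define the bait region from the local read-depth signal
#'
#' Starting at the sgRNA target site, the bait is extended outward, base
#' by base in each direction, over consecutive positions whose smoothed
#' depth is strictly greater than the local background; each direction
#' stops at its first failing position (no gap tolerance by default) or
#' at `max_extent`. If no enrichment is found (resulting interval
#' narrower than `min_bait_size`), a fixed `fallback_size` bin centred on
#' the target site is returned with source "fixed" — echoing the fixed
#' 2 kb bins of earlier capture methods.
#'
#' @param track depth track covering target_site +/- max_extent (clipped
#'   to the chromosome).
#' @param target_site 0-based sgRNA target position.
#' @param window local-background window (bp).
#' @param halfwin smoothing half-window (bp).
#' @param max_extent maximum extension per direction (bp); unbounded
#'   baits would break the binning model.
#' @param gap number of consecutive failing positions tolerated before
#'   stopping (0 = strict first failure).
#' @param min_bait_size minimum credible bait width (bp).
#' @param fallback_size width of the fixed fallback bin (bp); `NULL`
#'   disables the fallback and makes absent signal a fatal error.
#' @param chrom_len chromosome length (clips the fallback interval).
#' @return a [bait_region()].
#' @export
define_bait <- function(track, target_site, window = 100000L, halfwin = 50L,
                        max_extent = 20000L, gap = 0L, min_bait_size = 200L,
                        fallback_size = 2000L, chrom_len = NULL) {
  bg <- local_background(track, target_site, window)
  lo_lim <- max(track$origin, target_site - max_extent)
  hi_lim <- min(track$origin + length(track$depth) - 1, target_site + max_extent)
  pos <- seq(lo_lim, hi_lim)
  sm <- smoothed_depth(track, pos, halfwin)
  above <- sm > bg
  centre <- which(pos == target_site)
  extend <- function(idx_seq) {
    run <- 0L; fails <- 0L
    for (i in idx_seq) {
      if (above[i]) { run <- run + 1L + fails; fails <- 0L }
      else { fails <- fails + 1L; if (fails > gap) break }
    }
    run
  }
  right <- if (above[centre] && centre < length(pos))
    extend(seq(centre + 1L, length(pos))) else 0L
  left  <- if (above[centre] && centre > 1L)
    extend(seq(centre - 1L, 1L)) else 0L
  s <- target_site - left
  e <- target_site + right + 1   # half-open
  if (!above[centre] || (e - s) < min_bait_size) {
    if (is.null(fallback_size))
      stop("no bait signal at target site and fallback disabled")
    half <- floor(fallback_size / 2)
    s <- max(0, target_site - half)
    e <- s + fallback_size
    if (!is.null(chrom_len) && e > chrom_len) { e <- chrom_len; s <- e - fallback_size }
    return(bait_region(track$chrom, s, e, target_site, source = "fixed"))
  }
  bait_region(track$chrom, s, e, target_site, source = "heuristic")
}
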