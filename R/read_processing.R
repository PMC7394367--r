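## read_processing: DpnII-junction rescue, MAPQ filtering, mate pairing
## and PCR de-duplication. Output is the clean PET table every downstream
## stage consumes.

#' Trim a read at DpnII digestion sites and keep the longest fragment
#'
#' Proximity ligation through DpnII leaves GATC junctions inside chimeric
#' reads. The read is split at the start of every `GATC` occurrence
#' (DpnII cuts 5' of GATC, so every fragment after the first begins with
#' GATC when `keep_site = TRUE`); the longest fragment is returned and is
#' rescuable when strictly longer than `min_fragment`. Ties are broken in
#' favour of the 5'-most fragment.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param min_fragment minimum rescuable fragment length in bp (kept
#'   requires length > `min_fragment`).
#' @param keep_site keep the GATC motif at the 5' end of downstream
#'   fragments (the enzyme's biology); `FALSE` drops it.
#' @return list with `fragment` (string), `offset` (0-based start of the
#'   fragment within the read) and `kept` (logical).
#' @export
trim_at_dpnii <- function(seq, min_fragment = 20L, keep_site = TRUE) {
  if (is.na(seq) || !nzchar(seq))
    return(list(fragment = "", offset = 0L, kept = FALSE))
  hits <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    return(list(fragment = seq, offset = 0L,
                kept = nchar(seq) > min_fragment))
  cuts <- as.integer(hits) - 1L              # 0-based split points
  starts <- unique(c(0L, cuts))
  ends <- c(starts[-1], nchar(seq))
  if (!keep_site) starts <- c(starts[1], starts[-1] + 4L)
  lens <- ends - starts
  i <- which.max(lens)                        # which.max takes the 5'-most tie
  frag <- substr(seq, starts[i] + 1L, ends[i])
  list(fragment = frag, offset = starts[i], kept = lens[i] > min_fragment)
}

#' Filter aligned ends on mapping quality
#'
#' Retains exactly the ends with `mapq` strictly greater than the
#' threshold (MAPQ > 30 by default).
#'
#' @param ends data.table of aligned ends with a `mapq` column.
#' @param threshold strict lower bound on MAPQ.
#' @export
filter_mapq <- function(ends, threshold = 30L) {
  data.table::as.data.table(ends)[mapq > threshold]
}

## Strip mate suffixes ("/1", "/2") and trailing space-comments so mate
## files index into the same read-id space.
#' @noRd
normalize_read_id <- function(id) sub("/[12]$", "", sub("[ \t].*$", "", id))

#' Pair aligned ends from the two mate files into PETs
#'
#' One PET per read id present in both (post-filter) inputs; read ids
#' present in only one input are counted as orphans. PET ends are stored
#' in canonical order: the (chrom, pos) lexicographically smallest end
#' first. A duplicated read id within one mate file keeps its first
#' record with a warning.
#'
#' @param ends1,ends2 data.tables of aligned ends (read_id, chrom, pos,
#'   strand, mapq).
#' @return list with `pets` (data.table; category = "unclassified") and
#'   `n_orphans`.
#' @export
pair_ends <- function(ends1, ends2) {
  e1 <- data.table::as.data.table(ends1)
  e2 <- data.table::as.data.table(ends2)
  for (e in list(e1, e2)) if (nrow(e)) e[, read_id := normalize_read_id(read_id)]
  dedup_ids <- function(e, which) {
    if (nrow(e) && anyDuplicated(e$read_id)) {
      warning("duplicate read ids within mate file ", which, "; keeping first")
      e <- e[!duplicated(read_id)]
    }
    e
  }
  e1 <- dedup_ids(e1, 1L); e2 <- dedup_ids(e2, 2L)
  keep <- c("read_id", "chrom", "pos", "strand", "mapq")
  m <- merge(e1[, keep, with = FALSE], e2[, keep, with = FALSE],
             by = "read_id", suffixes = c("1", "2"))
  n_orphans <- (nrow(e1) - nrow(m)) + (nrow(e2) - nrow(m))
  pets <- m[, .(read_id, chrom1, pos1, strand1, mapq1,
                chrom2, pos2, strand2, mapq2)]
  pets[, category := "unclassified"]
  list(pets = canonicalize_pets(pets), n_orphans = n_orphans)
}

#' Put PET ends in canonical order
#'
#' The (chrom, pos) lexicographically smallest end is stored as end 1, so
#' duplicate detection and binning are orientation-free.
#' @param pets PET data.table.
#' @export
canonicalize_pets <- function(pets) {
  dt <- data.table::as.data.table(pets)
  if (!nrow(dt)) return(dt)
  swap <- dt$chrom2 < dt$chrom1 | (dt$chrom2 == dt$chrom1 & dt$pos2 < dt$pos1)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, pos1, strand1, mapq1)]
    dt[swap, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2,
                  mapq1 = mapq2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, strand2 = tmp$strand1,
                  mapq2 = tmp$mapq1)]
  }
  dt[]
}

#' Remove PCR duplicates from a PET table
#'
#' PETs sharing identical positions at both ends are PCR duplicates; one
#' representative (the first encountered) is retained per key. The key
#' includes both strands by default (standard practice; the position-only
#' alternative is available via `use_strand = FALSE`). Output is sorted
#' by key, so the result is deterministic and order-independent.
#'
#' @param pets canonically ordered PET data.table.
#' @param use_strand include strands in the duplicate key.
#' @export
dedup_pets <- function(pets, use_strand = TRUE) {
  dt <- data.table::as.data.table(pets)
  if (!nrow(dt)) return(dt)
  keycols <- if (use_strand)
    c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  else c("chrom1", "pos1", "chrom2", "pos2")
  out <- dt[!duplicated(dt, by = keycols)]
  data.table::setorderv(out, keycols)
  out[]
}

#' Run the whole read-processing stage on two mate alignment files
#'
#' SAM/BAM in, deduplicated PET table out: read both mates, (optionally)
#' count rescuable unmapped chimeras, apply the strict MAPQ filter, pair,
#' and de-duplicate. Rescued fragments are reported for QC; remapping is
#' delegated to an external aligner (or supplied directly by the
#' simulator in pure-synthetic mode).
#'
#' @param path1,path2 SAM/BAM files for mate 1 and mate 2.
#' @param min_mapq strict MAPQ threshold.
#' @param rescue attempt DpnII trimming of unmapped records (statistics
#'   only; no remapping is performed here).
#' @param min_fragment minimum rescuable fragment length.
#' @return list: `pets`, `stats` (per-mate record counts, unmapped,
#'   post-filter retention, orphans, duplicate count, rescue stats).
#' @export
process_reads <- function(path1, path2, min_mapq = 30L, rescue = TRUE,
                          min_fragment = 20L) {
  a1 <- read_alignments(path1, keep_unmapped = rescue)
  a2 <- read_alignments(path2, keep_unmapped = rescue)
  rescue_stats <- NULL
  if (rescue) {
    un <- rbind(a1$unmapped, a2$unmapped)
    if (!is.null(un) && nrow(un)) {
      res <- lapply(un$seq, trim_at_dpnii, min_fragment = min_fragment)
      rescue_stats <- list(
        n_unmapped = nrow(un),
        n_rescuable = sum(vapply(res, `[[`, TRUE, "kept")))
    } else rescue_stats <- list(n_unmapped = 0L, n_rescuable = 0L)
  }
  f1 <- filter_mapq(a1$ends, min_mapq)
  f2 <- filter_mapq(a2$ends, min_mapq)
  paired <- pair_ends(f1, f2)
  pets <- dedup_pets(paired$pets)
  list(pets = pets,
       stats = list(
         n_records1 = a1$n_mapped + a1$n_unmapped,
         n_records2 = a2$n_mapped + a2$n_unmapped,
         n_mapped1 = a1$n_mapped, n_mapped2 = a2$n_mapped,
         n_unmapped1 = a1$n_unmapped, n_unmapped2 = a2$n_unmapped,
         n_postfilter1 = nrow(f1), n_postfilter2 = nrow(f2),
         n_paired = nrow(paired$pets), n_orphans = paired$n_orphans,
         n_duplicates = nrow(paired$pets) - nrow(pets),
         rescue = rescue_stats))
}
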