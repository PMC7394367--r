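## genomic_io: readers/writers for every external format the pipeline
## touches. All internal coordinates are 0-based half-open (BED
## convention); SAM's 1-based POS is converted on ingest and nowhere else.

#' Read a UCSC chrom.sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp).
#' @return named integer vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "len")[1:2])
  assert_that(ncol(dt) >= 2, "chrom.sizes must have two columns")
  assert_that(!anyDuplicated(dt$chrom), "duplicate chromosome names")
  assert_that(all(dt$len > 0), "chromosome lengths must be > 0")
  stats::setNames(as.numeric(dt$len), dt$chrom)
}

#' Write a chrom.sizes table
#' @param sizes named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  data.table::fwrite(data.table(chrom = names(sizes), len = as.integer(sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read aligned ends from a SAM or BAM file
#'
#' One record per mapped primary alignment; secondary and supplementary
#' alignments are skipped and unmapped records are counted (and, when
#' `keep_unmapped = TRUE`, returned with their sequence so they can be
#' rescued by DpnII-junction trimming).
#'
#' SAM text input is converted through [Rsamtools::asBam()]; the header
#' must carry a sequence dictionary (`@SQ` lines), which is also the
#' cross-check against the chrom.sizes table.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param keep_unmapped also return unmapped records with sequences.
#' @return list with elements `ends` (data.table: read_id, chrom, pos
#'   (0-based leftmost), strand, mapq, width), `n_unmapped`, `n_mapped`,
#'   and (optionally) `unmapped` (data.table: read_id, seq).
#' @export
read_alignments <- function(path, keep_unmapped = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("cannot parse SAM (missing/invalid header?): ",
                               conditionMessage(e), call. = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (length(hdr$targets) == 0L)
    stop("missing header sequence dictionary in ", path)
  p_mapped <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "rname", "pos", "strand", "mapq", "qwidth"))
  m <- Rsamtools::scanBam(bam, param = p_mapped)[[1]]
  ends <- data.table(
    read_id = m$qname,
    chrom   = as.character(m$rname),
    pos     = as.integer(m$pos) - 1L,      # 1-based SAM -> 0-based
    strand  = as.character(m$strand),
    mapq    = as.integer(m$mapq),
    width   = as.integer(m$qwidth))
  p_un <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "seq"))
  u <- Rsamtools::scanBam(bam, param = p_un)[[1]]
  out <- list(ends = ends, n_mapped = nrow(ends),
              n_unmapped = length(u$qname))
  if (keep_unmapped)
    out$unmapped <- data.table(read_id = u$qname,
                               seq = as.character(u$seq))
  out
}

#' Read a BED3+ file of intervals
#'
#' @param path BED file (0-based half-open, as BED natively is).
#' @return data.table with columns chrom, start, end (and name if present).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  assert_that(ncol(dt) >= 3, "BED requires at least 3 columns")
  out <- dt[, 1:3]
  data.table::setnames(out, c("chrom", "start", "end"))
  out[, `:=`(start = as.numeric(start), end = as.numeric(end))]
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad))
    stop(sprintf("malformed BED record at line %d: start >= end (%s:%s-%s)",
                 bad[1], out$chrom[bad[1]], out$start[bad[1]], out$end[bad[1]]))
  if (ncol(dt) >= 4) out[, name := as.character(dt[[4]])]
  out[]
}

#' Write intervals as BED3
#' @param intervals data.table/data.frame with chrom, start, end.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table::as.data.table(intervals)[, .(chrom, start = as.integer(start),
                                                 end = as.integer(end))]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## WashU longrange score string: BF rounded to 2 decimals, with a single
## trailing zero dropped ("25.00" -> "25.0") to match browser convention.
#' @noRd
format_score <- function(x) sub("0$", "", sprintf("%.2f", x))

#' Write interaction calls in WashU longrange format
#'
#' Tab-delimited text, one interaction per line:
#' `chrom  start  end  chrom2:start2-end2,score`, 0-based half-open
#' starts as in BED, sorted by chromosome then start. The score is the
#' Bayes factor rounded to 2 decimals (the pipeline's decision
#' statistic). Block-gzip + tabix indexing for browser loading is a
#' documented post-step, not performed here.
#'
#' @param calls data.table of interaction calls (see
#'   [call_interactions()]); needs bait/target interval columns and
#'   `bayes_factor`.
#' @param path output path.
#' @export
write_longrange <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(calls)
  lines <- dt[, .(chrom = bait_chrom, start = as.integer(bait_start),
                  end = as.integer(bait_end),
                  partner = sprintf("%s:%d-%d,%s", target_chrom,
                                    as.integer(target_start),
                                    as.integer(target_end),
                                    format_score(bayes_factor)))]
  data.table::setorder(lines, chrom, start)
  data.table::fwrite(lines, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a WashU longrange file back into intervals and scores
#' @param path longrange file written by [write_longrange()].
#' @return data.table: bait_chrom, bait_start, bait_end, target_chrom,
#'   target_start, target_end, score.
#' @export
read_longrange <- function(path) {
  if (file.size(path) == 0)
    return(data.table(bait_chrom = character(), bait_start = numeric(),
                      bait_end = numeric(), target_chrom = character(),
                      target_start = numeric(), target_end = numeric(),
                      score = numeric()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("bait_chrom", "bait_start",
                                        "bait_end", "partner"))
  m <- regmatches(dt$partner,
                  regexec("^([^:]+):([0-9]+)-([0-9]+),(.*)$", dt$partner))
  assert_that(all(lengths(m) == 5L), "malformed longrange partner field")
  dt[, `:=`(target_chrom = vapply(m, `[`, "", 2L),
            target_start = as.numeric(vapply(m, `[`, "", 3L)),
            target_end   = as.numeric(vapply(m, `[`, "", 4L)),
            score        = as.numeric(vapply(m, `[`, "", 5L)))]
  dt[, partner := NULL]
  dt[]
}

#' Write / read a PET table as TSV
#'
#' Columns: read_id, chrom1, pos1, strand1, mapq1, chrom2, pos2, strand2,
#' mapq2 and, when present, category.
#' @param pets PET data.table.
#' @param path file path.
#' @export
write_pets <- function(pets, path) {
  cols <- intersect(c("read_id", "chrom1", "pos1", "strand1", "mapq1",
                      "chrom2", "pos2", "strand2", "mapq2", "category"),
                    names(pets))
  data.table::fwrite(data.table::as.data.table(pets)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_pets
#' @export
read_pets <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  dt[]
}

#' Write interaction calls as TSV
#' @param calls call table from [call_interactions()].
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  dt <- data.table::copy(data.table::as.data.table(calls))
  for (col in intersect(c("bait_start", "bait_end", "target_start",
                          "target_end"), names(dt)))
    data.table::set(dt, j = col, value = as.integer(dt[[col]]))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Serialize a QC report (or any report list) to JSON
#' @param x report list.
#' @param path output path.
#' @export
write_qc_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
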