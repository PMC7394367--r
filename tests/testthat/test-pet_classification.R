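bait2500 <- bait_region("chr1", 5e6, 5e6 + 2500)
sizes3 <- c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7)

test_that("bin_grid tiles the chromosome with the bait as its own bin", {
  g <- bin_grid(sizes3, bait2500)
  bins <- g$intra
  # full partition: contiguous, non-overlapping, covers [0, L)
  expect_equal(bins$start[1], 0)
  expect_equal(bins$end[nrow(bins)], 1e7)
  expect_equal(bins$start[-1], bins$end[-nrow(bins)])
  expect_equal(sum(bins$is_bait), 1L)
  expect_equal(bins[is_bait == TRUE, .(start, end)],
               data.table::data.table(start = 5e6, end = 5e6 + 2500))
  expect_equal(bins[is_bait == TRUE]$d, 0L)
  # unaligned bait produces flanking partial bins with d = 1
  boff <- bait_region("chr1", 5e6 + 700, 5e6 + 3200)
  g2 <- bin_grid(sizes3, boff)
  partial <- g2$intra[!is_bait & (end - start) < 2500 &
                        (end == boff$start | start == boff$end)]
  expect_gte(nrow(partial), 1L)
  expect_true(all(partial$d == 1L))
  # every base belongs to exactly one bin
  expect_equal(sum(g2$intra$end - g2$intra$start), 1e7)
})

test_that("distance multipliers follow the arithmetic rule", {
  g <- bin_grid(sizes3, bait2500)
  # one bin to the right of the bait -> d = 1
  idx <- capture3c:::intra_bin_index(g, 5e6 + 2500 + 100)
  expect_equal(g$intra$d[idx], 1L)
  # +/- 1 Mb from a 2.5 kb bait -> d = 400
  idx2 <- capture3c:::intra_bin_index(g, 5e6 + 1250 + 1e6)
  expect_equal(g$intra$d[idx2], 400L)
  idx3 <- capture3c:::intra_bin_index(g, 5e6 + 1250 - 1e6)
  expect_equal(g$intra$d[idx3], 400L)
})

test_that("classification matches the simulator truth table exactly", {
  sim <- default_sim()
  cl <- classify_pets(sim$pets, sim$truth$bait)
  expect_equal(cl$pets$category, sim$pets$category)
  # partition property: every PET in exactly one category
  expect_equal(sum(cl$tally), nrow(sim$pets))
  # hand-built corner cases
  mk <- function(c1, p1, c2, p2)
    data.table::data.table(read_id = "x", chrom1 = c1, pos1 = p1,
                           strand1 = "+", mapq1 = 42L, chrom2 = c2,
                           pos2 = p2, strand2 = "+", mapq2 = 42L,
                           category = "unclassified")
  expect_equal(classify_pets(mk("chr1", 5e6, "chr1", 5e6 + 2499),
                             bait2500)$pets$category, "self_ligated")
  # boundary: end exactly at bait end is outside (half-open)
  expect_equal(classify_pets(mk("chr1", 5e6, "chr1", 5e6 + 2500),
                             bait2500)$pets$category, "bait_intra")
  expect_equal(classify_pets(mk("chr1", 5e6 + 10, "chr2", 100),
                             bait2500)$pets$category, "bait_inter")
  expect_equal(classify_pets(mk("chr1", 100, "chr1", 7e6),
                             bait2500)$pets$category, "background_intra")
  expect_equal(classify_pets(mk("chr1", 100, "chr3", 7e6),
                             bait2500)$pets$category, "background_inter")
})

test_that("bin_contacts counts every bait PET exactly once", {
  sim <- default_sim()
  cl <- classify_pets(sim$pets, sim$truth$bait)
  g <- bin_grid(sizes3, sim$truth$bait)
  cv <- bin_contacts(cl$pets, g)
  expect_equal(sum(cv$count),
               sum(cl$tally[c("bait_intra", "bait_inter")]))
  expect_equal(sum(cv[kind == "intra"]$count), cl$tally[["bait_intra"]])
  # spiked bins carry at least their spike counts
  sp <- sim$truth$bins[kind == "intra"]
  for (i in seq_len(nrow(sp))) {
    got <- cv[kind == "intra" & start <= sp$pos[i] & end > sp$pos[i]]
    expect_gte(sum(got$count), 1)
  }
  # binning is order-independent
  cv2 <- bin_contacts(cl$pets[sample(nrow(cl$pets))], g)
  expect_equal(cv2, cv)
  # unknown chromosome is dropped with a warning
  odd <- data.table::copy(cl$pets[category == "bait_inter"][1])
  odd[, chrom2 := "chrUn"]
  expect_warning(bin_contacts(rbind(cl$pets, odd), g), "absent")
})

test_that("a spiked loop of 30 PETs lands in one bin with count >= 30", {
  cfg <- sim_config(seed = 12, mu1 = 0, lambda_far = 0, lambda_inter = 0,
                    dup_rate = 0, self_fraction = 0.1, n_pets = 100,
                    spikes = data.table::data.table(
                      chrom = "chr1", pos = 5e6 + 2500 + 1250,
                      kind = "intra", count = 30L))
  sim <- simulate_pets(cfg)
  cl <- classify_pets(sim$pets, sim$truth$bait)
  g <- bin_grid(sizes3, sim$truth$bait)
  cv <- bin_contacts(cl$pets, g)
  expect_equal(cv[kind == "intra" & start == 5e6 + 2500]$count, 30L)
})

test_that("qc_summary reproduces the published tally arithmetic", {
  qc <- qc_summary(counts = list(total = 11692, intra = 118, inter = 57,
                                 intra_within_1mb = 96, downstream = 80,
                                 upstream = 38))
  expect_equal(qc$pet_counts$self_ligated, 11517)
  expect_equal(qc$pet_percent$self_ligated, 98.5)
  expect_equal(qc$pet_percent$intra, 1.0)
  expect_equal(qc$pet_percent$inter, 0.5)
  expect_equal(qc$intra_within_1mb$percent, 81.36)
  expect_equal(qc$direction$fold, 2.11)
})

test_that("qc_summary from a classified library is internally consistent", {
  sim <- default_sim()
  cl <- classify_pets(sim$pets, sim$truth$bait)
  qc <- qc_summary(pets = cl$pets, bait = sim$truth$bait)
  expect_equal(qc$pet_counts$total,
               sum(cl$tally[c("self_ligated", "bait_intra", "bait_inter")]))
  expect_equal(qc$pet_counts$intra, cl$tally[["bait_intra"]])
  expect_lte(qc$intra_within_1mb$count, qc$pet_counts$intra)
  # serializes to JSON
  f <- tempfile(fileext = ".json")
  write_qc_json(qc, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))
  # zero-PET report warns and nulls percentages
  expect_warning(qc0 <- qc_summary(counts = list(total = 0, intra = 0,
                                                 inter = 0)), "zero")
  expect_null(qc0$pet_percent$self_ligated)
})
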