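test_that("trim_at_dpnii handles stated cases", {
  # no cut site: whole read kept
  s <- strrep("AC", 25)
  r <- trim_at_dpnii(s)
  expect_equal(r$fragment, s)
  expect_true(r$kept)
  expect_equal(r$offset, 0L)
  # AAAAA|GATC+T*40: downstream 44-mer wins and starts with GATC
  s2 <- paste0("AAAAA", "GATC", strrep("T", 40))
  r2 <- trim_at_dpnii(s2)
  expect_equal(nchar(r2$fragment), 44L)
  expect_equal(substr(r2$fragment, 1, 4), "GATC")
  expect_equal(r2$offset, 5L)
  expect_true(r2$kept)
  # longest fragment at threshold: > 20 strictly required
  s3 <- paste0(strrep("A", 20), "GATC", strrep("T", 10))
  expect_false(trim_at_dpnii(s3)$kept)        # longest piece is exactly 20
  s4 <- paste0(strrep("A", 21), "GATC", strrep("T", 10))
  expect_true(trim_at_dpnii(s4)$kept)
  # empty / NA input
  expect_false(trim_at_dpnii("")$kept)
  expect_false(trim_at_dpnii(NA_character_)$kept)
  # drop-site variant removes the motif from downstream fragments
  r5 <- trim_at_dpnii(s2, keep_site = FALSE)
  expect_equal(r5$fragment, strrep("T", 40))
})

test_that("trim_at_dpnii matches the brute-force enumeration oracle", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_read(sample(10:80, 1), n_gatc = sample(0:3, 1))
    got <- trim_at_dpnii(s)
    want <- oracle_trim(s)
    expect_equal(got$fragment, want$fragment, info = s)
    expect_equal(got$kept, want$kept, info = s)
    # no internal GATC except at the fragment start
    inner <- substr(got$fragment, 2, nchar(got$fragment))
    expect_false(grepl("GATC", inner, fixed = TRUE), info = s)
  }
})

test_that("filter_mapq is strictly greater-than", {
  ends <- make_ends(paste0("r", 1:4), mapq = c(0L, 30L, 31L, 42L))
  expect_equal(filter_mapq(ends)$mapq, c(31L, 42L))
  all42 <- make_ends(paste0("r", 1:5))
  expect_equal(nrow(filter_mapq(all42)), 5L)
})

test_that("pair_ends intersects read ids and counts orphans", {
  e1 <- make_ends(c("A", "B", "C"))
  e2 <- make_ends(c("B", "C", "D"), pos = c(5000, 6000, 7000))
  p <- pair_ends(e1, e2)
  expect_equal(nrow(p$pets), 2L)
  expect_equal(p$n_orphans, 2L)
  expect_setequal(p$pets$read_id, c("B", "C"))
  # empty second mate
  p0 <- pair_ends(e1, e1[0])
  expect_equal(nrow(p0$pets), 0L)
  expect_equal(p0$n_orphans, 3L)
  # identity: pair(x, x) gives |x| PETs, zero orphans
  pid <- pair_ends(e1, e1)
  expect_equal(nrow(pid$pets), 3L)
  expect_equal(pid$n_orphans, 0L)
  # mate suffixes are stripped before matching
  e1s <- make_ends(c("A/1", "B/1"))
  e2s <- make_ends(c("A/2", "B extra-comment"), pos = c(900, 950))
  expect_equal(nrow(pair_ends(e1s, e2s)$pets), 2L)
  # duplicate id within one file: keep first, warn
  expect_warning(pd <- pair_ends(make_ends(c("A", "A")), make_ends("A", pos = 9)),
                 "duplicate")
  expect_equal(nrow(pd$pets), 1L)
})

test_that("pairing conserves reads: |pets| + orphans covers both inputs", {
  set.seed(5)
  for (i in 1:20) {
    ids <- paste0("r", 1:50)
    k1 <- sample(ids, sample(10:50, 1))
    k2 <- sample(ids, sample(10:50, 1))
    p <- pair_ends(make_ends(k1, pos = seq_along(k1)),
                   make_ends(k2, pos = seq_along(k2) + 500))
    expect_equal(2L * nrow(p$pets) + p$n_orphans, length(k1) + length(k2))
  }
})

test_that("canonical ordering puts the smaller (chrom, pos) end first", {
  pets <- data.table::data.table(
    read_id = c("a", "b"), chrom1 = c("chr2", "chr1"), pos1 = c(100, 900),
    strand1 = "+", mapq1 = 42L, chrom2 = c("chr1", "chr1"),
    pos2 = c(50, 100), strand2 = "-", mapq2 = 40L,
    category = "unclassified")
  cc <- canonicalize_pets(pets)
  expect_equal(cc$chrom1, c("chr1", "chr1"))
  expect_equal(cc$pos1, c(50, 100))
  expect_equal(cc$strand1, c("-", "-"))
})

test_that("dedup_pets keeps one PET per positional key", {
  base <- data.table::data.table(
    read_id = paste0("r", 1:5), chrom1 = "chr1", pos1 = 100, strand1 = "+",
    mapq1 = 42L, chrom2 = "chr1", pos2 = 900, strand2 = "-", mapq2 = 42L,
    category = "unclassified")
  expect_equal(nrow(dedup_pets(base)), 1L)
  # strand is part of the key
  two <- data.table::copy(base[1:2])
  two[2, strand1 := "-"]
  expect_equal(nrow(dedup_pets(two)), 2L)
  expect_equal(nrow(dedup_pets(two, use_strand = FALSE)), 1L)
  # idempotence
  expect_equal(dedup_pets(dedup_pets(two)), dedup_pets(two))
})

test_that("dedup on simulated duplicates matches brute-force distinct keys", {
  sim <- default_sim()                      # dup_rate 0.1
  dd <- dedup_pets(sim$pets)
  key <- paste(sim$pets$chrom1, sim$pets$pos1, sim$pets$strand1,
               sim$pets$chrom2, sim$pets$pos2, sim$pets$strand2)
  expect_equal(nrow(dd), length(unique(key)))
  expect_lt(nrow(dd), nrow(sim$pets))
})

test_that("process_reads runs SAM to deduplicated PETs with stats", {
  cfg <- sim_config(seed = 55, n_pets = 500, mu1 = 0.5, lambda_far = 1e-4,
                    lambda_inter = 0.2)
  sim <- simulate_pets(cfg)
  sam <- simulate_sam(sim)
  pr <- process_reads(sam$sam1, sam$sam2)
  expect_equal(pr$stats$n_records1, nrow(sim$pets))
  expect_equal(pr$stats$n_unmapped2, pr$stats$rescue$n_unmapped)
  # every chimeric mate-2 is rescuable by construction
  expect_equal(pr$stats$rescue$n_rescuable, pr$stats$rescue$n_unmapped)
  # MAPQ>30 keeps only 42s; paired count = both ends 42 and mate2 mapped
  both42 <- sim$pets[mapq1 > 30 & mapq2 > 30]
  chim <- sam$chimeras$read_id
  expect_equal(pr$stats$n_paired, nrow(both42[!read_id %in% chim]))
  # dedup removed something (duplicates injected at 10%)
  expect_lte(nrow(pr$pets), pr$stats$n_paired)
  unlink(dirname(sam$sam1), recursive = TRUE)
})
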