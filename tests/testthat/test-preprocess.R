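# preprocess: trimming, merging, error estimation, and the full step.

test_that("trim_read follows the window rule on the canonical cases", {
  # uniform Q30: kept untouched
  t1 <- trim_read(strrep("A", 150), rep(30L, 150))
  expect_true(t1$kept)
  expect_equal(c(t1$start, t1$end), c(0L, 150L))
  # uniform Q10: no window passes
  expect_false(trim_read(strrep("A", 150), rep(10L, 150))$kept)
  # 120 bp of Q30 then 30 bp of Q2: trailing cut at 120 (w = 15)
  t3 <- trim_read(strrep("A", 150), c(rep(30L, 120), rep(2L, 30)))
  expect_true(t3$kept)
  expect_equal(c(t3$start, t3$end), c(0L, 120L))
  # trimmed length below min_length drops the read
  expect_false(trim_read(strrep("A", 150),
                         c(rep(30L, 90), rep(2L, 60)))$kept)
})

test_that("trim_read never lengthens and respects min_length (property)", {
  set.seed(21)
  for (i in 1:60) {
    len <- sample(100:300, 1)
    qual <- sample(2:41, len, replace = TRUE)
    tr <- trim_read(strrep("A", len), qual, min_length = 100L)
    if (tr$kept) {
      expect_gte(tr$start, 0L)
      expect_lte(tr$end, len)
      expect_gte(tr$end - tr$start, 100L)
    }
  }
})

test_that("merge_pair merges exact overlaps, resolves conflicts by quality, and N-joins", {
  set.seed(31)
  core <- random_seq(20)
  s1 <- paste0(random_seq(80), core)
  s2 <- revcomp(paste0(core, random_seq(80)))
  m <- merge_pair(s1, rep(30L, 100), s2, rep(30L, 100))
  expect_equal(m$mode, "overlap_merged")
  expect_equal(nchar(m$sequence), 180L)
  expect_equal(length(m$qual), 180L)

  # unrelated reads fall back to a single internal N run
  u <- merge_pair(random_seq(100), rep(30L, 100),
                  random_seq(100), rep(30L, 100))
  expect_equal(u$mode, "artificially_joined")
  expect_equal(nchar(u$sequence), 210L)
  expect_equal(lengths(regmatches(u$sequence, gregexpr("N+", u$sequence))), 1L)
  expect_equal(nchar(regmatches(u$sequence, regexpr("N+", u$sequence))), 10L)

  # one conflicting base: higher PHRED wins
  core1 <- paste0(substr(core, 1, 9), "A", substr(core, 11, 20))
  core2 <- paste0(substr(core, 1, 9), "C", substr(core, 11, 20))
  sa <- paste0(random_seq(50), core1)
  sb <- revcomp(paste0(core2, random_seq(50)))
  hi_r1 <- merge_pair(sa, rep(40L, 70), sb, rep(10L, 70))
  expect_equal(substr(hi_r1$sequence, 60, 60), "A")
  hi_r2 <- merge_pair(sa, rep(10L, 70), sb, rep(40L, 70))
  expect_equal(substr(hi_r2$sequence, 60, 60), "C")
  # merged length can never exceed len1 + len2 - min_overlap
  expect_lte(nchar(hi_r1$sequence), 70 + 70 - 10)
})

test_that("estimate_locus_error applies the PHRED-mean formula with clamping", {
  expect_equal(estimate_locus_error(list(L = list(rep(20L, 50))))[["L"]], 0.01)
  # per-read means 10 and 30 average to 20
  expect_equal(estimate_locus_error(
    list(L = list(rep(10L, 30), rep(30L, 70))))[["L"]], 0.01)
  expect_equal(estimate_locus_error(list(L = list(rep(60L, 10))))[["L"]], 1e-6)
  # monotone: higher mean quality, lower error
  e <- estimate_locus_error(list(a = list(rep(15L, 10)), b = list(rep(25L, 10))))
  expect_gt(e[["a"]], e[["b"]])
  expect_warning(estimate_locus_error(list(L = list(), M = list(rep(20L, 5)))),
                 "no retained reads")
})

test_that("run_preprocess conserves reads and writes the stated outputs", {
  d <- withr_local_tempdir()
  cfg <- sim_config(taxa = data.frame(taxon = c("Ta", "Tb", "Tc"),
                                      ploidy = c(2L, 2L, 2L),
                                      known = c(TRUE, TRUE, TRUE)),
                    loci = c(Lx = 550L), depth = 20L, seed = 5L)
  sim <- simulate_dataset(cfg, file.path(d, "sim"))
  out <- run_preprocess(sim$r1, sim$r2, file.path(d, "pre"))
  cnt <- out$counts
  expect_equal(cnt[["input"]],
               cnt[["discarded"]] + cnt[["merged"]] + cnt[["n_joined"]] +
                 cnt[["single_survivor"]])
  expect_equal(nrow(out$records),
               cnt[["merged"]] + cnt[["n_joined"]] + cnt[["single_survivor"]])
  # guaranteed-overlap simulation: everything merges
  expect_equal(cnt[["merged"]], cnt[["input"]])
  # taxon table lists every taxon with unknown ploidy by default
  tt <- read_taxon_table(file.path(d, "pre", "taxon_table.txt"))
  expect_setequal(names(tt), c("Ta", "Tb", "Tc"))
  expect_true(all(is.na(tt)))
  le <- read_locus_error_table(file.path(d, "pre", "locus_err.txt"))
  expect_named(le, "Lx")
  # FASTA re-parses to the same records
  back <- read_locus_fasta(file.path(d, "pre", "Lx.fasta"))
  expect_equal(nrow(back), nrow(out$records))
})

test_that("run_preprocess on empty input yields empty outputs and zero counts", {
  d <- withr_local_tempdir()
  e1 <- file.path(d, "e1.fastq"); e2 <- file.path(d, "e2.fastq")
  writeLines(character(0), e1); writeLines(character(0), e2)
  out <- run_preprocess(e1, e2, file.path(d, "pre"))
  expect_equal(unname(out$counts[["input"]]), 0L)
  expect_equal(nrow(out$records), 0L)
  expect_length(out$locus_err, 0L)
})
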