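# haplotypes: gap-identical merging, partitions, likelihoods, calls.

test_that("merge_gap_identical combines gapped twins and respects conflicts", {
  cs <- cluster_set("T", "L", c("ACGTAATTGA", "ACGT----GA"), c(7L, 5L))
  out <- merge_gap_identical(cs)
  expect_equal(out$m, 1L)
  expect_equal(out$clusters$sequence, "ACGTAATTGA")
  expect_equal(out$clusters$size, 12L)

  cs2 <- cluster_set("T", "L", c("ACGTAATTGA", "ACGTCC--GA"), c(7L, 5L))
  expect_equal(merge_gap_identical(cs2)$m, 2L)

  cs3 <- cluster_set("T", "L", c("ACGT", "ACGTA"), c(2L, 1L))
  expect_error(merge_gap_identical(cs3), "realign")
})

test_that("merge_gap_identical matches the iterative oracle on small sets", {
  set.seed(81)
  for (case in 1:15) {
    k <- sample(2:5, 1)
    len <- 12L
    base <- random_seq(len)
    seqs <- vapply(seq_len(k), function(i) {
      ch <- strsplit(base, "")[[1]]
      ng <- sample(0:4, 1)
      if (ng > 0) ch[sample(len, ng)] <- "-"
      if (runif(1) < 0.3) {
        pos <- sample(len, 1)
        if (ch[pos] != "-") ch[pos] <- sample(c("A", "C", "G", "T"), 1)
      }
      paste(ch, collapse = "")
    }, character(1))
    sizes <- sample(1:10, k, replace = TRUE)
    got <- merge_gap_identical(cluster_set("T", "L", seqs, sizes))$clusters
    want <- oracle_merge_gap_identical(seqs, sizes)
    expect_equal(got$sequence, want$sequence, info = paste("case", case))
    expect_equal(got$size, as.integer(want$size), info = paste("case", case))
  }
})

test_that("integer_partitions enumerates the tetraploid configurations", {
  expect_equal(integer_partitions(4),
               list(4L, c(3L, 1L), c(2L, 2L), c(2L, 1L, 1L),
                    c(1L, 1L, 1L, 1L)))
  expect_equal(integer_partitions(1), list(1L))
  expect_error(integer_partitions(0), "positive")
})

test_that("config_loglik evaluates the multinomial kernel", {
  expect_equal(config_loglik(100, c(2L), 0.01), 0)            # p = 1
  expect_equal(config_loglik(c(50, 50), c(1L, 1L), 0.01), 100 * log(0.5))
  expect_equal(config_loglik(c(50, 50), c(2L), 0.01),
               50 * log(0.99) + 50 * log(0.01))
  # j = m renormalizes away the error mass entirely
  expect_equal(config_loglik(c(10, 5), c(3L, 1L), 0.05),
               10 * log(0.75) + 5 * log(0.25))
})

test_that("infer_known_ploidy picks the ML partition on canonical cases", {
  even <- infer_known_ploidy(cluster_set("T", "L", c("AAAA", "CCCC"),
                                         c(50L, 50L)), 2L, 0.01)
  expect_equal(even$partition, c(1L, 1L))
  expect_equal(even$haplotypes$copies, c(1L, 1L))

  skew <- infer_known_ploidy(cluster_set("T", "L", c("AAAA", "CCCC"),
                                         c(97L, 3L)), 2L, 0.01)
  expect_equal(skew$partition, 2L)
  expect_equal(nrow(skew$haplotypes), 1L)
  expect_equal(skew$haplotypes$copies, 2L)

  # copies always sum to K; distinct haplotypes bounded by min(K, m)
  set.seed(91)
  for (i in 1:20) {
    m <- sample(1:8, 1)
    K <- sample(1:8, 1)
    sizes <- sort(sample(1:200, m, replace = TRUE), decreasing = TRUE)
    cs <- cluster_set("T", "L", vapply(seq_len(m), function(j)
      random_seq(10), character(1)), sizes)
    call <- infer_known_ploidy(cs, K, 0.01)
    expect_equal(sum(call$haplotypes$copies), K)
    expect_lte(nrow(call$haplotypes), min(K, m))
  }
})

test_that("infer_known_ploidy equals the exhaustive oracle on random instances", {
  set.seed(92)
  for (i in 1:100) {
    m <- sample(1:8, 1)
    K <- sample(1:8, 1)
    sizes <- sort(sample(1:500, m, replace = TRUE), decreasing = TRUE)
    eps <- sample(c(0.001, 0.01, 0.05), 1)
    cs <- cluster_set("T", "L", vapply(seq_len(m), function(j)
      paste0(random_seq(6), j), character(1)), sizes)
    got <- infer_known_ploidy(cs, K, eps)$partition
    want <- oracle_best_config(cs$clusters$size, K, eps)
    expect_equal(got, want, info = sprintf("i=%d K=%d m=%d", i, K, m))
  }
})

test_that("scan_unknown_ploidy reproduces the hand-derived cases", {
  cs1 <- cluster_set("T", "L", c("A", "C", "G"), c(100L, 100L, 1L))
  s1 <- scan_unknown_ploidy(cs1, 0.01, 0.10)
  expect_equal(s1$h_star, 2L)
  expect_equal(unname(s1$logliks["1"]), -536.13, tolerance = 1e-4)
  expect_equal(unname(s1$logliks["2"]), -145.25, tolerance = 1e-4)
  expect_equal(unname(s1$logliks["3"]), -220.82, tolerance = 1e-4)

  cs2 <- cluster_set("T", "L", c("A", "C", "G", "T"), c(10L, 9L, 8L, 1L))
  expect_equal(scan_unknown_ploidy(cs2, 0.01, 0.10)$h_star, 3L)

  # a single cluster is always one haplotype
  expect_equal(scan_unknown_ploidy(cluster_set("T", "L", "A", 42L),
                                   0.01)$h_star, 1L)
})

test_that("scan_unknown_ploidy is bounded by m and monotone in the cutoff", {
  set.seed(93)
  for (i in 1:20) {
    m <- sample(1:10, 1)
    sizes <- sort(sample(1:300, m, replace = TRUE), decreasing = TRUE)
    cs <- cluster_set("T", "L", vapply(seq_len(m), function(j)
      paste0(random_seq(6), j), character(1)), sizes)
    hs <- vapply(c(0.001, 0.01, 0.1, 0.5, 2), function(cut)
      scan_unknown_ploidy(cs, 0.01, cut)$h_star, integer(1))
    expect_true(all(hs <= m) && all(hs >= 1L))
    expect_true(all(diff(hs) <= 0L))  # larger cutoff, never more haplotypes
  }
})

test_that("call_haploid returns the dominant cluster with deterministic ties", {
  cs <- cluster_set("T", "L", c("GGGG", "AAAA", "CCCC"), c(2L, 30L, 1L))
  expect_equal(call_haploid(cs)$haplotypes$sequence, "AAAA")
  tie <- cluster_set("T", "L", c("TTTT", "AAAA"), c(10L, 10L))
  expect_equal(call_haploid(tie)$haplotypes$sequence, "AAAA")
})

test_that("crunch dispatches per-taxon modes and enforces table coverage", {
  d <- withr_local_tempdir()
  s1 <- random_seq(60)
  s2 <- mutate_at_rate(s1, 0.2)
  cl <- data.frame(taxon = rep(c("Dip", "Unk"), each = 2),
                   locus = "Lx", cluster_index = rep(0:1, 2),
                   size = c(48L, 47L, 60L, 3L),
                   sequence = rep(c(s1, s2), 2), stringsAsFactors = FALSE)
  p <- file.path(d, "Lx_clusters.fasta")
  write_cluster_fasta(cl, p)
  tt <- c(Dip = 2L, Unk = NA_integer_)
  le <- c(Lx = 0.005)
  res <- crunch(p, tt, le, file.path(d, "out"))
  expect_equal(res$calls[["Dip|Lx"]]$mode, "known_ploidy")
  expect_equal(res$calls[["Dip|Lx"]]$partition, c(1L, 1L))
  expect_equal(res$calls[["Unk|Lx"]]$mode, "unknown_ploidy")
  expect_equal(res$calls[["Unk|Lx"]]$h_star, 1L)
  lines <- readLines(res$fasta_paths[["Lx"]])
  expect_true(any(grepl("^>Dip\\|Lx\\|hap1_copy1$", lines)))
  expect_true(file.exists(res$report))

  # --haploid overrides every mode: exactly one sequence per taxon x locus
  hap <- crunch(p, tt, le, file.path(d, "hap"), haploid = TRUE)
  expect_true(all(vapply(hap$calls, function(x)
    nrow(x$haplotypes) == 1L, logical(1))))

  expect_error(crunch(p, c(Dip = 2L), le, file.path(d, "e")), "Unk")
  expect_error(crunch(p, tt, c(Other = 0.01), file.path(d, "e")), "Lx")
})
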