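# recluster: identity metric, greedy clustering, chimera filter, rounds.

test_that("pairwise_identity matches the stated examples and is symmetric", {
  s <- random_seq(50)
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 0.875)
  expect_equal(pairwise_identity("NNNNACGT", "TTTTACGT"), 1.0)
  set.seed(41)
  for (i in 1:20) {
    a <- random_seq(sample(20:60, 1))
    b <- mutate_at_rate(a, 0.1)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("pairwise_identity agrees with the pure-R DP oracle", {
  set.seed(42)
  for (i in 1:40) {
    a <- random_seq(sample(15:60, 1))
    b <- if (i %% 3 == 0) random_seq(sample(15:60, 1)) else {
      x <- mutate_at_rate(a, 0.08)
      # occasional indel
      if (i %% 2 == 0) x <- paste0(substr(x, 1, 10), substr(x, 12, nchar(x)))
      x
    }
    expect_equal(pairwise_identity(a, b), oracle_nw_identity(a, b),
                 tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("pairwise_identity agrees with Biostrings on clean substitution cases", {
  skip_if_not_installed("Biostrings")
  set.seed(43)
  for (i in 1:10) {
    a <- random_seq(80)
    b <- mutate_at_rate(a, 0.05)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 2)
    expect_equal(pairwise_identity(a, b), Biostrings::pid(pa, "PID1") / 100,
                 tolerance = 1e-9)
  }
})

test_that("greedy_cluster collapses replicates and separates divergent sequences", {
  s <- random_seq(60)
  recs <- data.frame(sequence = rep(s, 30), size = 1L)
  out <- greedy_cluster(recs, 0.99)
  expect_equal(nrow(out), 1L)
  expect_equal(out$size, 30L)

  set.seed(51)
  a <- random_seq(300)
  b <- mutate_at_rate(a, 0.2)   # ~80% identity
  two <- greedy_cluster(data.frame(sequence = c(a, b), size = c(5L, 3L)), 0.99)
  expect_equal(nrow(two), 2L)
  expect_equal(sum(two$size), 8L)
})

test_that("greedy_cluster matches the exhaustive oracle on small random sets", {
  set.seed(52)
  for (case in 1:12) {
    base <- random_seq(sample(40:80, 1))
    k <- sample(3:6, 1)
    seqs <- vapply(seq_len(k), function(i)
      mutate_at_rate(base, sample(c(0.005, 0.02, 0.3), 1)), character(1))
    sizes <- sample(1:20, k, replace = TRUE)
    thr <- sample(c(0.9, 0.97, 0.99), 1)
    got <- greedy_cluster(data.frame(sequence = seqs, size = sizes), thr)
    want <- oracle_greedy_cluster(seqs, sizes, thr)
    expect_equal(got$sequence, want$sequence, info = paste("case", case))
    expect_equal(got$size, want$size, info = paste("case", case))
  }
})

test_that("chimera_filter flags constructed chimeras and keeps parents", {
  set.seed(61)
  p1 <- random_seq(400)
  p2 <- mutate_at_rate(p1, 0.1)     # ~90% mutual identity
  chi <- paste0(substr(p1, 1, 200), substr(p2, 201, 400))
  cen <- data.frame(sequence = c(p1, p2, chi), size = c(100L, 100L, 10L))
  res <- chimera_filter(cen, abundance_skew = 2, chimera_identity = 0.99)
  expect_equal(res$flagged$sequence, chi)
  expect_setequal(res$kept$sequence, c(p1, p2))

  # with no pair of larger parents nothing is flagged
  solo <- data.frame(sequence = c(p1, p2), size = c(100L, 100L))
  expect_equal(nrow(chimera_filter(solo)$flagged), 0L)
})

test_that("recluster_iterative conserves sizes up to flagged chimeras", {
  set.seed(62)
  a <- random_seq(300)
  reads <- c(vapply(1:40, function(i) mutate_at_rate(a, 0.003), character(1)),
             vapply(1:40, function(i)
               mutate_at_rate(mutate_at_rate(a, 0.02), 0.003), character(1)))
  res <- recluster_iterative(data.frame(sequence = reads, size = 1L))
  expect_equal(sum(res$centroids$size) + sum(res$chimeras$size), 80L)
  # single sequence passes through unchanged
  one <- recluster_iterative(data.frame(sequence = a, size = 1L))
  expect_equal(one$centroids$sequence, a)
  expect_equal(one$centroids$size, 1L)
})

test_that("recluster separates 2%-divergent haplotypes and drops planted chimeras", {
  set.seed(63)
  hits <- 0L
  for (rep in 1:10) {
    anc <- random_seq(550)
    h1 <- mutate_at_rate(anc, 0.01)
    h2 <- mutate_at_rate(h1, 0.02)
    reads <- vapply(1:100, function(i)
      mutate_at_rate(if (i <= 50) h1 else h2, 0.005), character(1))
    res <- recluster_iterative(data.frame(sequence = reads, size = 1L))
    big <- res$centroids[res$centroids$size >= 10, ]
    if (nrow(big) == 2L && sum(res$centroids$size) == 100L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # planted chimera at ~5% abundance is absent from the output
  set.seed(64)
  anc <- random_seq(500)
  h1 <- mutate_at_rate(anc, 0.03)
  h2 <- mutate_at_rate(anc, 0.03)
  chi <- paste0(substr(h1, 1, 250), substr(h2, 251, 500))
  reads <- c(vapply(1:48, function(i) mutate_at_rate(h1, 0.003), character(1)),
             vapply(1:48, function(i) mutate_at_rate(h2, 0.003), character(1)),
             vapply(1:5, function(i) mutate_at_rate(chi, 0.003), character(1)))
  res <- recluster_iterative(data.frame(sequence = reads, size = 1L))
  ids_to_chi <- vapply(res$centroids$sequence, pairwise_identity, numeric(1),
                       b = chi)
  keep_big <- res$centroids$size >= 4
  expect_false(any(ids_to_chi[keep_big] > 0.995 &
                     res$centroids$size[keep_big] >= 4 &
                     vapply(res$centroids$sequence[keep_big], function(s)
                       pairwise_identity(s, h1) < 0.99 &&
                       pairwise_identity(s, h2) < 0.99, logical(1))))
  expect_gt(nrow(res$chimeras), 0L)
})

test_that("raising the threshold never decreases the number of centroids", {
  set.seed(65)
  base <- random_seq(200)
  seqs <- vapply(1:15, function(i)
    mutate_at_rate(base, sample(c(0.002, 0.01, 0.05), 1)), character(1))
  recs <- data.frame(sequence = seqs, size = sample(1:5, 15, TRUE))
  ns <- vapply(c(0.90, 0.95, 0.99, 0.995, 1.0), function(t)
    nrow(greedy_cluster(recs, t)), integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("run_recluster keeps taxa separate and writes parseable output", {
  d <- withr_local_tempdir()
  set.seed(66)
  s1 <- random_seq(120); s2 <- mutate_at_rate(s1, 0.001)
  recs <- data.frame(taxon = rep(c("Ta", "Tb"), each = 10),
                     locus = "Lx", uid = rep(1:10, 2),
                     sequence = rep(c(s1, s2), each = 10),
                     stringsAsFactors = FALSE)
  write_purc_fasta(recs, d)
  out <- run_recluster(file.path(d, "Lx.fasta"), file.path(d, "cl"))
  cl <- read_cluster_fasta(file.path(d, "cl", "Lx_clusters.fasta"))
  # near-identical sequences from different taxa must not merge
  expect_setequal(cl$taxon, c("Ta", "Tb"))
  expect_equal(cl$size, c(10L, 10L))
})
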