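# Independent oracles: deliberately simple, pure-R reimplementations used
# only to verify the package's fast paths.  They never call the package's
# alignment or likelihood code.

# Full-matrix Needleman-Wunsch identity (match 1, mismatch -1, gap -2),
# terminal gap columns excluded, N wildcard.  Traceback prefers diagonal,
# then up (gap in b), then left, mirroring the documented tie-break.
oracle_nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -2 * (0:m)
  S[, 1] <- -2 * (0:n)
  mscore <- function(x, y) if (x == y || x == "N" || y == "N") 1 else -1
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + mscore(A[i], B[j]),
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  }
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + mscore(A[i], B[j])) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1
    }
  }
  both <- which(ra != "-" & rb != "-")
  if (!length(both)) return(0)
  rng <- min(both):max(both)
  keep_a <- ra[rng]; keep_b <- rb[rng]
  matches <- sum(keep_a != "-" & keep_b != "-" &
                   (keep_a == keep_b | keep_a == "N" | keep_b == "N"))
  matches / length(rng)
}

# Greedy best-hit clustering, written as a direct transcription of the rule.
oracle_greedy_cluster <- function(seqs, sizes, threshold) {
  ord <- order(-sizes, seqs)
  seqs <- seqs[ord]; sizes <- sizes[ord]
  cen <- integer(0)              # indices of founders
  cen_size <- integer(0)
  for (i in seq_along(seqs)) {
    best <- 0L; best_id <- -1
    for (c in seq_along(cen)) {
      id <- oracle_nw_identity(seqs[i], seqs[cen[c]])
      if (id > best_id) { best_id <- id; best <- c }
    }
    if (best > 0L && best_id >= threshold) {
      cen_size[best] <- cen_size[best] + sizes[i]
    } else {
      cen <- c(cen, i)
      cen_size <- c(cen_size, sizes[i])
    }
  }
  out <- data.frame(sequence = seqs[cen], size = cen_size)
  out[order(-out$size, out$sequence), , drop = FALSE]
}

# All partitions of K by composition enumeration + dedup (brute force).
oracle_partitions <- function(K) {
  comps <- function(k) {
    if (k == 0L) return(list(integer(0)))
    out <- list()
    for (first in 1:k) for (rest in comps(k - first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  parts <- unique(lapply(comps(K), function(x) sort(x, decreasing = TRUE)))
  keys <- vapply(parts, paste, character(1), collapse = ",")
  parts[order(keys)]
}

# Exhaustive known-ploidy maximisation with its own likelihood evaluation.
oracle_best_config <- function(sizes, K, eps) {
  m <- length(sizes)
  parts <- Filter(function(p) length(p) <= min(K, m), oracle_partitions(K))
  ll <- vapply(parts, function(p) {
    j <- length(p)
    pr <- numeric(m)
    if (j == m) pr <- p / K
    else {
      pr[1:j] <- (1 - eps) * p / K
      pr[(j + 1):m] <- eps / (m - j)
    }
    if (any(pr == 0 & sizes > 0)) return(-Inf)
    sum(sizes * log(pr))
  }, numeric(1))
  nparts <- vapply(parts, length, integer(1))
  k1 <- vapply(parts, `[[`, integer(1), 1L)
  parts[[order(-ll, nparts, -k1)[1L]]]
}

# Iterative gap-identical merging transcribed directly from the rule.
oracle_merge_gap_identical <- function(seqs, sizes) {
  compat <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    both <- ca != "-" & ca != "N" & cb != "-" & cb != "N"
    all(ca[both] == cb[both])
  }
  gapn <- function(s) nchar(s) - nchar(gsub("[-N]", "", s))
  repeat {
    ord <- order(-sizes, seqs)
    seqs <- seqs[ord]; sizes <- sizes[ord]
    n <- length(seqs); hit <- FALSE
    for (i in seq_len(max(0, n - 1))) {
      for (j in (i + 1):n) {
        if (compat(seqs[i], seqs[j])) {
          surv <- if (gapn(seqs[i]) < gapn(seqs[j])) i
            else if (gapn(seqs[j]) < gapn(seqs[i])) j
            else if (sizes[i] > sizes[j]) i else if (sizes[j] > sizes[i]) j
            else if (seqs[i] <= seqs[j]) i else j
          new_seq <- seqs[surv]; new_size <- sizes[i] + sizes[j]
          seqs <- seqs[-c(i, j)]; sizes <- sizes[-c(i, j)]
          seqs <- c(seqs, new_seq); sizes <- c(sizes, new_size)
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) break
  }
  ord <- order(-sizes, seqs)
  data.frame(sequence = seqs[ord], size = sizes[ord])
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

mutate_at_rate <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
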