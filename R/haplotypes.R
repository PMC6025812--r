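# Haplotype calling from abundance-sorted clusters: gap-identical cluster
# merging, integer-partition enumeration, the multinomial likelihood for
# known ploidy, the real-vs-error likelihood scan for unknown ploidy, and
# the haploid/consensus mode.

#' Construct a cluster set for one taxon x locus
#'
#' @param taxon,locus labels.
#' @param sequence character vector of cluster sequences (possibly gapped).
#' @param size positive integer read counts per cluster.
#' @return object of class \code{cluster_set}: clusters sorted by size
#'   descending (ties lexicographic), with \code{m} clusters and \code{N}
#'   total reads.
#' @export
cluster_set <- function(taxon, locus, sequence, size) {
  stopifnot(length(sequence) == length(size), all(size >= 1))
  ord <- order(-size, sequence)
  structure(list(taxon = taxon, locus = locus,
                 clusters = data.frame(sequence = sequence[ord],
                                       size = as.integer(size[ord]),
                                       stringsAsFactors = FALSE),
                 m = length(size), N = sum(as.integer(size))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %s | %s: m = %d clusters, N = %d reads\n",
              x$taxon, x$locus, x$m, x$N))
  print(head(data.frame(size = x$clusters$size,
                        length = nchar(x$clusters$sequence)), 10L))
  invisible(x)
}

gapn_count <- function(s) {
  nchar(s) - nchar(gsub("[-N]", "", s))
}

#' Merge clusters that are identical ignoring gaps
#'
#' Artificially N-joined read pairs often form a second, heavily gapped
#' cluster for a haplotype that also has a fully merged cluster.  Two
#' aligned clusters merge iff at every column where both carry an
#' informative character (non-gap, non-N) the characters agree.  The
#' survivor is the sequence with fewer gap+N characters (ties: larger
#' size, then lexicographically smaller sequence) and takes the summed
#' size.  Merging iterates in size order until no pair merges.
#'
#' @param cs a [cluster_set()] whose sequences are mutually aligned (equal
#'   length); unequal lengths are a hard error (realign first).
#' @return a merged, re-sorted \code{cluster_set}.
#' @export
merge_gap_identical <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- cs$clusters
  if (length(unique(nchar(cl$sequence))) != 1L) {
    stop("merge_gap_identical: clusters have unequal lengths; realign first ",
         "(e.g. crunch(..., realign = TRUE))")
  }
  compatible <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    both <- ca != "-" & ca != "N" & cb != "-" & cb != "N"
    all(ca[both] == cb[both])
  }
  repeat {
    ord <- order(-cl$size, cl$sequence)
    cl <- cl[ord, , drop = FALSE]
    n <- nrow(cl)
    merged <- FALSE
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in (i + 1L):n) {
        if (compatible(cl$sequence[i], cl$sequence[j])) {
          gi <- gapn_count(cl$sequence[i]); gj <- gapn_count(cl$sequence[j])
          surv <- if (gi < gj) i else if (gj < gi) j else
            if (cl$size[i] > cl$size[j]) i else if (cl$size[j] > cl$size[i]) j else
              if (cl$sequence[i] <= cl$sequence[j]) i else j
          keep_seq <- cl$sequence[surv]
          new_size <- cl$size[i] + cl$size[j]
          cl <- cl[-c(i, j), , drop = FALSE]
          cl <- rbind(cl, data.frame(sequence = keep_seq, size = new_size,
                                     stringsAsFactors = FALSE))
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  cluster_set(cs$taxon, cs$locus, cl$sequence, cl$size)
}

#' Enumerate integer partitions of K
#'
#' All partitions of \code{K} as non-increasing positive integer vectors,
#' in decreasing lexicographic order; e.g. K = 4 yields (4), (3,1), (2,2),
#' (2,1,1), (1,1,1,1) — the dosage configurations a tetraploid can take.
#'
#' @param K positive integer (the ploidy).
#' @return list of integer vectors.
#' @export
integer_partitions <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  gen <- function(k, maxpart) {
    if (k == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq(min(k, maxpart), 1L)) {
      for (rest in gen(k - first, first)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  gen(K, K)
}

clamp_eps <- function(eps) {
  if (eps <= 0 || eps >= 1) {
    warning("error rate ", eps, " outside (0,1); clamped")
  }
  min(0.5, max(1e-6, eps))
}

#' Multinomial log-likelihood of a dosage configuration
#'
#' For a partition \eqn{(k_1 \ge \dots \ge k_j)} of ploidy K and
#' size-sorted cluster counts \eqn{n_1 \ge \dots \ge n_m}, the first j
#' clusters are real haplotypes with expected read proportions
#' \eqn{p_i = (1-\epsilon) k_i / K}, and the remaining \eqn{m - j}
#' clusters share the error mass \eqn{\epsilon} uniformly.  When j = m
#' there is no error cluster and \eqn{p_i = k_i / K}.  The returned value
#' is the multinomial kernel \eqn{\sum_i n_i \log p_i} (the combinatorial
#' constant is omitted; it does not affect ranking).
#'
#' @param sizes integer cluster sizes, sorted non-increasing.
#' @param partition non-increasing positive integers summing to K, with at
#'   most \code{length(sizes)} parts.
#' @param eps per-read error probability in (0, 1).
#' @return log-likelihood (\code{-Inf} if any cluster gets probability 0).
#' @export
config_loglik <- function(sizes, partition, eps) {
  m <- length(sizes)
  j <- length(partition)
  K <- sum(partition)
  stopifnot(j >= 1L, j <= m)
  eps <- clamp_eps(eps)
  p <- numeric(m)
  if (j == m) {
    p <- partition / K
  } else {
    p[seq_len(j)] <- (1 - eps) * partition / K
    p[(j + 1L):m] <- eps / (m - j)
  }
  if (any(p == 0 & sizes > 0)) return(-Inf)
  sum(sizes * log(p))
}

#' Maximum-likelihood haplotype call for known ploidy
#'
#' Evaluates [config_loglik()] over every partition of \code{K} with at
#' most \code{min(K, m)} parts and returns the argmax; ties prefer fewer
#' distinct haplotypes, then a larger leading dosage.  The call returns
#' each haplotype with its copy number, so copies always sum to K.
#'
#' @param cs a [cluster_set()].
#' @param K ploidy (positive integer).
#' @param eps per-read error probability.
#' @param unique_only collapse copy numbers to 1 per distinct haplotype.
#' @return object of class \code{haplotype_call} with fields taxon, locus,
#'   mode, haplotypes (data.frame sequence/copies), partition, loglik.
#' @export
infer_known_ploidy <- function(cs, K, eps, unique_only = FALSE) {
  stopifnot(inherits(cs, "cluster_set"), K >= 1L)
  eps <- clamp_eps(eps)
  parts <- Filter(function(p) length(p) <= min(K, cs$m), integer_partitions(K))
  sizes <- cs$clusters$size
  ll <- vapply(parts, function(p) config_loglik(sizes, p, eps), numeric(1))
  nparts <- vapply(parts, length, integer(1))
  k1 <- vapply(parts, `[[`, integer(1), 1L)
  best <- order(-ll, nparts, -k1)[1L]
  p <- parts[[best]]
  haps <- data.frame(sequence = cs$clusters$sequence[seq_along(p)],
                     copies = if (unique_only) rep(1L, length(p)) else p,
                     stringsAsFactors = FALSE)
  structure(list(taxon = cs$taxon, locus = cs$locus, mode = "known_ploidy",
                 haplotypes = haps, partition = p, loglik = ll[best],
                 all_logliks = setNames(ll, vapply(parts, paste, character(1),
                                                   collapse = ","))),
            class = "haplotype_call")
}

#' Real-vs-error likelihood scan for unknown ploidy
#'
#' For each hypothesis h = 0..m that the h largest clusters are real
#' haplotypes, the real clusters share probability \eqn{(1-\epsilon)/h}
#' each and the remaining clusters share \eqn{\epsilon} uniformly (h = 0:
#' all clusters uniform at 1/m; h = m: the error mass is renormalized and
#' each cluster gets 1/m).  Starting at h = 1, h+1 is accepted while the
#' relative log-likelihood increase \eqn{(LL(h+1)-LL(h)) / |LL(h)|}
#' reaches \code{cutoff}; the last accepted h is \code{h_star}.  An
#' individual with any reads always keeps at least one haplotype.
#'
#' @param cs a [cluster_set()].
#' @param eps per-read error probability.
#' @param cutoff relative-increase cutoff (default 0.10).
#' @return object of class \code{haplotype_call} with extra fields
#'   \code{h_star}, \code{logliks} (named vector, h = 0..m) and
#'   \code{cutoff}; haplotypes carry 1 copy each.
#' @export
scan_unknown_ploidy <- function(cs, eps, cutoff = 0.10) {
  stopifnot(inherits(cs, "cluster_set"))
  eps <- clamp_eps(eps)
  m <- cs$m
  sizes <- cs$clusters$size
  ll <- numeric(m + 1L)
  for (h in 0:m) {
    p <- if (h == 0L || h == m) rep(1 / m, m) else
      c(rep((1 - eps) / h, h), rep(eps / (m - h), m - h))
    ll[h + 1L] <- sum(sizes * log(p))
  }
  h_star <- 1L
  while (h_star < m) {
    inc <- (ll[h_star + 2L] - ll[h_star + 1L]) / abs(ll[h_star + 1L])
    if (is.nan(inc) || inc < cutoff) break
    h_star <- h_star + 1L
  }
  haps <- data.frame(sequence = cs$clusters$sequence[seq_len(h_star)],
                     copies = rep(1L, h_star), stringsAsFactors = FALSE)
  structure(list(taxon = cs$taxon, locus = cs$locus, mode = "unknown_ploidy",
                 haplotypes = haps, h_star = h_star,
                 logliks = setNames(ll, 0:m), cutoff = cutoff),
            class = "haplotype_call")
}

#' Haploid / consensus mode: keep only the largest cluster
#'
#' @param cs a [cluster_set()].
#' @return a \code{haplotype_call} with exactly one haplotype (ties on
#'   size go to the lexicographically smallest sequence).
#' @export
call_haploid <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  haps <- data.frame(sequence = cs$clusters$sequence[1L], copies = 1L,
                     stringsAsFactors = FALSE)
  structure(list(taxon = cs$taxon, locus = cs$locus, mode = "haploid",
                 haplotypes = haps), class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat(sprintf("<haplotype_call> %s | %s [%s]: %d haplotype(s)\n",
              x$taxon, x$locus, x$mode, nrow(x$haplotypes)))
  invisible(x)
}

#' Call haplotypes for every taxon x locus from clustered FASTA files
#'
#' Dispatches per taxon x locus on the taxon table: an integer ploidy runs
#' [infer_known_ploidy()], the unknown marker runs [scan_unknown_ploidy()],
#' and \code{haploid = TRUE} overrides both.  Optional realignment
#' ([center_star_align()]), column cleaning ([clean_columns()]) and
#' gap-identical merging are applied before inference.  Output is one
#' FASTA per locus with headers \code{>taxon|locus|hapN_copyM} (gaps
#' stripped) plus a TSV call report.
#'
#' @param cluster_files character vector of cluster FASTA paths (from
#'   [run_recluster()]).
#' @param taxon_table named integer vector (NA = unknown), as from
#'   [read_taxon_table()].
#' @param locus_err named numeric vector, as from
#'   [read_locus_error_table()].
#' @param out_dir output directory.
#' @param haploid,unique_only,cutoff mode options.
#' @param realign realign clusters internally before merging/inference.
#' @param clean column-occupancy threshold applied after realignment, or
#'   \code{NULL} to skip cleaning.
#' @param merge_gaps run [merge_gap_identical()] before inference.
#' @return invisibly, list(calls, report, fasta_paths).
#' @export
crunch <- function(cluster_files, taxon_table, locus_err, out_dir,
                   haploid = FALSE, unique_only = FALSE, cutoff = 0.10,
                   realign = FALSE, clean = NULL, merge_gaps = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  all_cl <- do.call(rbind, lapply(cluster_files, read_cluster_fasta))
  missing_tax <- setdiff(unique(all_cl$taxon), names(taxon_table))
  if (length(missing_tax)) {
    stop("taxa missing from the taxon table: ",
         paste(missing_tax, collapse = ", "))
  }
  missing_loc <- setdiff(unique(all_cl$locus), names(locus_err))
  if (length(missing_loc)) {
    stop("loci missing from the locus-error table: ",
         paste(missing_loc, collapse = ", "))
  }
  calls <- list()
  report <- list()
  fasta_paths <- character(0)
  for (loc in unique(all_cl$locus)) {
    eps <- locus_err[[loc]]
    loc_cl <- all_cl[all_cl$locus == loc, , drop = FALSE]
    fasta_lines <- character(0)
    for (tax in unique(loc_cl$taxon)) {
      sub <- loc_cl[loc_cl$taxon == tax, , drop = FALSE]
      seqs <- sub$sequence
      if (realign && length(seqs) > 1L) {
        aln <- center_star_align(gsub("-", "", seqs, fixed = TRUE))
        if (!is.null(clean)) aln <- clean_columns(aln, clean)
        seqs <- aln$rows
      }
      cs <- cluster_set(tax, loc, seqs, sub$size)
      if (merge_gaps) cs <- merge_gap_identical(cs)
      call <- if (haploid) {
        call_haploid(cs)
      } else if (is.na(taxon_table[[tax]])) {
        scan_unknown_ploidy(cs, eps, cutoff)
      } else {
        infer_known_ploidy(cs, taxon_table[[tax]], eps, unique_only)
      }
      calls[[paste(tax, loc, sep = "|")]] <- call
      haps <- call$haplotypes
      fasta_lines <- c(fasta_lines, as.vector(rbind(
        sprintf(">%s|%s|hap%d_copy%d", tax, loc, seq_len(nrow(haps)),
                haps$copies),
        gsub("-", "", haps$sequence, fixed = TRUE))))
      detail <- switch(call$mode,
        known_ploidy = sprintf("partition=%s;loglik=%.4f",
                               paste(call$partition, collapse = ","),
                               call$loglik),
        unknown_ploidy = sprintf("h_star=%d;loglik=%s", call$h_star,
                                 paste(sprintf("%.4f", call$logliks),
                                       collapse = ",")),
        haploid = "largest_cluster")
      report[[length(report) + 1L]] <- sprintf(
        "%s\t%s\t%s\t%d\t%d\t%g\t%s", tax, loc, call$mode, cs$m, cs$N, eps,
        detail)
    }
    p <- file.path(out_dir, paste0(loc, "_haplotypes.fasta"))
    write_lines_atomic(fasta_lines, p)
    fasta_paths[loc] <- p
  }
  rp <- file.path(out_dir, "crunch_report.tsv")
  write_lines_atomic(c("taxon\tlocus\tmode\tm\tN\teps\tdetail",
                       unlist(report)), rp)
  invisible(list(calls = calls, report = rp, fasta_paths = fasta_paths))
}
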