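# Step 2 stand-in: iterative rounds of two-parent chimera filtering and
# identity-based greedy centroid clustering, per taxon within each locus.

#' Global-alignment identity between two DNA strings
#'
#' Needleman-Wunsch global alignment (match 1, mismatch -1, gap -2) followed
#' by identity = matches / alignment columns, with terminal gap columns
#' excluded and N matching any base.  Symmetric in its arguments.
#'
#' @param a,b non-empty DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  .nw_identity_cpp(a, b)
}

#' Greedy abundance-sorted centroid clustering
#'
#' Records are scanned in decreasing size order (ties broken
#' lexicographically by sequence).  Each record joins the existing centroid
#' of highest identity provided that identity reaches \code{threshold}
#' (best-hit, not first-hit; identity ties go to the earliest-founded
#' centroid), otherwise it founds a new centroid.  Centroid sequences are
#' their founders'; centroid sizes are the sums of absorbed member sizes.
#'
#' @param records data.frame with columns sequence and size (and optionally
#'   members, a list column of uids).
#' @param threshold identity threshold in (0.5, 1].
#' @return data.frame of centroids (sequence, size, members) sorted by size
#'   descending, ties lexicographic by sequence.
#' @export
greedy_cluster <- function(records, threshold) {
  stopifnot(threshold > 0.5, threshold <= 1)
  if (!nrow(records)) {
    return(data.frame(sequence = character(0), size = integer(0)))
  }
  if (is.null(records$members)) {
    records$members <- as.list(seq_len(nrow(records)))
  }
  ord <- order(-records$size, records$sequence)
  records <- records[ord, , drop = FALSE]
  assign <- .greedy_assign_cpp(records$sequence, threshold)
  founders <- unique(assign)
  out <- data.frame(sequence = records$sequence[founders],
                    size = as.integer(vapply(founders, function(f)
                      sum(records$size[assign == f]), numeric(1))),
                    stringsAsFactors = FALSE)
  out$members <- lapply(founders, function(f)
    unlist(records$members[assign == f], use.names = FALSE))
  out[order(-out$size, out$sequence), , drop = FALSE]
}

#' Two-parent chimera filtering of clustered centroids
#'
#' A centroid c is flagged as chimeric iff (a) no single sufficiently large
#' parent (size >= abundance_skew * size(c)) explains it at full-length
#' identity >= chimera_identity, and (b) some ordered pair of such parents
#' and some breakpoint exist with c's prefix at identity >=
#' chimera_identity to the first parent, its suffix likewise to the second,
#' and at least \code{min_diagnostic} diagnostic positions on each side of
#' the breakpoint (positions where c matches that side's parent but not
#' the other).  The diagnostic requirement is the standard two-sided
#' "vote" that stops degenerate breakpoints near the sequence ends from
#' flagging ordinary error-bearing reads.  Flagged centroids are removed;
#' their sizes are not redistributed.
#'
#' @param centroids data.frame (sequence, size) sorted by size descending.
#' @param abundance_skew minimum parent/candidate size ratio (default 2).
#' @param chimera_identity segment identity threshold (default 0.99).
#' @param min_diagnostic minimum diagnostic sites per segment (default 3).
#' @return list(kept, flagged): two centroid data.frames.
#' @export
chimera_filter <- function(centroids, abundance_skew = 2.0,
                           chimera_identity = 0.99, min_diagnostic = 3L) {
  n <- nrow(centroids)
  if (n < 3L) return(list(kept = centroids, flagged = centroids[0, , drop = FALSE]))
  flag <- logical(n)
  for (ci in seq_len(n)) {
    par_idx <- setdiff(which(centroids$size >= abundance_skew * centroids$size[ci]), ci)
    if (length(par_idx) < 2L) next
    cseq <- centroids$sequence[ci]
    L <- nchar(cseq)
    if (L < 2L) next
    profs <- lapply(par_idx, function(p)
      .match_profile_cpp(cseq, centroids$sequence[p]))
    cums <- lapply(profs, cumsum)
    full_id <- vapply(cums, function(cm) cm[L] / L, numeric(1))
    if (any(full_id >= chimera_identity)) next  # one parent explains c
    is_chim <- FALSE
    for (pi in seq_along(par_idx)) {
      for (pj in seq_along(par_idx)) {
        if (pi == pj) next
        cm1 <- cums[[pi]]; cm2 <- cums[[pj]]
        d1 <- cumsum(profs[[pi]] == 1L & profs[[pj]] == 0L)
        d2 <- cumsum(profs[[pj]] == 1L & profs[[pi]] == 0L)
        s <- seq_len(L - 1L)
        pref <- cm1[s] / s
        suff <- (cm2[L] - cm2[s]) / (L - s)
        diag_ok <- d1[s] >= min_diagnostic &
          (d2[L] - d2[s]) >= min_diagnostic
        if (any(pref >= chimera_identity & suff >= chimera_identity &
                  diag_ok)) {
          is_chim <- TRUE
          break
        }
      }
      if (is_chim) break
    }
    flag[ci] <- is_chim
  }
  list(kept = centroids[!flag, , drop = FALSE],
       flagged = centroids[flag, , drop = FALSE])
}

#' Iterative chimera filtering and reclustering
#'
#' Runs the configured rounds: in round r the current centroids are chimera
#' filtered, then greedily clustered at \code{identity_thresholds[r]}, and
#' the resulting centroids feed the next round.  Total absorbed size never
#' increases across rounds (it drops exactly by the flagged chimera sizes).
#'
#' @param records data.frame with columns sequence and size.
#' @param identity_thresholds per-round identity thresholds.
#' @param abundance_skew,chimera_identity see [chimera_filter()].
#' @return list(centroids, chimeras, rounds): final centroids, all flagged
#'   chimeras (with a round column), and a per-round summary data.frame.
#' @export
recluster_iterative <- function(records,
                                identity_thresholds = c(0.997, 0.995, 0.990, 0.997),
                                abundance_skew = 2.0,
                                chimera_identity = 0.99) {
  stopifnot(length(identity_thresholds) >= 1L,
            all(identity_thresholds > 0.5 & identity_thresholds <= 1))
  current <- records
  if (is.null(current$members)) current$members <- as.list(seq_len(nrow(records)))
  chims <- list()
  rounds <- data.frame(round = integer(0), threshold = numeric(0),
                       centroids = integer(0), flagged = integer(0))
  for (r in seq_along(identity_thresholds)) {
    cf <- chimera_filter(current, abundance_skew, chimera_identity)
    if (nrow(cf$flagged)) {
      fl <- cf$flagged
      fl$round <- r
      chims[[length(chims) + 1L]] <- fl[, c("sequence", "size", "round")]
    }
    current <- greedy_cluster(cf$kept, identity_thresholds[r])
    rounds <- rbind(rounds, data.frame(round = r,
                                       threshold = identity_thresholds[r],
                                       centroids = nrow(current),
                                       flagged = nrow(cf$flagged)))
  }
  chimeras <- if (length(chims)) do.call(rbind, chims) else
    data.frame(sequence = character(0), size = integer(0), round = integer(0))
  list(centroids = current, chimeras = chimeras, rounds = rounds)
}

#' Recluster one per-locus FASTA file into abundance-annotated clusters
#'
#' Reads a \code{>taxon|locus|uid} FASTA, clusters each taxon's reads
#' separately (sequences from different taxa never merge), and writes
#' \code{<locus>_clusters.fasta} with \code{;size=} headers plus a chimera
#' report TSV.
#'
#' @param locus_fasta path to a per-locus FASTA from [run_preprocess()].
#' @param out_dir output directory.
#' @inheritParams recluster_iterative
#' @return invisibly, list(clusters, chimeras, paths).
#' @export
run_recluster <- function(locus_fasta, out_dir,
                          identity_thresholds = c(0.997, 0.995, 0.990, 0.997),
                          abundance_skew = 2.0, chimera_identity = 0.99) {
  recs <- read_locus_fasta(locus_fasta)
  if (!nrow(recs)) stop("no records in ", locus_fasta)
  locus <- unique(recs$locus)
  if (length(locus) != 1L) {
    stop("'", locus_fasta, "' mixes loci: ", paste(locus, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  all_clusters <- list()
  all_chims <- list()
  for (tax in unique(recs$taxon)) {
    sub <- recs[recs$taxon == tax, , drop = FALSE]
    records <- data.frame(sequence = sub$sequence,
                          size = rep(1L, nrow(sub)), stringsAsFactors = FALSE)
    records$members <- as.list(sub$uid)
    res <- recluster_iterative(records, identity_thresholds,
                               abundance_skew, chimera_identity)
    cen <- res$centroids
    if (nrow(cen)) {
      all_clusters[[tax]] <- data.frame(
        taxon = tax, locus = locus,
        cluster_index = seq_len(nrow(cen)) - 1L,
        size = cen$size, sequence = cen$sequence, stringsAsFactors = FALSE)
    }
    if (nrow(res$chimeras)) {
      ch <- res$chimeras
      ch$taxon <- tax
      ch$locus <- locus
      all_chims[[tax]] <- ch
    }
  }
  clusters <- do.call(rbind, c(all_clusters, list(make.row.names = FALSE)))
  out_fa <- file.path(out_dir, paste0(locus, "_clusters.fasta"))
  write_cluster_fasta(clusters, out_fa)
  chims <- if (length(all_chims)) do.call(rbind, c(all_chims, list(make.row.names = FALSE)))
    else data.frame(sequence = character(0), size = integer(0),
                    round = integer(0), taxon = character(0), locus = character(0))
  out_ch <- file.path(out_dir, paste0(locus, "_chimeras.tsv"))
  write_lines_atomic(c("taxon\tlocus\tround\tsize\tsequence",
                       if (nrow(chims))
                         sprintf("%s\t%s\t%d\t%d\t%s", chims$taxon, chims$locus,
                                 chims$round, chims$size, chims$sequence)),
                     out_ch)
  invisible(list(clusters = clusters, chimeras = chims,
                 paths = c(clusters = out_fa, chimeras = out_ch)))
}
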