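# Step 1: sliding-window quality trimming, paired-read overlap merging with
# an artificial N-join fallback, per-locus error estimation, and emission of
# per-locus FASTA plus the taxon and locus-error tables.

#' Sliding-window quality trimming of a single read
#'
#' Scans windows of width \code{w = max(1, floor(0.1 * len))}.  The 5' cut
#' is placed at the first window (scanning 5' to 3') whose mean PHRED
#' reaches \code{q_threshold}, refined to the first base in or after that
#' window meeting the threshold; the 3' cut is found symmetrically from the
#' other end.  The read is dropped if no window passes or if the trimmed
#' length falls below \code{min_length}.
#'
#' @param seq DNA string.
#' @param qual integer PHRED scores, same length as \code{seq}.
#' @param q_threshold mean-window PHRED threshold (default 20).
#' @param min_length minimum retained length in bp (default 100).
#' @return list(kept, start, end): 0-based half-open slice into the read.
#' @export
trim_read <- function(seq, qual, q_threshold = 20L, min_length = 100L) {
  len <- nchar(seq)
  stopifnot(len > 0L, length(qual) == len)
  w <- max(1L, as.integer(floor(0.1 * len)))
  nwin <- len - w + 1L
  cs <- c(0, cumsum(qual))
  means <- (cs[(w + 1L):(len + 1L)] - cs[1L:nwin]) / w
  pass <- which(means >= q_threshold)
  if (!length(pass)) return(list(kept = FALSE, start = 0L, end = 0L))
  lead_win <- pass[1L]                      # 1-based window start
  trail_win <- pass[length(pass)]           # last passing window
  # refine to bases meeting the threshold inside/after the window edges
  start <- lead_win
  while (qual[start] < q_threshold) start <- start + 1L
  end <- trail_win + w - 1L                 # 1-based inclusive window end
  while (qual[end] < q_threshold) end <- end - 1L
  if (end - start + 1L < min_length) return(list(kept = FALSE, start = 0L, end = 0L))
  list(kept = TRUE, start = start - 1L, end = end)
}

#' Merge a trimmed read pair by 3' overlap, or join artificially
#'
#' The reverse complement of the second mate is searched for a 3'(R1)/5'(R2)
#' overlap of at least \code{min_overlap} bases.  Candidates are scored by
#' mismatch fraction (positions where both bases are non-N and differ); the
#' lowest fraction wins, ties going to the longest overlap, and the winner
#' is accepted only if its fraction is at most \code{max_mismatch_frac}.
#' Within the overlap the base with the higher PHRED score is emitted (ties
#' keep R1's base).  If no candidate is accepted the pair is joined
#' artificially as \code{R1 + N*n_pad + revcomp(R2)} with quality 0 at the
#' pad positions.
#'
#' @param seq1,seq2 trimmed mate sequences (R2 in sequencer orientation).
#' @param qual1,qual2 integer PHRED scores for each mate.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum accepted mismatch fraction (default 0.25).
#' @param n_pad number of N characters inserted when joining (default 10).
#' @return list(mode, sequence, qual) where mode is "overlap_merged" or
#'   "artificially_joined" and qual is an integer vector aligned to sequence.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                       max_mismatch_frac = 0.25, n_pad = 10L) {
  rc2 <- revcomp(seq2)
  rq2 <- rev(qual2)
  cand <- .overlap_scan_cpp(seq1, rc2, as.integer(min_overlap))
  if (cand$overlap >= min_overlap && !is.na(cand$mismatch_frac) &&
      cand$mismatch_frac <= max_mismatch_frac) {
    o <- cand$overlap
    n1 <- nchar(seq1); n2 <- nchar(rc2)
    c1 <- strsplit(substr(seq1, n1 - o + 1L, n1), "")[[1]]
    c2 <- strsplit(substr(rc2, 1L, o), "")[[1]]
    q1 <- qual1[(n1 - o + 1L):n1]
    q2 <- rq2[1L:o]
    take1 <- (c1 == c2) | (c2 == "N" & c1 != "N") |
      (c1 != "N" & c2 != "N" & q1 >= q2)
    ov_seq <- ifelse(take1, c1, c2)
    ov_q <- ifelse(c1 == c2, pmax(q1, q2), ifelse(take1, q1, q2))
    seq <- paste0(substr(seq1, 1L, n1 - o), paste(ov_seq, collapse = ""),
                  substr(rc2, o + 1L, n2))
    qual <- c(if (n1 > o) qual1[1L:(n1 - o)] else integer(0),
              as.integer(ov_q),
              if (n2 > o) rq2[(o + 1L):n2] else integer(0))
    list(mode = "overlap_merged", sequence = seq, qual = qual)
  } else {
    list(mode = "artificially_joined",
         sequence = paste0(seq1, strrep("N", n_pad), rc2),
         qual = c(qual1, rep(0L, n_pad), rq2))
  }
}

#' Estimate per-locus sequencing error from PHRED scores
#'
#' For each locus, the mean PHRED score is computed within each retained
#' read, averaged across reads, and converted to an error probability
#' \eqn{\epsilon = 10^{-\bar{Q}/10}}, clamped to \[1e-6, 0.5\].
#'
#' @param reads_by_locus named list: locus -> list of integer PHRED vectors.
#' @return named numeric vector of error rates (a locus-error table).
#' @export
estimate_locus_error <- function(reads_by_locus) {
  out <- numeric(0)
  for (loc in names(reads_by_locus)) {
    quals <- reads_by_locus[[loc]]
    quals <- quals[vapply(quals, length, integer(1)) > 0L]
    if (!length(quals)) {
      warning("locus '", loc, "' has no retained reads; omitted from error table")
      next
    }
    qbar <- mean(vapply(quals, mean, numeric(1)))
    out[loc] <- min(0.5, max(1e-6, 10^(-qbar / 10)))
  }
  out
}

#' Run the full preprocessing step on an annotated FASTQ pair
#'
#' Trims both mates, merges overlapping pairs (N-joining the rest), emits
#' one sequence record per retained pair, and writes per-locus FASTA files,
#' a taxon table (all ploidies \code{None}), a locus-error table, and a
#' summary log under \code{out_dir}.  If exactly one mate survives trimming
#' it is emitted alone (mode \code{single_survivor}); pairs in which neither
#' mate survives are discarded.  Counts reconcile exactly:
#' input = discarded + merged + n_joined + single_survivor.
#'
#' @param path_r1,path_r2 annotated FASTQ paths.
#' @param out_dir output directory.
#' @param q_threshold,min_length see [trim_read()].
#' @param min_overlap,max_mismatch_frac,n_pad see [merge_pair()].
#' @param format a [header_format()].
#' @param offset PHRED ASCII offset.
#' @return invisibly, a list with \code{counts}, \code{records},
#'   \code{taxon_table}, \code{locus_err} and the output paths.
#' @export
run_preprocess <- function(path_r1, path_r2, out_dir,
                           q_threshold = 20L, min_length = 100L,
                           min_overlap = 10L, max_mismatch_frac = 0.25,
                           n_pad = 10L, format = header_format(),
                           offset = 33L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  parsed <- parse_annotated_fastq(path_r1, path_r2, format = format,
                                  reject_path = file.path(out_dir, "rejects.log"),
                                  offset = offset)
  pairs <- parsed$pairs
  n_in <- nrow(pairs)
  counts <- c(input = n_in, discarded = 0L, merged = 0L, n_joined = 0L,
              single_survivor = 0L, rejected = nrow(parsed$rejected))
  rec_taxon <- character(0); rec_locus <- character(0); rec_seq <- character(0)
  qual_by_locus <- list()
  uid_counter <- new.env(parent = emptyenv())
  add_qual <- function(loc, q) {
    qual_by_locus[[loc]] <<- c(qual_by_locus[[loc]], list(q))
  }
  for (i in seq_len(n_in)) {
    q1 <- phred_to_int(pairs$qual1[i], offset)
    q2 <- phred_to_int(pairs$qual2[i], offset)
    t1 <- trim_read(pairs$seq1[i], q1, q_threshold, min_length)
    t2 <- trim_read(pairs$seq2[i], q2, q_threshold, min_length)
    loc <- pairs$locus[i]
    if (!t1$kept && !t2$kept) {
      counts["discarded"] <- counts["discarded"] + 1L
      next
    }
    if (t1$kept && t2$kept) {
      s1 <- substr(pairs$seq1[i], t1$start + 1L, t1$end)
      s2 <- substr(pairs$seq2[i], t2$start + 1L, t2$end)
      tq1 <- q1[(t1$start + 1L):t1$end]
      tq2 <- q2[(t2$start + 1L):t2$end]
      m <- merge_pair(s1, tq1, s2, tq2, min_overlap, max_mismatch_frac, n_pad)
      seq_out <- m$sequence
      if (m$mode == "overlap_merged") {
        counts["merged"] <- counts["merged"] + 1L
      } else {
        counts["n_joined"] <- counts["n_joined"] + 1L
      }
      add_qual(loc, tq1); add_qual(loc, tq2)
    } else {
      counts["single_survivor"] <- counts["single_survivor"] + 1L
      if (t1$kept) {
        seq_out <- substr(pairs$seq1[i], t1$start + 1L, t1$end)
        add_qual(loc, q1[(t1$start + 1L):t1$end])
      } else {
        seq_out <- revcomp(substr(pairs$seq2[i], t2$start + 1L, t2$end))
        add_qual(loc, q2[(t2$start + 1L):t2$end])
      }
    }
    key <- paste(pairs$taxon[i], loc, sep = "|")
    uid <- (get0(key, envir = uid_counter, ifnotfound = 0L)) + 1L
    assign(key, uid, envir = uid_counter)
    rec_taxon <- c(rec_taxon, pairs$taxon[i])
    rec_locus <- c(rec_locus, loc)
    rec_seq <- c(rec_seq, seq_out)
    names(rec_seq)[length(rec_seq)] <- as.character(uid)
  }
  records <- data.frame(taxon = rec_taxon, locus = rec_locus,
                        uid = as.integer(names(rec_seq) %||% character(0)),
                        sequence = unname(rec_seq), stringsAsFactors = FALSE)
  fasta_paths <- if (nrow(records)) write_purc_fasta(records, out_dir) else character(0)
  taxa <- unique(pairs$taxon)
  taxon_table <- setNames(rep(NA_integer_, length(taxa)), taxa)
  locus_err <- estimate_locus_error(qual_by_locus)
  write_taxon_table(taxon_table, file.path(out_dir, "taxon_table.txt"))
  write_locus_error_table(locus_err, file.path(out_dir, "locus_err.txt"))
  stopifnot(counts["input"] == counts["discarded"] + counts["merged"] +
              counts["n_joined"] + counts["single_survivor"])
  log_lines <- c(sprintf("preprocess: %s + %s", path_r1, path_r2),
                 sprintf("%s\t%d", names(counts), counts))
  write_lines_atomic(log_lines, file.path(out_dir, "preprocess.log"))
  invisible(list(counts = counts, records = records,
                 taxon_table = taxon_table, locus_err = locus_err,
                 fasta_paths = fasta_paths, out_dir = out_dir))
}
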