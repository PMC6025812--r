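# Internal realignment (center-star) and alignment-column cleaning, the
# in-package substitutes for shelling out to an external aligner and a
# column-occupancy cleaner.

#' Center-star multiple alignment
#'
#' The center is the sequence with maximal summed pairwise identity to all
#' others (ties broken toward the longest, then lexicographically
#' smallest).  Every other sequence is globally aligned to the center
#' (match 1, mismatch -1, gap -2) and the pairwise alignments are merged by
#' gap propagation.  Ungapping any output row recovers its input sequence.
#'
#' @param seqs character vector of one or more non-empty DNA strings.
#' @return list of class \code{amp_alignment} with elements \code{rows}
#'   (gapped strings, in input order) and \code{center} (index of the
#'   center sequence).
#' @export
center_star_align <- function(seqs) {
  stopifnot(length(seqs) >= 1L, all(nzchar(seqs)))
  n <- length(seqs)
  if (n == 1L) {
    return(structure(list(rows = seqs, center = 1L), class = "amp_alignment"))
  }
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    ids <- .nw_identity_many_cpp(seqs[i], seqs[(i + 1L):n])
    idm[i, (i + 1L):n] <- ids
    idm[(i + 1L):n, i] <- ids
  }
  sums <- rowSums(idm) - 1
  best <- which(sums == max(sums))
  if (length(best) > 1L) {
    lens <- nchar(seqs[best])
    best <- best[lens == max(lens)]
    if (length(best) > 1L) best <- best[order(seqs[best])][1L]
  }
  center <- best[1L]
  master <- strsplit(seqs[center], "")[[1]]        # gapped center, grown as we merge
  rows <- list()                                   # gapped non-center rows, parallel to master
  others <- setdiff(seq_len(n), center)
  for (k in others) {
    al <- .nw_align_cpp(seqs[center], seqs[k])
    ca <- strsplit(al$a, "")[[1]]
    sa <- strsplit(al$b, "")[[1]]
    # merge (ca, sa) into master coordinates
    new_master <- character(0)
    new_row <- character(0)
    i <- 1L; j <- 1L
    nm <- length(master); np <- length(ca)
    while (i <= nm || j <= np) {
      mi <- if (i <= nm) master[i] else NULL
      cj <- if (j <= np) ca[j] else NULL
      if (!is.null(mi) && mi == "-" && (is.null(cj) || cj != "-")) {
        # master has a gap column the new pairwise alignment lacks
        new_master <- c(new_master, "-")
        new_row <- c(new_row, "-")
        i <- i + 1L
      } else if (!is.null(cj) && cj == "-" && (is.null(mi) || mi != "-")) {
        # new alignment inserts a gap into the center: add a column everywhere
        new_master <- c(new_master, "-")
        new_row <- c(new_row, sa[j])
        rows <- lapply(rows, function(r) append(r, "-", after = length(new_master) - 1L))
        j <- j + 1L
      } else {
        # both gap, or both the same center base: columns coincide
        new_master <- c(new_master, mi)
        new_row <- c(new_row, sa[j])
        i <- i + 1L; j <- j + 1L
      }
    }
    master <- new_master
    rows <- lapply(rows, function(r) c(r, rep("-", length(master) - length(r))))
    rows[[length(rows) + 1L]] <- new_row
  }
  rows <- lapply(rows, function(r) c(r, rep("-", length(master) - length(r))))
  out <- character(n)
  out[center] <- paste(master, collapse = "")
  for (t in seq_along(others)) out[others[t]] <- paste(rows[[t]], collapse = "")
  structure(list(rows = out, center = center), class = "amp_alignment")
}

#' Drop low-occupancy alignment columns
#'
#' Removes every column whose fraction of informative characters (non-gap,
#' non-N) is strictly below \code{min_occupancy}.  With
#' \code{min_occupancy = 0} this is the identity.
#'
#' @param aln an \code{amp_alignment} or a character vector of equal-length
#'   gapped strings.
#' @param min_occupancy occupancy threshold in \[0, 1\] (default 0.33).
#' @return object of the same shape with the offending columns removed.
#' @export
clean_columns <- function(aln, min_occupancy = 0.33) {
  rows <- if (inherits(aln, "amp_alignment")) aln$rows else aln
  stopifnot(length(rows) >= 1L, length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, ""))
  occ <- colMeans(mat != "-" & mat != "N")
  keep <- occ >= min_occupancy
  if (!any(keep)) {
    stop("clean_columns: every column falls below occupancy ", min_occupancy,
         "; lower the threshold")
  }
  cleaned <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (inherits(aln, "amp_alignment")) {
    aln$rows <- cleaned
    aln
  } else cleaned
}
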