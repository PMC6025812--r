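# Readers/writers for every file the pipeline touches: annotated paired
# FASTQ, per-locus FASTA with the '>taxon|locus|uid' header grammar,
# clustered FASTA with ';size=' annotations, and the two TSV tables.

#' Describe where the taxon/locus annotation sits in a FASTQ header
#'
#' Demultiplexers annotate read headers with the sample and locus each read
#' belongs to.  The exact layout varies, so the parser is configurable: the
#' header (after the leading \code{@}) is split on whitespace, one field is
#' taken as the annotation, and that field is split again on \code{sep} to
#' yield the taxon and locus.  The default matches headers of the form
#' \code{@read001 TaxA:LocX}.
#'
#' @param field 1-based index of the whitespace-delimited header field
#'   carrying the annotation.
#' @param sep separator inside the annotation field.
#' @param taxon_index,locus_index 1-based positions of taxon and locus within
#'   the split annotation field.
#' @return an object of class \code{header_format}.
#' @export
header_format <- function(field = 2L, sep = ":", taxon_index = 1L,
                          locus_index = 2L) {
  structure(list(field = as.integer(field), sep = sep,
                 taxon_index = as.integer(taxon_index),
                 locus_index = as.integer(locus_index)),
            class = "header_format")
}

read_fastq_raw <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (near line %d)",
                 path, n, n))
  }
  if (n == 0L) {
    return(data.frame(header = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  h <- lines[seq(1L, n, by = 4L)]
  s <- lines[seq(2L, n, by = 4L)]
  p <- lines[seq(3L, n, by = 4L)]
  q <- lines[seq(4L, n, by = 4L)]
  bad_h <- which(!startsWith(h, "@"))
  if (length(bad_h)) {
    stop(sprintf("malformed FASTQ '%s': record header at line %d does not start with '@'",
                 path, (bad_h[1L] - 1L) * 4L + 1L))
  }
  bad_p <- which(!startsWith(p, "+"))
  if (length(bad_p)) {
    stop(sprintf("malformed FASTQ '%s': separator at line %d does not start with '+'",
                 path, (bad_p[1L] - 1L) * 4L + 3L))
  }
  bad_l <- which(nchar(s) != nchar(q))
  if (length(bad_l)) {
    stop(sprintf("malformed FASTQ '%s': sequence/quality length mismatch at line %d",
                 path, (bad_l[1L] - 1L) * 4L + 2L))
  }
  data.frame(header = sub("^@", "", h), seq = toupper(s), qual = q,
             stringsAsFactors = FALSE)
}

parse_annotation <- function(headers, format) {
  fields <- strsplit(headers, "[[:space:]]+")
  ann <- vapply(fields, function(f) {
    if (length(f) >= format$field) f[[format$field]] else NA_character_
  }, character(1))
  parts <- strsplit(ann, format$sep, fixed = TRUE)
  taxon <- vapply(parts, function(p) {
    if (!all(is.na(p)) && length(p) >= format$taxon_index) p[[format$taxon_index]] else NA_character_
  }, character(1))
  locus <- vapply(parts, function(p) {
    if (!all(is.na(p)) && length(p) >= format$locus_index) p[[format$locus_index]] else NA_character_
  }, character(1))
  id <- vapply(fields, `[[`, character(1), 1L)
  ok <- !is.na(taxon) & !is.na(locus) & nzchar(taxon) & nzchar(locus) &
    !grepl("[|[:space:]]", taxon) & !grepl("[|[:space:]]", locus)
  list(read_id = id, taxon = taxon, locus = locus, ok = ok)
}

#' Parse a demultiplexed, annotated paired-end FASTQ pair
#'
#' Reads two position-paired FASTQ files whose headers carry taxon and locus
#' annotations (see [header_format()]).  Records whose annotation cannot be
#' parsed are routed to a reject set (and optionally a reject log file),
#' never silently dropped: emitted + rejected always equals the input count.
#'
#' @param path_r1,path_r2 paths to the R1/R2 FASTQ files.
#' @param format a [header_format()].
#' @param reject_path optional path for a TSV log of rejected read ids.
#' @param offset PHRED ASCII offset (33 or 64).
#' @return a list with \code{pairs} (data.frame: read_id, taxon, locus,
#'   seq1, seq2, qual1, qual2 — qualities as PHRED strings) and
#'   \code{rejected} (data.frame: read_id, reason).
#' @export
parse_annotated_fastq <- function(path_r1, path_r2, format = header_format(),
                                  reject_path = NULL, offset = 33L) {
  r1 <- read_fastq_raw(path_r1)
  r2 <- read_fastq_raw(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("paired FASTQ files disagree: '%s' has %d records but '%s' has %d",
                 path_r1, nrow(r1), path_r2, nrow(r2)))
  }
  if (nrow(r1) == 0L) {
    return(list(pairs = data.frame(read_id = character(0), taxon = character(0),
                                   locus = character(0), seq1 = character(0),
                                   seq2 = character(0), qual1 = character(0),
                                   qual2 = character(0), stringsAsFactors = FALSE),
                rejected = data.frame(read_id = character(0), reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  ann <- parse_annotation(r1$header, format)
  pairs <- data.frame(read_id = ann$read_id, taxon = ann$taxon,
                      locus = ann$locus, seq1 = r1$seq, seq2 = r2$seq,
                      qual1 = r1$qual, qual2 = r2$qual,
                      stringsAsFactors = FALSE)[ann$ok, , drop = FALSE]
  rownames(pairs) <- NULL
  rejected <- data.frame(read_id = ann$read_id[!ann$ok],
                         reason = rep("missing or malformed taxon/locus annotation",
                                      sum(!ann$ok)),
                         stringsAsFactors = FALSE)
  if (!is.null(reject_path) && nrow(rejected) > 0L) {
    write_lines_atomic(paste(rejected$read_id, rejected$reason, sep = "\t"),
                       reject_path)
  }
  list(pairs = pairs, rejected = rejected)
}

#' Write per-locus FASTA files with phased-pipeline headers
#'
#' Each record is written as \code{>taxon|locus|uid} followed by its
#' sequence, one FASTA file per locus (\code{<locus>.fasta} in
#' \code{out_dir}).  Re-parsing with [read_locus_fasta()] reproduces the
#' input records.
#'
#' @param records data.frame with columns taxon, locus, uid, sequence.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written (named by locus).
#' @export
write_purc_fasta <- function(records, out_dir) {
  stopifnot(all(c("taxon", "locus", "uid", "sequence") %in% names(records)))
  check_label(records$taxon, "taxon")
  check_label(records$locus, "locus")
  key <- paste(records$taxon, records$locus, sep = "|")
  dup <- duplicated(paste(key, records$uid))
  if (any(dup)) {
    stop("duplicate uid within taxon x locus: ",
         paste(unique(paste(key, records$uid)[dup]), collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (loc in unique(records$locus)) {
    sub <- records[records$locus == loc, , drop = FALSE]
    lines <- as.vector(rbind(sprintf(">%s|%s|%d", sub$taxon, sub$locus,
                                     as.integer(sub$uid)),
                             sub$sequence))
    p <- file.path(out_dir, paste0(loc, ".fasta"))
    write_lines_atomic(lines, p)
    paths[loc] <- p
  }
  invisible(paths)
}

parse_fasta_lines <- function(lines) {
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) {
    return(list(header = character(0), sequence = character(0)))
  }
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (starts[i] > ends[i]) "" else
      paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  list(header = sub("^>", "", lines[hdr_idx]), sequence = toupper(seqs))
}

#' Read a per-locus FASTA written by [write_purc_fasta()]
#'
#' @param path FASTA file path.
#' @return data.frame with columns taxon, locus, uid, sequence.
#' @export
read_locus_fasta <- function(path) {
  fa <- parse_fasta_lines(readLines(path))
  parts <- strsplit(fa$header, "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("'%s': header '%s' is not 'taxon|locus|uid'", path,
                 fa$header[which(bad)[1L]]))
  }
  data.frame(taxon = vapply(parts, `[[`, character(1), 1L),
             locus = vapply(parts, `[[`, character(1), 2L),
             uid = as.integer(vapply(parts, `[[`, character(1), 3L)),
             sequence = fa$sequence, stringsAsFactors = FALSE)
}

#' Read/write clustered FASTA with size annotations
#'
#' Cluster files use the dereplication-style header grammar
#' \code{>taxon|locus|clusterN;size=S}; round-tripping is lossless.
#'
#' @param clusters data.frame with columns taxon, locus, cluster_index
#'   (0-based), size, sequence.
#' @param path file path.
#' @return \code{write_cluster_fasta}: invisibly, the path;
#'   \code{read_cluster_fasta}: the clusters data.frame.
#' @export
write_cluster_fasta <- function(clusters, path) {
  stopifnot(all(c("taxon", "locus", "cluster_index", "size", "sequence")
                %in% names(clusters)))
  if (any(clusters$size < 1L)) stop("cluster sizes must be >= 1")
  lines <- as.vector(rbind(
    sprintf(">%s|%s|cluster%d;size=%d", clusters$taxon, clusters$locus,
            as.integer(clusters$cluster_index), as.integer(clusters$size)),
    clusters$sequence))
  write_lines_atomic(lines, path)
  invisible(path)
}

#' @rdname write_cluster_fasta
#' @export
read_cluster_fasta <- function(path) {
  fa <- parse_fasta_lines(readLines(path))
  m <- regmatches(fa$header,
                  regexec("^([^|]+)\\|([^|]+)\\|cluster([0-9]+);size=([0-9]+)$",
                          fa$header))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop(sprintf("'%s': header '%s' is not 'taxon|locus|clusterN;size=S'",
                 path, fa$header[which(bad)[1L]]))
  }
  data.frame(taxon = vapply(m, `[[`, character(1), 2L),
             locus = vapply(m, `[[`, character(1), 3L),
             cluster_index = as.integer(vapply(m, `[[`, character(1), 4L)),
             size = as.integer(vapply(m, `[[`, character(1), 5L)),
             sequence = fa$sequence, stringsAsFactors = FALSE)
}

#' Read/write the taxon (ploidy) table
#'
#' A two-column TSV mapping each taxon to its ploidy; unknown ploidy is the
#' literal string \code{None}.  In R the table is a named vector whose
#' values are positive integers or \code{NA} (unknown).
#'
#' @param taxa named integer vector (NA = unknown ploidy).
#' @param path file path.
#' @export
write_taxon_table <- function(taxa, path) {
  vals <- ifelse(is.na(taxa), "None", as.character(as.integer(taxa)))
  write_lines_atomic(if (length(taxa)) paste(names(taxa), vals, sep = "\t")
                     else character(0), path)
  invisible(path)
}

#' @rdname write_taxon_table
#' @export
read_taxon_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(integer(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop(sprintf("'%s': line %d is not two tab-separated columns",
                             path, which(bad)[1L]))
  taxon <- vapply(parts, `[[`, character(1), 1L)
  raw <- vapply(parts, `[[`, character(1), 2L)
  ploidy <- rep(NA_integer_, length(raw))
  known <- raw != "None"
  suppressWarnings(ploidy[known] <- as.integer(raw[known]))
  bad_p <- known & (is.na(ploidy) | ploidy < 1L)
  if (any(bad_p)) {
    i <- which(bad_p)[1L]
    stop(sprintf("'%s': unparseable ploidy '%s' for taxon '%s' at line %d",
                 path, raw[i], taxon[i], i))
  }
  if (anyDuplicated(taxon)) {
    stop(sprintf("'%s': duplicated taxon '%s'", path,
                 taxon[duplicated(taxon)][1L]))
  }
  setNames(ploidy, taxon)
}

#' Read/write the per-locus sequencing-error table
#'
#' A two-column TSV mapping each locus to its error probability
#' \eqn{\epsilon \in (0, 1)}, written with 6 significant digits.
#'
#' @param errs named numeric vector of error rates.
#' @param path file path.
#' @export
write_locus_error_table <- function(errs, path) {
  if (length(errs) && (any(errs <= 0) || any(errs >= 1))) {
    stop("error rates must lie strictly in (0, 1)")
  }
  write_lines_atomic(if (length(errs))
    paste(names(errs), sprintf("%#.6g", errs), sep = "\t")
    else character(0), path)
  invisible(path)
}

#' @rdname write_locus_error_table
#' @export
read_locus_error_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop(sprintf("'%s': line %d is not two tab-separated columns",
                             path, which(bad)[1L]))
  locus <- vapply(parts, `[[`, character(1), 1L)
  eps <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad_e <- is.na(eps) | eps <= 0 | eps >= 1
  if (any(bad_e)) {
    i <- which(bad_e)[1L]
    stop(sprintf("'%s': invalid error rate for locus '%s' at line %d",
                 path, locus[i], i))
  }
  setNames(eps, locus)
}
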