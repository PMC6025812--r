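#' @useDynLib ampliphase, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Handles the alphabet \{A,C,G,T,N\}; other characters are left unchanged
#' (after complementation lookup they map to \code{N}).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- comp[ch]
    out[is.na(out)] <- "N"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between PHRED quality strings and integer scores
#'
#' @param x a quality string (one read) or integer vector of scores.
#' @param offset ASCII offset, 33 (Sanger) by default; 64 selectable.
#' @return integer vector of scores, or a single quality string.
#' @export
phred_to_int <- function(x, offset = 33L) {
  utf8ToInt(x) - as.integer(offset)
}

#' @rdname phred_to_int
#' @export
int_to_phred <- function(x, offset = 33L) {
  intToUtf8(as.integer(x) + as.integer(offset))
}

# Write lines atomically: temp file in the same directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wt")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  writeLines(lines, con)
  close(con)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("atomic rename failed for ", path)
  }
  invisible(path)
}

check_label <- function(x, what) {
  bad <- !nzchar(x) | grepl("[|[:space:]]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s label(s): %s (must be non-empty, no '|' or whitespace)",
                 what, paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
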