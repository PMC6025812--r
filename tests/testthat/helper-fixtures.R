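# Small in-code fixtures shared across test files.

write_fastq <- function(path, ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, path)
  path
}

uniform_qual <- function(len, q) {
  ampliphase::int_to_phred(rep(q, len))
}

# A minimal annotated two-record FASTQ pair in a temp dir.
toy_fastq_pair <- function(dir = withr_local_tempdir()) {
  r1 <- file.path(dir, "R1.fastq")
  r2 <- file.path(dir, "R2.fastq")
  s <- strrep("ACGT", 40)
  q <- uniform_qual(160, 35L)
  write_fastq(r1, c("read1 TaxA:LocX", "read2 TaxA:LocX"), c(s, s), c(q, q))
  write_fastq(r2, c("read1 TaxA:LocX", "read2 TaxA:LocX"),
              c(ampliphase::revcomp(s), ampliphase::revcomp(s)), c(q, q))
  list(r1 = r1, r2 = r2)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("ampfix")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
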