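# Synthetic polyploid amplicon data with known ground truth: haplotypes
# with integer dosages, paired-end reads with PHRED-consistent substitution
# errors, a stated fraction of non-overlapping pairs, and single-breakpoint
# PCR chimeras at a stated rate.

#' Build a simulation configuration
#'
#' The defaults describe the stated world of the test suite: two-locus,
#' ~550 bp amplicons read as 300 bp pairs (guaranteeing a >= 50 bp
#' overlap), 200 read pairs per taxon x locus, a per-base error rate of
#' 0.005 (about Q23) and 2\% haplotype divergence.
#'
#' @param taxa data.frame with columns taxon, ploidy (true ploidy used for
#'   generation) and known (logical: is the ploidy written to the taxon
#'   table, or listed as \code{None}?).
#' @param loci named integer vector of amplicon lengths (bp).
#' @param divergence substitutions/site between haplotypes and their
#'   ancestor.
#' @param dosage optional nested list \code{dosage[[taxon]][[locus]]} of
#'   integer dosage vectors summing to the taxon's ploidy; default: one
#'   haplotype for K = 1, otherwise two haplotypes at
#'   \code{(ceiling(K/2), floor(K/2))}.
#' @param depth read pairs per taxon x locus.
#' @param read_length length of each mate (bp).
#' @param epsilon per-base error rate, recycled over loci.
#' @param chimera_rate fraction of reads drawn from two-parent
#'   recombinants.
#' @param non_overlap_fraction fraction of pairs whose mates cannot
#'   overlap.
#' @param min_overlap overlap guarantee used to validate read_length.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(taxa = data.frame(taxon = c("TaxA", "TaxB"),
                                         ploidy = c(2L, 4L),
                                         known = c(TRUE, TRUE)),
                       loci = c(L1 = 550L, L2 = 550L),
                       divergence = 0.02, dosage = NULL, depth = 200L,
                       read_length = 300L, epsilon = 0.005,
                       chimera_rate = 0, non_overlap_fraction = 0,
                       min_overlap = 10L, seed = 1L) {
  if (is.list(loci)) loci <- unlist(loci)          # e.g. from a JSON config
  if (is.list(epsilon)) epsilon <- unlist(epsilon)
  stopifnot(is.data.frame(taxa),
            all(c("taxon", "ploidy", "known") %in% names(taxa)),
            length(loci) >= 1L, !is.null(names(loci)),
            divergence >= 0, divergence < 1, depth >= 1L,
            chimera_rate >= 0, chimera_rate < 1,
            non_overlap_fraction >= 0, non_overlap_fraction < 1)
  eps <- rep_len(epsilon, length(loci))
  names(eps) <- names(loci)
  stopifnot(all(eps > 0 & eps < 1))
  if (any(2L * read_length - loci < min_overlap)) {
    stop("read_length too short: overlapping pairs need ",
         "2*read_length - locus_length >= min_overlap")
  }
  if (any(read_length > loci)) stop("read_length exceeds a locus length")
  structure(list(taxa = taxa, loci = loci, divergence = divergence,
                 dosage = dosage, depth = as.integer(depth),
                 read_length = as.integer(read_length), epsilon = eps,
                 chimera_rate = chimera_rate,
                 non_overlap_fraction = non_overlap_fraction,
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_dosage <- function(K) {
  if (K == 1L) c(1L) else c(as.integer(ceiling(K / 2)), as.integer(floor(K / 2)))
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Draw true haplotypes and dosages per taxon x locus
#'
#' One ancestral sequence per locus; each haplotype mutates it
#' independently at the divergence rate.  Colliding haplotypes are
#' regenerated (bounded retries, with a warning).
#'
#' @param config a [sim_config()].
#' @return object of class \code{sim_truth}: nested list
#'   \code{truth[[taxon]][[locus]]} with haplotypes and dosage, plus the
#'   ancestors.
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ancestors <- vapply(config$loci, random_dna, character(1))
  truth <- list()
  for (ti in seq_len(nrow(config$taxa))) {
    tax <- config$taxa$taxon[ti]
    K <- config$taxa$ploidy[ti]
    truth[[tax]] <- list()
    for (loc in names(config$loci)) {
      dos <- config$dosage[[tax]][[loc]] %||% default_dosage(K)
      stopifnot(sum(dos) == K, all(dos >= 1L))
      nh <- length(dos)
      if (nh > 1L && config$divergence == 0) {
        stop("divergence 0 cannot produce ", nh, " distinct haplotypes")
      }
      haps <- character(nh)
      for (attempt in 1:25) {
        haps <- vapply(seq_len(nh), function(i)
          mutate_seq(ancestors[[loc]], config$divergence), character(1))
        if (!anyDuplicated(haps)) break
        if (attempt == 25L) stop("could not draw distinct haplotypes")
        warning("haplotype collision at divergence ", config$divergence,
                "; regenerating")
      }
      truth[[tax]][[loc]] <- list(haplotypes = haps, dosage = as.integer(dos))
    }
  }
  structure(list(truth = truth, ancestors = ancestors, config = config),
            class = "sim_truth")
}

apply_errors <- function(seq, eps) {
  if (eps <= 0) return(seq)
  mutate_seq(seq, eps)
}

sim_qual_string <- function(len, eps) {
  q0 <- as.integer(round(-10 * log10(eps)))
  q <- pmin(41L, pmax(2L, q0 + sample(-2:2, len, replace = TRUE)))
  int_to_phred(q)
}

#' Simulate annotated paired-end FASTQ reads from a truth set
#'
#' Reads are drawn from haplotypes proportional to dosage; a
#' \code{chimera_rate} fraction come from single-breakpoint two-parent
#' recombinants; a \code{non_overlap_fraction} of pairs are read short
#' enough that the mates cannot overlap.  Substitution errors occur at the
#' per-locus rate, and quality strings have per-read mean PHRED equal to
#' \eqn{-10 \log_{10} \epsilon} in expectation.  Output is byte-identical
#' under a fixed seed.
#'
#' @param truth a [simulate_haplotypes()] result.
#' @param out_dir directory for \code{reads_R1.fastq}/\code{reads_R2.fastq},
#'   truth tables and a config echo.
#' @return invisibly, list with paths, the per-read truth data.frame, the
#'   haplotype truth data.frame, and the taxon table.
#' @export
simulate_reads <- function(truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  r1 <- character(0); r2 <- character(0)
  read_rows <- list()
  counter <- 0L
  for (tax in names(truth$truth)) {
    for (loc in names(config$loci)) {
      tl <- truth$truth[[tax]][[loc]]
      L <- config$loci[[loc]]
      eps <- config$epsilon[[loc]]
      nh <- length(tl$haplotypes)
      probs <- tl$dosage / sum(tl$dosage)
      for (r in seq_len(config$depth)) {
        counter <- counter + 1L
        is_chim <- nh >= 2L && runif(1) < config$chimera_rate
        if (is_chim) {
          pp <- sample(nh, 2L)
          b <- sample(seq(2L, L - 1L), 1L)
          template <- paste0(substr(tl$haplotypes[pp[1L]], 1L, b),
                             substr(tl$haplotypes[pp[2L]], b + 1L, L))
          origin <- sprintf("chimera:%d+%d@%d", pp[1L], pp[2L], b)
        } else {
          h <- sample.int(nh, 1L, prob = probs)
          template <- tl$haplotypes[h]
          origin <- sprintf("hap%d", h)
        }
        overlap <- runif(1) >= config$non_overlap_fraction
        rl <- if (overlap) config$read_length else
          max(config$min_overlap, (L - 20L) %/% 2L)
        fwd <- apply_errors(substr(template, 1L, rl), eps)
        rev <- apply_errors(revcomp(substr(template, L - rl + 1L, L)), eps)
        id <- sprintf("sim%06d", counter)
        ann <- sprintf("@%s %s:%s", id, tax, loc)
        r1 <- c(r1, ann, fwd, "+", sim_qual_string(rl, eps))
        r2 <- c(r2, ann, rev, "+", sim_qual_string(rl, eps))
        read_rows[[counter]] <- data.frame(read_id = id, taxon = tax,
                                           locus = loc, origin = origin,
                                           overlaps = overlap,
                                           stringsAsFactors = FALSE)
      }
    }
  }
  p1 <- file.path(out_dir, "reads_R1.fastq")
  p2 <- file.path(out_dir, "reads_R2.fastq")
  write_lines_atomic(r1, p1)
  write_lines_atomic(r2, p2)
  reads <- do.call(rbind, read_rows)
  hap_rows <- do.call(rbind, lapply(names(truth$truth), function(tax) {
    do.call(rbind, lapply(names(config$loci), function(loc) {
      tl <- truth$truth[[tax]][[loc]]
      data.frame(taxon = tax, locus = loc,
                 hap = seq_along(tl$haplotypes), dosage = tl$dosage,
                 sequence = tl$haplotypes, stringsAsFactors = FALSE)
    }))
  }))
  tt <- setNames(ifelse(config$taxa$known, config$taxa$ploidy, NA_integer_),
                 config$taxa$taxon)
  write_lines_atomic(
    c("read_id\ttaxon\tlocus\torigin\toverlaps",
      sprintf("%s\t%s\t%s\t%s\t%s", reads$read_id, reads$taxon, reads$locus,
              reads$origin, reads$overlaps)),
    file.path(out_dir, "truth_reads.tsv"))
  write_lines_atomic(
    c("taxon\tlocus\thap\tdosage\tsequence",
      sprintf("%s\t%s\t%d\t%d\t%s", hap_rows$taxon, hap_rows$locus,
              hap_rows$hap, hap_rows$dosage, hap_rows$sequence)),
    file.path(out_dir, "truth_haplotypes.tsv"))
  write_taxon_table(tt, file.path(out_dir, "true_taxon_table.txt"))
  cfg <- config
  cfg$taxa <- as.list(setNames(cfg$taxa$ploidy, cfg$taxa$taxon))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "sim_config.json"))
  invisible(list(r1 = p1, r2 = p2, reads = reads, haplotypes = hap_rows,
                 taxon_table = tt, out_dir = out_dir))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a complete annotated dataset
#'
#' Seeds the RNG from \code{config$seed}, draws haplotypes and reads, and
#' writes FASTQ + truth tables to \code{out_dir}.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, the [simulate_reads()] result plus the truth object.
#' @export
simulate_dataset <- function(config, out_dir) {
  with_seed(config$seed, {
    truth <- simulate_haplotypes(config)
    res <- simulate_reads(truth, out_dir)
    res$truth <- truth
    invisible(res)
  })
}
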