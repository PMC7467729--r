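# Paired-end short-read simulation.
#
# FR-oriented pairs are drawn uniformly along each chromosome in proportion
# to its length; fragment sizes are normal (rounded, clamped); per-base
# substitution errors are applied independently at error_rate. Read names
# encode the true origin (chromosome, 0-based fragment start, fragment
# length) so downstream stages can be evaluated against truth.

#' Simulate paired-end reads from a genome
#'
#' @param genome a `toy_genome`, or a named character vector of chromosome
#'   sequences.
#' @param coverage target fold coverage (per-base expected read depth).
#' @param read_length read length (bp).
#' @param insert_mean,insert_sd fragment (outer insert) size mean and sd (bp).
#' @param error_rate per-base substitution error probability (< 0.1).
#' @param seed integer seed for the read substream.
#' @return a list of class `read_set`: `r1`, `r2` (character vectors),
#'   `names`, and a `truth` data.frame (chrom, frag_start, frag_len).
#' @export
simulate_reads <- function(genome, coverage = NULL, read_length = NULL,
                           insert_mean = NULL, insert_sd = NULL,
                           error_rate = NULL, seed = NULL) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  cfg <- if (inherits(genome, "toy_genome")) genome$config else NULL
  pick <- function(x, d) if (!is.null(x)) x else d
  coverage <- pick(coverage, cfg$coverage)
  read_length <- pick(read_length, cfg$read_length)
  insert_mean <- pick(insert_mean, cfg$insert_mean)
  insert_sd <- pick(insert_sd, cfg$insert_sd)
  error_rate <- pick(error_rate, cfg$error_rate)
  if (is.null(seed)) {
    seed <- substream_seed(if (!is.null(cfg)) cfg$master_seed else 0L, "reads")
  }
  stopifnot(read_length < insert_mean, coverage > 0,
            error_rate >= 0, error_rate < 0.1)
  lens <- nchar(chroms)
  if (insert_mean >= min(lens)) {
    stop("insert_mean must be smaller than the shortest chromosome")
  }
  set.seed(as.integer(seed))

  n_pairs <- max(1L, round(sum(lens) * coverage / (2 * read_length)))
  chrom_idx <- sample.int(length(chroms), n_pairs, replace = TRUE,
                          prob = lens / sum(lens))
  frag_len <- pmax(read_length + 10L,
                   as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                                 insert_sd))))
  frag_len <- pmin(frag_len, lens[chrom_idx] - 1L)
  start <- vapply(seq_len(n_pairs), function(i) {
    sample.int(lens[chrom_idx[i]] - frag_len[i] + 1L, 1L) - 1L
  }, integer(1))

  r1 <- character(n_pairs)
  r2 <- character(n_pairs)
  for (ci in seq_along(chroms)) {
    sel <- which(chrom_idx == ci)
    if (length(sel) == 0L) next
    s <- chroms[[ci]]
    frag1 <- substring(s, start[sel] + 1L, start[sel] + read_length)
    frag2 <- substring(s, start[sel] + frag_len[sel] - read_length + 1L,
                       start[sel] + frag_len[sel])
    r1[sel] <- frag1
    r2[sel] <- revcomp(frag2)
  }
  if (error_rate > 0) {
    r1 <- add_seq_errors(r1, error_rate)
    r2 <- add_seq_errors(r2, error_rate)
  }
  nm <- sprintf("sim:%s:%d:%d:%d", names(chroms)[chrom_idx], start, frag_len,
                seq_len(n_pairs))
  out <- list(
    r1 = r1, r2 = r2, names = nm,
    truth = data.frame(chrom = names(chroms)[chrom_idx], frag_start = start,
                       frag_len = frag_len),
    read_length = read_length, insert_mean = insert_mean,
    insert_sd = insert_sd
  )
  class(out) <- "read_set"
  out
}

# Independent per-base substitution errors at rate e
add_seq_errors <- function(reads, e) {
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, e)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Write a read set as paired FASTQ files
#'
#' @param reads a `read_set`.
#' @param r1_path,r2_path output paths (R1/R2).
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  qual1 <- strrep("I", nchar(reads$r1))
  qual2 <- strrep("I", nchar(reads$r2))
  l1 <- paste0("@", reads$names, "/1\n", reads$r1, "\n+\n", qual1)
  l2 <- paste0("@", reads$names, "/2\n", reads$r2, "\n+\n", qual2)
  writeLines(l1, r1_path)
  writeLines(l2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read set
#'
#' @param r1_path,r2_path paths to the R1/R2 FASTQ files.
#' @return a `read_set` (without truth information).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  parse_one <- function(path) {
    ln <- readLines(path)
    if (length(ln) %% 4L != 0L) {
      stop("malformed FASTQ ", path, ": record ", length(ln) %/% 4L + 1L,
           " is truncated")
    }
    heads <- ln[seq(1L, length(ln), by = 4L)]
    if (any(substr(heads, 1L, 1L) != "@")) {
      bad <- which(substr(heads, 1L, 1L) != "@")[1]
      stop("malformed FASTQ ", path, ": record ", bad, " lacks '@' header")
    }
    list(names = sub("/[12]$", "", sub("^@", "", heads)),
         seq = toupper(ln[seq(2L, length(ln), by = 4L)]))
  }
  a <- parse_one(r1_path)
  b <- parse_one(r2_path)
  stopifnot(identical(a$names, b$names))
  out <- list(r1 = a$seq, r2 = b$seq, names = a$names, truth = NULL,
              read_length = max(nchar(a$seq)))
  class(out) <- "read_set"
  out
}
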