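# Shared helpers: hand-built records and independent oracles the
# implementation is checked against.

make_reads <- function(chrom, start, end, mapq = 60L,
                       read_length = end - start) {
  n <- length(start)
  data.frame(
    query_id = sprintf("r%04d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = as.integer(start),
    end = as.integer(end),
    mapq = rep_len(as.integer(mapq), n),
    read_length = rep_len(as.integer(read_length), n),
    is_mapped = rep(TRUE, n),
    mate_index = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}

make_intervals <- function(chrom, start, end, label) {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             label = rep_len(label, length(start)),
             strand = ".", stringsAsFactors = FALSE)
}

# Exhaustive pairwise counting oracle: for every (interval, read) pair,
# compute the half-open overlap and apply the inclusive fractional rule.
# Deliberately straight-line; independent of the package's interval code.
oracle_count <- function(reads, intervals, f) {
  counts <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    same <- reads$chrom == intervals$chrom[i] & reads$is_mapped
    ov <- pmin(reads$end, intervals$end[i]) -
      pmax(reads$start, intervals$start[i])
    hit <- same & (ov >= f * (intervals$end[i] - intervals$start[i]))
    counts[i] <- sum(hit)
  }
  counts
}

# Random counting instance on one contig.
random_instance <- function(n_reads, n_intervals, genome = 100000L,
                            f = NULL) {
  rl <- sample(30:150, 1)
  rs <- sample.int(genome - rl, n_reads, replace = TRUE)
  is <- sample.int(genome - 500L, n_intervals, replace = TRUE)
  iw <- sample(50:2000, n_intervals, replace = TRUE)
  list(
    reads = make_reads("chr1", rs, rs + rl),
    intervals = make_intervals("chr1", is, pmin(is + iw, genome),
                               sprintf("I%03d", seq_len(n_intervals))),
    f = if (is.null(f)) stats::runif(1, 0.001, 1) else f
  )
}

# Pooled-variance two-sample t oracle: closed form plus the reference
# t-distribution CDF, independent of stats::t.test.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Small two-group sample sheet (no fractions, no duplicates).
flat_sheet <- function(n_case = 3, n_control = 3, read_length = 100L) {
  ids <- c(sprintf("A%02d", seq_len(n_case)),
           sprintf("B%02d", seq_len(n_control)))
  data.frame(
    sample_id = ids,
    patient_id = ids,
    group = rep(c("case", "control"), c(n_case, n_control)),
    fraction = "bulk",
    nominal_read_length = as.integer(read_length),
    alignment_path = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Tiny annotation: two families and the four housekeeping genes.
tiny_annotation <- function() {
  ints <- rbind(
    make_intervals("chr1", c(1000, 8000), c(5000, 14000), "HERV-H"),
    make_intervals("chr1", 20000, 26000, "HERV-W"),
    make_intervals("chr2", c(1000, 10000, 20000, 30000),
                   c(6000, 16000, 25000, 34000),
                   c("SDHA", "HPRT1", "RBX1", "RRAGA"))
  )
  build_annotation(ints)
}
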