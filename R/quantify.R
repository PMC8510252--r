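#' Derive the minimum overlap fraction for a family
#'
#' The counting rule requires that about a target fraction (default 0.8) of
#' the read overlap an element. Because the counter expresses the minimum
#' overlap as a fraction `f` of the *interval* length, `f` is back-derived
#' from the read length and an assumed element length per family:
#' `f = target * read_length / assumed_length`. `f` is recomputed per
#' sample (read lengths differ across sequencing runs) and per family
#' (assumed lengths differ).
#'
#' @param target_fraction_of_read Fraction of the read required to overlap
#'   (default 0.8).
#' @param read_length Nominal read length of the sample, in bases.
#' @param assumed_length Assumed element length of the family, in bp.
#' @return An object of class `min_overlap_spec`: a list carrying the
#'   inputs and the derived fraction `f`, for the run manifest.
#' @examples
#' min_overlap_fraction(0.8, 150, 17000)$f  # ~0.00706 for HERV-H at 150 bp
#' @export
min_overlap_fraction <- function(target_fraction_of_read = 0.8,
                                 read_length, assumed_length) {
  stopifnot(target_fraction_of_read > 0, read_length > 0, assumed_length > 0)
  f <- target_fraction_of_read * read_length / assumed_length
  if (f > 1) {
    stop("required overlap exceeds the element: f = ", signif(f, 4),
         " > 1 (target ", target_fraction_of_read, ", read length ",
         read_length, ", assumed length ", assumed_length, ")")
  }
  structure(
    list(target_fraction_of_read = target_fraction_of_read,
         read_length = read_length,
         assumed_length = assumed_length,
         f = f),
    class = "min_overlap_spec"
  )
}

# Count reads per interval given a per-interval required overlap in bp.
# Overlap is computed on half-open spans; the comparison is inclusive (>=)
# on the exact (possibly fractional) requirement, with no rounding. A read
# may be counted for several intervals; mates count independently.
.count_with_required <- function(reads, intervals, required_bp) {
  n_int <- nrow(intervals)
  counts <- integer(n_int)
  if (n_int == 0L || nrow(reads) == 0L) return(counts)
  reads <- reads[reads$is_mapped & reads$chrom %in% unique(intervals$chrom), ,
                 drop = FALSE]
  if (nrow(reads) == 0L) return(counts)
  ig <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  rg <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(reads$start + 1L, reads$end)
  )
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(ig, rg)
  })
  if (length(hits) == 0L) return(counts)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(intervals$end[qi], reads$end[si]) -
    pmax(intervals$start[qi], reads$start[si])
  keep <- ov >= required_bp[qi]
  tabulate(qi[keep], nbins = n_int)
}

#' Count reads per interval under a minimum-overlap rule
#'
#' A read is counted for an interval when its overlap (in bp, on the
#' half-open spans) is at least `f` times the interval length. The
#' comparison is inclusive and made on the exact product, without integer
#' rounding. A read may be counted for multiple intervals, and each mate of
#' a pair counts independently.
#'
#' @param reads Alignment data frame (already MAPQ-filtered).
#' @param intervals Interval data frame (`chrom`, `start`, `end`, `label`).
#' @param spec A `min_overlap_spec` from [min_overlap_fraction()], or a
#'   bare numeric fraction `f`.
#' @return Integer vector of counts, one per interval row.
#' @export
count_reads_per_interval <- function(reads, intervals, spec) {
  f <- if (inherits(spec, "min_overlap_spec")) spec$f else as.numeric(spec)
  stopifnot(f > 0, f <= 1)
  if (nrow(intervals) > 0L && nrow(reads) > 0L &&
      !any(reads$chrom %in% unique(intervals$chrom))) {
    warning("no shared contigs between reads and intervals; ",
            "all counts are zero")
  }
  required <- f * (intervals$end - intervals$start)
  .count_with_required(reads, intervals, required)
}

#' Sum per-interval counts into per-feature totals
#'
#' @param counts Integer vector of per-interval counts.
#' @param labels Character vector of interval labels, parallel to `counts`.
#' @param features Feature names the result must cover (absent features get
#'   0); unknown labels are an error.
#' @return Named integer vector of per-feature raw-count sums.
#' @export
aggregate_family_counts <- function(counts, labels, features = unique(labels)) {
  stopifnot(length(counts) == length(labels))
  unknown <- setdiff(unique(labels), features)
  if (length(unknown) > 0L) {
    stop("interval label not in the annotation: ",
         paste(unknown, collapse = ", "))
  }
  out <- stats::setNames(integer(length(features)), features)
  if (length(counts) > 0L) {
    sums <- tapply(counts, factor(labels, levels = features), sum)
    sums[is.na(sums)] <- 0L
    out[names(sums)] <- as.integer(sums)
  }
  out
}

#' Count a sample's reads against a family annotation
#'
#' Applies the per-family minimum-overlap rule and sums per-interval counts
#' to per-feature totals. HERV families use `f = target * read_length /
#' assumed_length`; housekeeping genes are counted the same way with each
#' interval's own length as the assumed length, so their required overlap
#' is exactly `target * read_length`.
#'
#' @param reads Alignment data frame, already MAPQ-filtered.
#' @param annotation `herv_annotation` from [build_annotation()].
#' @param read_length Nominal read length of the sample (bases).
#' @param target_fraction Fraction of the read required to overlap
#'   (default 0.8).
#' @return Named integer vector over `c(families, housekeeping)`, with the
#'   per-family `f` values attached as attribute `"f"`.
#' @export
count_sample <- function(reads, annotation, read_length,
                         target_fraction = 0.8) {
  stopifnot(inherits(annotation, "herv_annotation"))
  ints <- annotation$intervals
  features <- c(annotation$families, annotation$housekeeping)
  if (nrow(reads) > 0L && !any(reads$chrom %in% unique(ints$chrom))) {
    warning("no shared contigs between reads and the annotation; ",
            "all counts are zero")
  }
  out <- stats::setNames(integer(length(features)), features)
  fvals <- stats::setNames(numeric(length(features)), features)
  for (fam in annotation$families) {
    sub <- ints[ints$label == fam, , drop = FALSE]
    spec <- min_overlap_fraction(target_fraction, read_length,
                                 annotation$assumed_lengths[[fam]])
    fvals[[fam]] <- spec$f
    required <- spec$f * (sub$end - sub$start)
    out[[fam]] <- sum(.count_with_required(reads, sub, required))
  }
  for (gene in annotation$housekeeping) {
    sub <- ints[ints$label == gene, , drop = FALSE]
    lens <- sub$end - sub$start
    if (any(target_fraction * read_length > lens)) {
      stop("required overlap exceeds the annotated length of ", gene)
    }
    required <- rep(target_fraction * read_length, nrow(sub))
    fvals[[gene]] <- NA_real_
    out[[gene]] <- sum(.count_with_required(reads, sub, required))
  }
  attr(out, "f") <- fvals
  out
}

#' Build the raw count table for a study
#'
#' Reads each sample's alignments, applies the MAPQ filter, and counts
#' against the annotation, producing the samples-by-features table of raw
#' read counts.
#'
#' @param sheet Sample-sheet data frame from [parse_sample_sheet()].
#' @param annotation `herv_annotation`.
#' @param target_fraction Fraction of the read required to overlap
#'   (default 0.8).
#' @param mapq_threshold Minimum mapping quality (default 20).
#' @param strict_mapq Use strictly-greater-than MAPQ semantics?
#' @param reads_list Optional named list of pre-loaded alignment data
#'   frames (by `sample_id`), bypassing file I/O.
#' @return Integer matrix (samples x features) with the per-sample,
#'   per-family `f` values attached as attribute `"f_table"`.
#' @export
count_table <- function(sheet, annotation, target_fraction = 0.8,
                        mapq_threshold = 20, strict_mapq = FALSE,
                        reads_list = NULL) {
  features <- c(annotation$families, annotation$housekeeping)
  mat <- matrix(0L, nrow = nrow(sheet), ncol = length(features),
                dimnames = list(sheet$sample_id, features))
  f_table <- matrix(NA_real_, nrow = nrow(sheet), ncol = length(features),
                    dimnames = list(sheet$sample_id, features))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    reads <- if (!is.null(reads_list)) reads_list[[sid]]
             else read_alignments(sheet$alignment_path[i])
    reads <- filter_mapq(reads, mapq_threshold, strict = strict_mapq)
    row <- count_sample(reads, annotation,
                        read_length = sheet$nominal_read_length[i],
                        target_fraction = target_fraction)
    mat[i, ] <- row
    f_table[i, ] <- attr(row, "f")
  }
  attr(mat, "f_table") <- f_table
  mat
}

#' Write a count table as TSV
#'
#' @param counts Samples-by-features integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path.
#' @return Samples-by-features integer matrix.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  storage.mode(mat) <- "integer"
  mat
}
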