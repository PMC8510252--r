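#' Read alignment records from a SAM or BAM file
#'
#' Loads alignments into a minimal record table. Positions are converted
#' from SAM's 1-based inclusive coordinates to the internal 0-based
#' half-open convention shared with the BED annotations: `start` is
#' `POS - 1` and `end = start + reference width`, where the reference width
#' is the reference-consuming CIGAR length (soft clips do not extend the
#' span). `read_length` is the full query length including soft-clipped
#' bases. Each mate of a paired read yields its own record.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file with a header.
#' @param include_secondary Keep secondary/supplementary alignments?
#'   Default `FALSE`, avoiding double counting of multi-part alignments.
#' @return A data frame with one row per record: `query_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `mapq`, `read_length`,
#'   `is_mapped`, `mate_index` (1, 2 or `NA` for unpaired).
#' @export
read_alignments <- function(path, include_secondary = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("not a valid SAM file (", path, "): ",
                               conditionMessage(e))
    )
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (include_secondary) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "qwidth"),
    flag = flags
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  is_mapped <- bitwAnd(flag, 4L) == 0L & !is.na(res$pos)
  ref_width <- rep(0L, length(flag))
  qlen <- res$qwidth
  if (any(is_mapped)) {
    cig <- res$cigar[is_mapped]
    ref_width[is_mapped] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
    qlen[is_mapped] <- GenomicAlignments::cigarWidthAlongQuerySpace(
      cig, after.soft.clipping = FALSE)
  }
  start <- ifelse(is_mapped, res$pos - 1L, NA_integer_)
  mate <- rep(NA_integer_, length(flag))
  paired <- bitwAnd(flag, 1L) != 0L
  mate[paired & bitwAnd(flag, 64L) != 0L] <- 1L
  mate[paired & bitwAnd(flag, 128L) != 0L] <- 2L
  data.frame(
    query_id = res$qname,
    chrom = as.character(res$rname),
    start = start,
    end = start + ref_width,
    mapq = as.integer(res$mapq),
    read_length = as.integer(qlen),
    is_mapped = is_mapped,
    mate_index = mate,
    stringsAsFactors = FALSE
  )
}

#' Filter alignments by mapping quality
#'
#' Keeps mapped records whose MAPQ is at or above the threshold. The
#' default threshold of 20 matches `samtools view -q 20` semantics
#' (inclusive); set `strict = TRUE` for a strictly-greater-than cut.
#'
#' @param reads Alignment data frame from [read_alignments()].
#' @param threshold Minimum mapping quality (default 20).
#' @param strict If `TRUE`, require `mapq > threshold` instead of `>=`.
#' @return The filtered data frame.
#' @export
filter_mapq <- function(reads, threshold = 20, strict = FALSE) {
  stopifnot(threshold >= 0)
  mq <- reads$mapq
  keep <- reads$is_mapped & !is.na(mq) &
    (if (strict) mq > threshold else mq >= threshold)
  reads[keep, , drop = FALSE]
}

#' Write alignment records as a SAM file
#'
#' Serializes the internal record table back to SAM text (header plus one
#' line per record). Coordinates are converted back to SAM's 1-based
#' convention; records carry SEQ/QUAL `*` and a fully-matching CIGAR over
#' the aligned span, which is sufficient for counting-oriented use.
#'
#' @param reads Alignment data frame (`query_id`, `chrom`, `start`, `end`,
#'   `mapq`, `read_length`, `is_mapped`, optionally `mate_index`).
#' @param contigs Data frame with columns `name` and `length` describing
#'   the reference sequences for the `@SQ` header lines.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contigs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name,
                      as.integer(contigs$length)))
  n <- nrow(reads)
  if (n > 0L) {
    mate <- if ("mate_index" %in% names(reads)) reads$mate_index
            else rep(NA_integer_, n)
    flag <- integer(n)
    flag[!reads$is_mapped] <- 4L
    flag[!is.na(mate) & mate == 1L] <- bitwOr(flag[!is.na(mate) & mate == 1L], 65L)
    flag[!is.na(mate) & mate == 2L] <- bitwOr(flag[!is.na(mate) & mate == 2L], 129L)
    pos <- ifelse(reads$is_mapped, reads$start + 1L, 0L)
    rname <- ifelse(reads$is_mapped, reads$chrom, "*")
    cigar <- ifelse(reads$is_mapped,
                    sprintf("%dM", reads$end - reads$start), "*")
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                    reads$query_id, flag, rname, as.integer(pos),
                    as.integer(reads$mapq), cigar)
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
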