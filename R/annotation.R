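#' Default assumed element lengths per HERV family
#'
#' Assumed full-length element sizes (bp) used to derive the minimum
#' overlap fraction passed to the counter. The values are chosen close to
#' the longest elements of each family so that reads aligned within long
#' proviruses are still detected: 9,000 bp for HML-3, HML-5 and HML-6,
#' 10,000 bp for HML-1, HML-2, HML-4, HERV-W, ERV-L, HERV-E, HERV-I and
#' HERV-FRD, 12,000 bp for HERV-9, and 17,000 bp for HERV-H.
#'
#' @return Named numeric vector of element lengths in bp, one entry per
#'   HERV family.
#' @export
default_assumed_lengths <- function() {
  c(
    "HML-1"    = 10000,
    "HML-2"    = 10000,
    "HML-3"    = 9000,
    "HML-4"    = 10000,
    "HML-5"    = 9000,
    "HML-6"    = 9000,
    "HERV-W"   = 10000,
    "HERV-H"   = 17000,
    "HERV-9"   = 12000,
    "ERV-L"    = 10000,
    "HERV-I"   = 10000,
    "HERV-FRD" = 10000,
    "HERV-E"   = 10000
  )
}

#' Housekeeping genes used as normalization denominators
#'
#' @return Character vector of the four housekeeping gene symbols.
#' @export
housekeeping_genes <- function() {
  c("SDHA", "HPRT1", "RBX1", "RRAGA")
}

#' Parse a BED file of genomic intervals
#'
#' Reads BED4/BED6 records into a data frame of 0-based half-open
#' intervals. Coordinates are kept verbatim (no 1-based shift): `start` is
#' the 0-based inclusive start and `end` the 0-based exclusive end, exactly
#' as stored in the file.
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, start, end, name); column 6, when present, is the strand.
#' @return A data frame with columns `chrom`, `start`, `end`, `label`,
#'   `strand` (`"."` when absent), one row per interval in file order.
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- idx[which(nf < 4L)[1L]]
    stop("malformed BED line ", bad, ": fewer than 4 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed BED line ", bad, ": non-integer coordinate")
  }
  if (any(start < 0L)) {
    bad <- idx[which(start < 0L)[1L]]
    stop("invalid BED line ", bad, ": negative start")
  }
  if (any(start >= end)) {
    bad <- idx[which(start >= end)[1L]]
    stop("invalid BED line ", bad, ": start >= end")
  }
  label <- vapply(fields, `[[`, "", 4L)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(chrom = chrom, start = start, end = end, label = label,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals to a BED file
#'
#' Inverse of [parse_bed()]: writes 0-based half-open intervals verbatim as
#' BED6 so that parse -> write -> parse is the identity.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`,
#'   `label` and optionally `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(intervals)))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$label, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Build a family annotation set from intervals
#'
#' Groups intervals by their `label` column into per-family coordinate
#' sets, attaching the assumed element length used to derive the minimum
#' overlap fraction. Housekeeping genes are annotated the same way but use
#' each interval's own length as its assumed length, so that the required
#' overlap works out to exactly the target fraction of the read length.
#'
#' @param intervals Data frame as returned by [parse_bed()]; may mix HERV
#'   families and housekeeping genes in one file.
#' @param assumed_lengths Named numeric vector mapping each family label to
#'   its assumed element length in bp; defaults to
#'   [default_assumed_lengths()].
#' @param housekeeping Character vector of labels to treat as housekeeping
#'   genes; defaults to [housekeeping_genes()].
#' @return An object of class `herv_annotation`: a list with elements
#'   `intervals` (the input data frame), `families`, `housekeeping`, and
#'   `assumed_lengths` (per family; `NA` for housekeeping genes, whose
#'   per-interval lengths are used instead).
#' @export
build_annotation <- function(intervals,
                             assumed_lengths = default_assumed_lengths(),
                             housekeeping = housekeeping_genes()) {
  labels <- unique(intervals$label)
  hk <- intersect(housekeeping, labels)
  fams <- setdiff(labels, hk)
  missing <- setdiff(fams, names(assumed_lengths))
  if (length(missing) > 0L) {
    stop("no assumed element length for family: ",
         paste(missing, collapse = ", "))
  }
  if (any(assumed_lengths[fams] <= 0)) {
    stop("assumed element lengths must be positive")
  }
  structure(
    list(intervals = intervals,
         families = fams,
         housekeeping = hk,
         assumed_lengths = assumed_lengths[fams]),
    class = "herv_annotation"
  )
}

#' @export
print.herv_annotation <- function(x, ...) {
  cat("herv_annotation:", length(x$families), "families,",
      length(x$housekeeping), "housekeeping genes,",
      nrow(x$intervals), "intervals\n")
  invisible(x)
}

#' Read an assumed-length table from YAML or TSV
#'
#' @param path YAML file of `family: length` pairs, or a two-column TSV
#'   with header `family<TAB>assumed_length`.
#' @return Named numeric vector of assumed lengths (bp).
#' @export
read_assumed_lengths <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    x <- yaml::read_yaml(path)
    out <- vapply(x, as.numeric, numeric(1))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("family", "assumed_length") %in% names(tab)))
    out <- stats::setNames(as.numeric(tab$assumed_length), tab$family)
  }
  if (any(out <= 0)) stop("assumed lengths must be positive")
  out
}
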