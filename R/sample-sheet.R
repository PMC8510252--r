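#' Parse a sample sheet
#'
#' The sample sheet is a TSV with header columns `sample_id`, `patient_id`,
#' `group`, `fraction`, `nominal_read_length`, `alignment_path`. It encodes
#' the study structure the downstream stages rely on: samples sharing a
#' `patient_id` are biological duplicates to be averaged, and `CD3pos` /
#' `CD3neg` rows of one patient are cell fractions to be pooled at the
#' raw-count level.
#'
#' @param path Path to the TSV sheet.
#' @return Data frame of validated sample rows, in file order, with an
#'   additional logical attribute check performed: unique sample ids and
#'   known `group` / `fraction` tokens.
#' @export
parse_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  required <- c("sample_id", "patient_id", "group", "fraction",
                "nominal_read_length", "alignment_path")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  sheet$nominal_read_length <- as.integer(sheet$nominal_read_length)
  validate_sample_sheet(sheet)
  sheet
}

#' Validate a sample-sheet data frame
#'
#' @param sheet Data frame with the sample-sheet columns.
#' @return `sheet`, invisibly; stops on violation.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) {
    dup <- sheet$sample_id[duplicated(sheet$sample_id)][1L]
    stop("duplicate sample_id in sheet: ", dup)
  }
  bad_group <- setdiff(unique(sheet$group), c("case", "control"))
  if (length(bad_group) > 0L) {
    stop("unknown group token: ", paste(bad_group, collapse = ", "),
         " (expected case/control)")
  }
  bad_frac <- setdiff(unique(sheet$fraction), c("bulk", "CD3pos", "CD3neg"))
  if (length(bad_frac) > 0L) {
    stop("unknown fraction token: ", paste(bad_frac, collapse = ", "),
         " (expected bulk/CD3pos/CD3neg)")
  }
  if (any(is.na(sheet$nominal_read_length)) ||
      any(sheet$nominal_read_length <= 0L)) {
    stop("nominal_read_length must be a positive integer for every sample")
  }
  # a patient must not mix groups
  grp <- tapply(sheet$group, sheet$patient_id,
                function(g) length(unique(g)))
  if (any(grp > 1L)) {
    stop("patient assigned to more than one group: ",
         names(grp)[grp > 1L][1L])
  }
  invisible(sheet)
}

#' Write a sample sheet TSV
#'
#' @param sheet Sample-sheet data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
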