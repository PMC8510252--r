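#' Fold change between case and control groups
#'
#' Ratio of the arithmetic mean normalized expression value in the case
#' group to that in the control group, on the natural (un-logged) scale.
#'
#' @param case_nev Numeric vector of case-unit NEVs.
#' @param control_nev Numeric vector of control-unit NEVs; mean must be
#'   positive.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(case_nev, control_nev) {
  if (length(case_nev) == 0L || length(control_nev) == 0L) {
    stop("both groups must be non-empty")
  }
  m <- mean(control_nev)
  if (m <= 0) stop("control group mean is not positive")
  mean(case_nev) / m
}

#' Per-unit heterogeneity ratios
#'
#' Each case unit's NEV divided by the control-group mean NEV — the
#' measure of between-dataset heterogeneity in the size of the effect. The
#' mean of these ratios equals the fold change.
#'
#' @inheritParams fold_change
#' @return Named numeric vector, one ratio per case unit.
#' @export
heterogeneity_ratios <- function(case_nev, control_nev) {
  m <- mean(control_nev)
  if (m <= 0) stop("control group mean is not positive")
  case_nev / m
}

#' Two-sided t-test on ln-transformed expression values
#'
#' NEVs are log-transformed (`ln(NEV)`) and compared with an
#' independent-samples t-test: Student's pooled-variance test by default
#' (`df = n1 + n2 - 2`), or Welch's unequal-variance test when
#' `variance_mode = "welch"`.
#'
#' @inheritParams fold_change
#' @param variance_mode `"student"` (pooled variance, default) or
#'   `"welch"`.
#' @return A list with `t`, `df` and the two-sided `p`.
#' @export
ln_t_test <- function(case_nev, control_nev,
                      variance_mode = c("student", "welch")) {
  variance_mode <- match.arg(variance_mode)
  if (any(case_nev <= 0) || any(control_nev <= 0)) {
    stop("NEVs must be positive for the ln transform")
  }
  if (length(case_nev) < 2L || length(control_nev) < 2L) {
    stop("each group needs at least 2 units for the t-test")
  }
  x <- log(case_nev)
  y <- log(control_nev)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) stop("degenerate input: both groups constant and equal")
  }
  res <- stats::t.test(x, y, var.equal = (variance_mode == "student"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Compare case and control NEVs for every family
#'
#' @param nev `herv_nev` from [normalize_expression()].
#' @param variance_mode Passed to [ln_t_test()].
#' @return Data frame with one row per family: `family`, `fold_change`,
#'   `t`, `df`, `p`, and the per-case-unit heterogeneity ratios as a list
#'   column `heterogeneity`.
#' @export
differential_table <- function(nev, variance_mode = c("student", "welch")) {
  variance_mode <- match.arg(variance_mode)
  is_case <- nev$units$group == "case"
  fams <- colnames(nev$combined)
  out <- data.frame(family = fams, fold_change = NA_real_,
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  het <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    ca <- nev$combined[is_case, fams[k]]
    co <- nev$combined[!is_case, fams[k]]
    out$fold_change[k] <- fold_change(ca, co)
    tt <- ln_t_test(ca, co, variance_mode)
    out$t[k] <- tt$t
    out$df[k] <- tt$df
    out$p[k] <- tt$p
    het[[k]] <- heterogeneity_ratios(ca, co)
  }
  out$heterogeneity <- het
  out
}

#' Run the sensitivity-analysis grid
#'
#' Produces one result row per family and analysis mode, mirroring the
#' published sensitivity-table layout: the main analysis (median-combined
#' NEVs per patient), one analysis per housekeeping gene (per patient),
#' and the per-data-set analysis (median combiner, duplicates not
#' averaged). A Benjamini-Hochberg adjusted p-value column is attached as
#' supplementary output; it gates nothing.
#'
#' @param counts Samples-by-features matrix from [count_table()].
#' @param sheet Sample-sheet data frame.
#' @param annotation `herv_annotation`.
#' @param variance_mode Passed to [ln_t_test()].
#' @param per_dataset Include the per-data-set row? Default `TRUE`.
#' @return Data frame with columns `analysis`, `unit`, `combiner`,
#'   `family`, `fold_change`, `t`, `df`, `p`, `p_bh`.
#' @export
run_sensitivity_grid <- function(counts, sheet, annotation,
                                 variance_mode = c("student", "welch"),
                                 per_dataset = TRUE) {
  variance_mode <- match.arg(variance_mode)
  modes <- list(list(analysis = "Main analysis", unit = "patient",
                     combiner = "median"))
  for (g in annotation$housekeeping) {
    modes <- c(modes, list(list(
      analysis = paste(g, "analysis per patient"),
      unit = "patient", combiner = g)))
  }
  if (per_dataset) {
    modes <- c(modes, list(list(analysis = "Analysis per data set",
                                unit = "dataset", combiner = "median")))
  }
  rows <- lapply(modes, function(m) {
    nev <- normalize_expression(counts, sheet, annotation,
                                unit = m$unit, combiner = m$combiner)
    d <- differential_table(nev, variance_mode)
    d$heterogeneity <- NULL
    cbind(data.frame(analysis = m$analysis, unit = m$unit,
                     combiner = m$combiner, stringsAsFactors = FALSE),
          d)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::ave(out$p, out$analysis,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

#' Write a differential / sensitivity table as TSV
#'
#' @param grid Data frame from [run_sensitivity_grid()] or
#'   [differential_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(grid, path) {
  grid$heterogeneity <- NULL
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
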