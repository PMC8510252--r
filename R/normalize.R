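#' Pool CD3+/CD3- cell fractions at the raw-count level
#'
#' For patients whose sample was sequenced as separate CD3+ and CD3- cell
#' fractions, the two fractions' raw read counts (HERV families and
#' housekeeping genes alike) are summed cell-wise into one dataset before
#' any ratio is formed. Bulk samples pass through unchanged, one dataset
#' per sample; biological duplicates remain separate datasets here and are
#' only averaged later, after normalization.
#'
#' @param counts Samples-by-features integer matrix from [count_table()].
#' @param sheet Sample-sheet data frame.
#' @return A list with `counts` (datasets-by-features matrix) and
#'   `datasets` (data frame `dataset_id`, `patient_id`, `group`).
#' @export
pool_cell_fractions <- function(counts, sheet) {
  stopifnot(all(sheet$sample_id %in% rownames(counts)))
  rows <- list()
  meta <- list()
  for (pid in unique(sheet$patient_id)) {
    sub <- sheet[sheet$patient_id == pid, , drop = FALSE]
    bulk <- sub[sub$fraction == "bulk", , drop = FALSE]
    pos <- sub[sub$fraction == "CD3pos", , drop = FALSE]
    neg <- sub[sub$fraction == "CD3neg", , drop = FALSE]
    if (nrow(pos) != nrow(neg)) {
      miss <- if (nrow(pos) > nrow(neg)) "CD3neg" else "CD3pos"
      stop("patient ", pid, " has an unmatched cell fraction (missing ",
           miss, ")")
    }
    for (j in seq_len(nrow(bulk))) {
      did <- bulk$sample_id[j]
      rows[[did]] <- counts[bulk$sample_id[j], ]
      meta[[did]] <- data.frame(dataset_id = did, patient_id = pid,
                                group = bulk$group[j],
                                stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(pos))) {
      did <- if (nrow(pos) == 1L) paste0(pid, ".pooled")
             else paste0(pid, ".pooled", j)
      rows[[did]] <- counts[pos$sample_id[j], ] + counts[neg$sample_id[j], ]
      meta[[did]] <- data.frame(dataset_id = did, patient_id = pid,
                                group = pos$group[j],
                                stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  storage.mode(mat) <- "integer"
  list(counts = mat, datasets = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Normalize family counts by housekeeping-gene counts
#'
#' Forms the per-gene normalized expression ratios: each family's raw-count
#' sum divided by each housekeeping gene's raw-count total in the same
#' dataset ("HERV reads per housekeeping gene reads").
#'
#' @param family_counts Named numeric vector of family raw counts (one
#'   dataset).
#' @param hk_counts Named numeric vector of housekeeping-gene raw counts;
#'   all must be positive (a zero aborts unless `pseudocount > 0`).
#' @param pseudocount Value added to every count before division; 0 (off)
#'   by default.
#' @return Numeric matrix `families x genes` of dimensionless ratios.
#' @export
normalize_counts <- function(family_counts, hk_counts, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  fc <- family_counts + pseudocount
  hk <- hk_counts + pseudocount
  if (any(hk <= 0)) {
    stop("housekeeping gene with zero reads: ",
         paste(names(hk_counts)[hk <= 0], collapse = ", "),
         " (enable a pseudocount explicitly to proceed)")
  }
  outer(fc, hk, `/`)
}

#' Average biological duplicates per patient
#'
#' Averages each per-gene normalized ratio arithmetically across the
#' datasets belonging to one patient, *before* the median combination
#' across housekeeping genes.
#'
#' @param ratios 3-d array `datasets x families x genes` of per-gene
#'   ratios.
#' @param dataset_patient Character vector mapping each dataset (row of
#'   `ratios`) to its patient id.
#' @return 3-d array `patients x families x genes`.
#' @export
average_duplicates <- function(ratios, dataset_patient) {
  stopifnot(length(dataset_patient) == dim(ratios)[1])
  patients <- unique(dataset_patient)
  out <- array(NA_real_,
               dim = c(length(patients), dim(ratios)[2], dim(ratios)[3]),
               dimnames = c(list(patients), dimnames(ratios)[2:3]))
  for (p in patients) {
    idx <- which(dataset_patient == p)
    sub <- ratios[idx, , , drop = FALSE]
    out[p, , ] <- apply(sub, c(2, 3), mean)
  }
  out
}

#' Combine per-gene ratios into one normalized expression value
#'
#' The combined normalized expression value (NEV) is the median of the
#' per-housekeeping-gene ratios; with the four genes of the standard
#' panel this is the mean of the two middle ratios.
#'
#' @param per_gene_ratio Numeric vector of per-gene ratios for one unit
#'   and family (length >= 1).
#' @return The median ratio.
#' @export
median_combine <- function(per_gene_ratio) {
  x <- per_gene_ratio[!is.na(per_gene_ratio)]
  if (length(x) == 0L) stop("no per-gene ratios to combine")
  stats::median(x)
}

#' Compute normalized expression values for a study
#'
#' Runs the normalization chain in its fixed order: pool CD3+/CD3- cell
#' fractions (raw counts), form per-housekeeping-gene ratios per dataset,
#' average biological duplicates per patient (skipped in `unit =
#' "dataset"` mode), then combine across genes.
#'
#' @param counts Samples-by-features matrix from [count_table()].
#' @param sheet Sample-sheet data frame.
#' @param annotation `herv_annotation` (names the families and genes).
#' @param unit Analysis unit: `"patient"` (duplicates averaged; the main
#'   analysis) or `"dataset"` (each dataset kept separate; the
#'   per-data-set sensitivity analysis).
#' @param combiner `"median"` (default) or the name of a single
#'   housekeeping gene for the per-gene sensitivity analyses.
#' @param pseudocount Passed to [normalize_counts()]; 0 by default.
#' @return A list of class `herv_nev`: `units` (data frame `unit_id`,
#'   `group`), `per_gene` (array `units x families x genes`), `combined`
#'   (matrix `units x families`), `unit`, `combiner`.
#' @export
normalize_expression <- function(counts, sheet, annotation,
                                 unit = c("patient", "dataset"),
                                 combiner = "median", pseudocount = 0) {
  unit <- match.arg(unit)
  genes <- annotation$housekeeping
  fams <- annotation$families
  if (!identical(combiner, "median") && !combiner %in% genes) {
    stop("combiner must be \"median\" or one of: ",
         paste(genes, collapse = ", "))
  }
  pooled <- pool_cell_fractions(counts, sheet)
  dsets <- pooled$datasets
  ratios <- array(NA_real_,
                  dim = c(nrow(dsets), length(fams), length(genes)),
                  dimnames = list(dsets$dataset_id, fams, genes))
  for (i in seq_len(nrow(dsets))) {
    ratios[i, , ] <- normalize_counts(pooled$counts[i, fams],
                                      pooled$counts[i, genes],
                                      pseudocount = pseudocount)
  }
  if (unit == "patient") {
    ratios <- average_duplicates(ratios, dsets$patient_id)
    units <- unique(dsets[, c("patient_id", "group")])
    units <- data.frame(unit_id = units$patient_id, group = units$group,
                        stringsAsFactors = FALSE)
    ratios <- ratios[units$unit_id, , , drop = FALSE]
  } else {
    units <- data.frame(unit_id = dsets$dataset_id, group = dsets$group,
                        stringsAsFactors = FALSE)
  }
  combined <- if (identical(combiner, "median")) {
    apply(ratios, c(1, 2), median_combine)
  } else {
    ratios[, , combiner, drop = TRUE]
  }
  combined <- matrix(combined, nrow = nrow(units),
                     dimnames = list(units$unit_id, fams))
  structure(
    list(units = units, per_gene = ratios, combined = combined,
         unit = unit, combiner = combiner),
    class = "herv_nev"
  )
}

#' @export
print.herv_nev <- function(x, ...) {
  cat("herv_nev:", nrow(x$units), "units x", ncol(x$combined),
      "families; unit =", x$unit, "; combiner =", x$combiner, "\n")
  invisible(x)
}

#' Write normalized expression values as TSV
#'
#' One row per unit and family, with one column per housekeeping gene and
#' the combined (median) column.
#'
#' @param nev `herv_nev` from [normalize_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nev_table <- function(nev, path) {
  genes <- dimnames(nev$per_gene)[[3]]
  rows <- expand.grid(unit_id = nev$units$unit_id,
                      family = colnames(nev$combined),
                      stringsAsFactors = FALSE)
  df <- rows
  df$group <- nev$units$group[match(rows$unit_id, nev$units$unit_id)]
  for (g in genes) {
    df[[g]] <- mapply(function(u, fam) nev$per_gene[u, fam, g],
                      rows$unit_id, rows$family)
  }
  df$combined <- mapply(function(u, fam) nev$combined[u, fam],
                        rows$unit_id, rows$family)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
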