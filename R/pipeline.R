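#' Run the full expression-analysis pipeline
#'
#' Orchestrates the stages end to end: parse inputs, MAPQ-filter and count
#' reads per family under the minimum-overlap rule, normalize to
#' housekeeping-gene ratios (pool cell fractions, average duplicates,
#' median-combine), and compute the differential / sensitivity grid. All
#' stage outputs are written as TSV next to a run manifest that records
#' the parameters, operation order and input digests needed to reproduce
#' the run.
#'
#' @param sample_sheet Path to the sample-sheet TSV.
#' @param bed Path to the annotation BED (HERV family loci and
#'   housekeeping genes in one file, grouped by the name column).
#' @param out_dir Output directory (created if needed).
#' @param assumed_lengths Named vector of per-family assumed element
#'   lengths, or a path to a YAML/TSV table; defaults to
#'   [default_assumed_lengths()].
#' @param target_fraction Fraction of the read required to overlap
#'   (default 0.8).
#' @param mapq_threshold Minimum mapping quality (default 20).
#' @param strict_mapq Strictly-greater-than MAPQ semantics? Default
#'   `FALSE` (samtools `-q` inclusive semantics).
#' @param variance_mode `"student"` (default) or `"welch"` t-test.
#' @param housekeeping Housekeeping gene labels; defaults to
#'   [housekeeping_genes()].
#' @return Invisibly, a list with the count matrix, the main-analysis
#'   `herv_nev`, the sensitivity grid and the manifest.
#' @export
run_pipeline <- function(sample_sheet, bed, out_dir,
                         assumed_lengths = default_assumed_lengths(),
                         target_fraction = 0.8, mapq_threshold = 20,
                         strict_mapq = FALSE,
                         variance_mode = c("student", "welch"),
                         housekeeping = housekeeping_genes()) {
  variance_mode <- match.arg(variance_mode)
  if (is.character(assumed_lengths) && length(assumed_lengths) == 1L &&
      file.exists(assumed_lengths)) {
    assumed_lengths <- read_assumed_lengths(assumed_lengths)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sheet <- stage("parse_sample_sheet", parse_sample_sheet(sample_sheet))
  intervals <- stage("parse_bed", parse_bed(bed))
  annotation <- stage("build_annotation",
                      build_annotation(intervals, assumed_lengths,
                                       housekeeping))

  counts <- stage("count", count_table(sheet, annotation,
                                       target_fraction = target_fraction,
                                       mapq_threshold = mapq_threshold,
                                       strict_mapq = strict_mapq))
  write_count_table(counts, file.path(out_dir, "counts.tsv"))

  nev_main <- stage("normalize",
                    normalize_expression(counts, sheet, annotation,
                                         unit = "patient",
                                         combiner = "median"))
  write_nev_table(nev_main, file.path(out_dir, "nev_patient.tsv"))
  nev_dataset <- stage("normalize",
                       normalize_expression(counts, sheet, annotation,
                                            unit = "dataset",
                                            combiner = "median"))
  write_nev_table(nev_dataset, file.path(out_dir, "nev_dataset.tsv"))

  grid <- stage("differential",
                run_sensitivity_grid(counts, sheet, annotation,
                                     variance_mode = variance_mode))
  write_differential_table(grid, file.path(out_dir, "differential.tsv"))

  het <- stage("heterogeneity", {
    d <- differential_table(nev_main, variance_mode)
    do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
      r <- d$heterogeneity[[k]]
      data.frame(family = d$family[k], unit_id = names(r),
                 heterogeneity_ratio = unname(r),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(het, file.path(out_dir, "heterogeneity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- build_manifest(sheet, bed, sample_sheet, counts,
                             target_fraction, mapq_threshold, strict_mapq,
                             variance_mode, assumed_lengths)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(counts = counts, nev = nev_main, grid = grid,
                 heterogeneity = het, manifest = manifest,
                 out_dir = out_dir))
}

# Record everything needed to re-run the identical analysis.
build_manifest <- function(sheet, bed, sample_sheet, counts,
                           target_fraction, mapq_threshold, strict_mapq,
                           variance_mode, assumed_lengths) {
  f_table <- attr(counts, "f_table")
  fam_cols <- colnames(f_table)[!is.na(f_table[1, ])]
  list(
    tool = "hervfam",
    version = as.character(utils::packageVersion("hervfam")),
    parameters = list(
      target_fraction = target_fraction,
      mapq_threshold = mapq_threshold,
      mapq_semantics = if (strict_mapq) "greater-than" else
        "greater-or-equal",
      variance_mode = variance_mode,
      assumed_lengths = as.list(assumed_lengths)
    ),
    operation_order = c("pool_cell_fractions", "normalize_counts",
                        "average_duplicates", "median_combine"),
    min_overlap_fractions = lapply(
      stats::setNames(seq_len(nrow(f_table)), rownames(f_table)),
      function(i) as.list(round(f_table[i, fam_cols], 8))
    ),
    inputs = list(
      sample_sheet = list(path = sample_sheet,
                          md5 = unname(tools::md5sum(sample_sheet))),
      bed = list(path = bed, md5 = unname(tools::md5sum(bed))),
      alignments = lapply(
        stats::setNames(seq_len(nrow(sheet)), sheet$sample_id),
        function(i) list(path = sheet$alignment_path[i],
                         md5 = unname(tools::md5sum(
                           sheet$alignment_path[i]))))
    )
  )
}
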