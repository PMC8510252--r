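#' Build a simulation configuration
#'
#' Defines a seeded toy study: a compact reference with non-overlapping
#' HERV family loci and housekeeping genes, and a sample design mirroring
#' one of three study profiles:
#'
#' * `"BALF"` — 7 case patients (3 with biological duplicates, one of the
#'   duplicate pairs mixing 76 bp and 100 bp reads, 3 patients sequenced
#'   as paired CD3+/CD3- cell fractions at 150 bp) versus 3 bulk controls
#'   at 50 bp.
#' * `"PBMC"` — 3 cases (100 bp) versus 3 controls (one 100 bp,
#'   two 150 bp).
#' * `"HBEC"` — 12 induced versus 12 noninduced samples at 38 bp.
#'
#' Planted per-family fold changes default to the corresponding published
#' main-analysis estimates for each profile, so the generator's defaults
#' reproduce the study conditions; pass `planted_fold_changes` to override.
#' Reads per locus are Poisson with mean `depth x weight x fold change`;
#' read starts are uniform within the locus; a configured fraction of
#' reads is emitted with sub-threshold MAPQ, a fraction straddles locus
#' boundaries (partial overlap), and background reads fall uniformly in
#' intergenic space.
#'
#' @param profile Study profile, one of `"BALF"`, `"PBMC"`, `"HBEC"`.
#' @param seed Integer seed; fixes every downstream draw.
#' @param base_family_reads Expected reads per family in a unit-depth
#'   control dataset (split over that family's loci).
#' @param hk_reads Named vector of expected housekeeping-gene reads at
#'   unit depth.
#' @param planted_fold_changes Named vector of per-family case/control
#'   fold changes; `NULL` uses the profile default.
#' @param background_rate Expected intergenic reads as a fraction of
#'   feature reads (default 0.02).
#' @param low_mapq_fraction Fraction of reads emitted with MAPQ below the
#'   filter threshold (default 0.1).
#' @param edge_read_rate Fraction of feature reads straddling a locus
#'   boundary, overlapping it by 1..(read length - 1) bp (default 0.02).
#' @param depth_sdlog Log-sd of the per-sample depth factor (default 0.2),
#'   emulating unequal sequencing depths across runs.
#' @param target_fraction,mapq_threshold Counting parameters the truth
#'   ledger is computed against (defaults 0.8 and 20).
#' @return An object of class `herv_sim_config`.
#' @export
simulation_config <- function(profile = c("BALF", "PBMC", "HBEC"),
                              seed = 1,
                              base_family_reads = 200,
                              hk_reads = c(SDHA = 1500, HPRT1 = 1200,
                                           RBX1 = 1000, RRAGA = 1800),
                              planted_fold_changes = NULL,
                              background_rate = 0.02,
                              low_mapq_fraction = 0.1,
                              edge_read_rate = 0.02,
                              depth_sdlog = 0.2,
                              target_fraction = 0.8,
                              mapq_threshold = 20) {
  profile <- match.arg(profile)
  assumed <- default_assumed_lengths()
  fams <- names(assumed)
  if (is.null(planted_fold_changes)) {
    planted_fold_changes <- default_planted_fold_changes(profile)
  }
  missing <- setdiff(fams, names(planted_fold_changes))
  if (length(missing) > 0L) {
    stop("planted_fold_changes missing families: ",
         paste(missing, collapse = ", "))
  }
  if (any(planted_fold_changes <= 0)) stop("planted fold changes must be > 0")
  stopifnot(background_rate >= 0, low_mapq_fraction >= 0,
            low_mapq_fraction <= 1, edge_read_rate >= 0, edge_read_rate < 1)
  design <- profile_design(profile)
  set.seed(as.integer(seed))
  design$depth_factor <- round(stats::rlnorm(nrow(design), 0, depth_sdlog), 4)
  design$fraction_share <- c(bulk = 1, CD3pos = 0.45,
                             CD3neg = 0.55)[design$fraction]
  # 3 loci per family at 50/70/90% of the assumed element length, with
  # relative expression weights 0.5/0.3/0.2; gene lengths are gene-typical
  loci <- do.call(rbind, lapply(fams, function(fam) {
    data.frame(feature = fam, kind = "family",
               length = round(assumed[[fam]] * c(0.5, 0.7, 0.9)),
               weight = c(0.5, 0.3, 0.2), stringsAsFactors = FALSE)
  }))
  gene_len <- c(SDHA = 38000, HPRT1 = 40000, RBX1 = 20000, RRAGA = 6000)
  genes <- data.frame(feature = names(hk_reads), kind = "gene",
                      length = gene_len[names(hk_reads)], weight = 1,
                      stringsAsFactors = FALSE)
  structure(
    list(profile = profile, seed = as.integer(seed),
         base_family_reads = base_family_reads, hk_reads = hk_reads,
         planted_fold_changes = planted_fold_changes[fams],
         background_rate = background_rate,
         low_mapq_fraction = low_mapq_fraction,
         edge_read_rate = edge_read_rate,
         depth_sdlog = depth_sdlog,
         target_fraction = target_fraction,
         mapq_threshold = mapq_threshold,
         assumed_lengths = assumed,
         loci = rbind(loci, genes),
         design = design),
    class = "herv_sim_config"
  )
}

# Published main-analysis fold changes per profile: the default planted
# effects that make the generator's defaults the study conditions.
default_planted_fold_changes <- function(profile) {
  fams <- names(default_assumed_lengths())
  vals <- switch(profile,
    BALF = c(2.9, 2.79, 3.29, 0.56, 3.29, 1.44, 8.69, 18.46, 11.18,
             7.37, 4.51, 43.44, 5.52),
    PBMC = c(0.74, 1.12, 1.64, 1.37, 0.98, 0.94, 0.99, 0.77, 0.98,
             0.81, 0.73, 0.61, 1.06),
    HBEC = c(1.74, 2.11, 1.25, 0.65, 1.56, 1.20, 1.78, 1.12, 1.63,
             1.73, 0.75, 1.06, 3.77)
  )
  stats::setNames(vals, fams)
}

# Sample designs mirroring the three study layouts.
profile_design <- function(profile) {
  row <- function(sid, pid, group, fraction, rl) {
    data.frame(sample_id = sid, patient_id = pid, group = group,
               fraction = fraction, nominal_read_length = rl,
               stringsAsFactors = FALSE)
  }
  if (profile == "BALF") {
    rbind(
      row("S01", "P1", "case", "bulk", 150),
      row("S02", "P1", "case", "bulk", 150),
      row("S03", "P2", "case", "bulk", 150),
      row("S04", "P2", "case", "bulk", 150),
      row("S05", "P3", "case", "bulk", 76),
      row("S06", "P3", "case", "bulk", 100),
      row("S07", "P4", "case", "bulk", 100),
      row("S08", "P5", "case", "CD3pos", 150),
      row("S09", "P5", "case", "CD3neg", 150),
      row("S10", "P6", "case", "CD3pos", 150),
      row("S11", "P6", "case", "CD3neg", 150),
      row("S12", "P7", "case", "CD3pos", 150),
      row("S13", "P7", "case", "CD3neg", 150),
      row("S14", "C1", "control", "bulk", 50),
      row("S15", "C2", "control", "bulk", 50),
      row("S16", "C3", "control", "bulk", 50)
    )
  } else if (profile == "PBMC") {
    rbind(
      row("S01", "P1", "case", "bulk", 100),
      row("S02", "P2", "case", "bulk", 100),
      row("S03", "P3", "case", "bulk", 100),
      row("S04", "C1", "control", "bulk", 100),
      row("S05", "C2", "control", "bulk", 150),
      row("S06", "C3", "control", "bulk", 150)
    )
  } else {
    cases <- do.call(rbind, lapply(1:12, function(i) {
      row(sprintf("S%02d", i), sprintf("P%02d", i), "case", "bulk", 38)
    }))
    ctrls <- do.call(rbind, lapply(1:12, function(i) {
      row(sprintf("S%02d", i + 12), sprintf("C%02d", i), "control",
          "bulk", 38)
    }))
    rbind(cases, ctrls)
  }
}

#' Lay out the toy reference for a simulation
#'
#' Places every locus sequentially on two contigs with 1,000 bp intergenic
#' gaps (deterministic given the config), so features never overlap and a
#' read can only straddle one feature boundary.
#'
#' @param config `herv_sim_config`.
#' @return A list with `contigs` (data frame `name`, `length`) and
#'   `intervals` (BED-style data frame with one row per locus).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "herv_sim_config"))
  loci <- config$loci
  gap <- 1000L
  n <- nrow(loci)
  half <- ceiling(n / 2)
  contig_of <- rep(c("chrS1", "chrS2"), times = c(half, n - half))
  start <- integer(n)
  pos <- c(chrS1 = gap, chrS2 = gap)
  for (i in seq_len(n)) {
    ctg <- contig_of[i]
    start[i] <- pos[[ctg]]
    pos[[ctg]] <- pos[[ctg]] + loci$length[i] + gap
  }
  intervals <- data.frame(
    chrom = contig_of, start = start, end = start + loci$length,
    label = loci$feature, strand = ".", stringsAsFactors = FALSE
  )
  contigs <- data.frame(name = c("chrS1", "chrS2"),
                        length = as.integer(pos[c("chrS1", "chrS2")]),
                        stringsAsFactors = FALSE)
  list(contigs = contigs, intervals = intervals)
}

# Expected reads emitted per locus for one sample (before MAPQ/overlap).
.locus_means <- function(config, sample) {
  loci <- config$loci
  fc <- ifelse(loci$kind == "family" & sample$group == "case",
               config$planted_fold_changes[loci$feature], 1)
  base <- ifelse(loci$kind == "family",
                 config$base_family_reads * loci$weight,
                 config$hk_reads[loci$feature])
  base * fc * sample$depth_factor * sample$fraction_share
}

#' Simulate one sample's aligned reads and its truth ledger
#'
#' Draws Poisson read counts per locus, places interior reads uniformly
#' within the locus (full-length overlap), emits the configured fractions
#' of boundary-straddling and low-MAPQ reads, and adds background reads in
#' intergenic space. The ledger records, per feature, the reads emitted
#' and the reads that both pass the MAPQ threshold and meet the
#' minimum-overlap rule — the ground truth the counting stage is tested
#' against.
#'
#' @param config `herv_sim_config`.
#' @param sample_id One sample id from `config$design`.
#' @return A list with `reads` (alignment data frame as from
#'   [read_alignments()]) and `ledger` (data frame `feature`, `emitted`,
#'   `counted`).
#' @export
simulate_sample <- function(config, sample_id) {
  stopifnot(inherits(config, "herv_sim_config"))
  design <- config$design
  idx <- match(sample_id, design$sample_id)
  if (is.na(idx)) stop("unknown sample_id: ", sample_id)
  sample <- design[idx, ]
  set.seed(config$seed + idx * 101L)
  ref <- build_reference(config)
  ints <- ref$intervals
  loci <- config$loci
  rl <- sample$nominal_read_length
  means <- .locus_means(config, sample)
  n_loc <- stats::rpois(length(means), means)

  starts <- integer(0); mapqs <- integer(0); ovl <- integer(0)
  locus_of <- integer(0)
  for (i in seq_along(n_loc)) {
    n <- n_loc[i]
    if (n == 0L) next
    s <- ints$start[i]; e <- ints$end[i]
    is_edge <- stats::runif(n) < config$edge_read_rate
    st <- integer(n); ov <- integer(n)
    n_int <- sum(!is_edge)
    if (n_int > 0L) {
      st[!is_edge] <- s + floor(stats::runif(n_int) * (e - s - rl + 1))
      ov[!is_edge] <- rl
    }
    n_edge <- sum(is_edge)
    if (n_edge > 0L) {
      o <- 1L + floor(stats::runif(n_edge) * (rl - 1L))
      left <- stats::runif(n_edge) < 0.5
      st[is_edge] <- ifelse(left, s + o - rl, e - o)
      ov[is_edge] <- o
    }
    mq <- ifelse(stats::runif(n) < config$low_mapq_fraction, 5L, 60L)
    starts <- c(starts, st); mapqs <- c(mapqs, mq); ovl <- c(ovl, ov)
    locus_of <- c(locus_of, rep(i, n))
  }

  # background reads, uniform over intergenic gaps (never touch a feature)
  n_bg <- stats::rpois(1, config$background_rate * sum(means))
  bg_start <- integer(0); bg_chrom <- character(0)
  if (n_bg > 0L) {
    gaps <- .intergenic_gaps(ref, margin = rl)
    if (nrow(gaps) > 0L) {
      gi <- sample.int(nrow(gaps), n_bg, replace = TRUE,
                       prob = gaps$end - gaps$start)
      bg_start <- gaps$start[gi] +
        floor(stats::runif(n_bg) * (gaps$end[gi] - gaps$start[gi] - rl + 1))
      bg_chrom <- gaps$chrom[gi]
    } else n_bg <- 0L
  }
  bg_mapq <- if (n_bg > 0L) {
    ifelse(stats::runif(n_bg) < config$low_mapq_fraction, 5L, 60L)
  } else integer(0)

  chrom <- c(ints$chrom[locus_of], bg_chrom)
  st_all <- c(starts, bg_start)
  mq_all <- c(mapqs, bg_mapq)
  n_all <- length(st_all)
  reads <- data.frame(
    query_id = sprintf("%s_r%06d", sample_id, seq_len(n_all)),
    chrom = chrom,
    start = as.integer(st_all),
    end = as.integer(st_all + rl),
    mapq = as.integer(mq_all),
    read_length = rep(rl, n_all),
    is_mapped = rep(TRUE, n_all),
    mate_index = rep(NA_integer_, n_all),
    stringsAsFactors = FALSE
  )

  # ledger: counted = passes MAPQ and the fractional-overlap rule
  required <- ifelse(
    loci$kind == "family",
    config$target_fraction * rl / config$assumed_lengths[loci$feature] *
      loci$length,
    config$target_fraction * rl
  )
  pass <- mapqs >= config$mapq_threshold & ovl >= required[locus_of]
  features <- unique(loci$feature)
  emitted <- tabulate(factor(loci$feature[locus_of], levels = features),
                      nbins = length(features))
  counted <- tabulate(factor(loci$feature[locus_of][pass],
                             levels = features),
                      nbins = length(features))
  ledger <- data.frame(feature = features, emitted = emitted,
                       counted = counted, stringsAsFactors = FALSE)
  ledger <- rbind(ledger, data.frame(feature = "background",
                                     emitted = n_bg, counted = 0L))
  list(reads = reads, ledger = ledger)
}

.intergenic_gaps <- function(ref, margin) {
  ints <- ref$intervals
  out <- list()
  for (ctg in ref$contigs$name) {
    len <- ref$contigs$length[ref$contigs$name == ctg]
    sub <- ints[ints$chrom == ctg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    bounds <- c(0L, rbind(sub$start, sub$end), len)
    gs <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    keep <- (ge - gs) >= margin + 2L
    if (any(keep)) {
      out[[ctg]] <- data.frame(chrom = ctg, start = gs[keep] + 1L,
                               end = ge[keep] - 1L,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a whole study in memory
#'
#' Runs [simulate_sample()] for every design row, returning the reads and
#' ledgers keyed by sample id plus the sample sheet (without file paths),
#' for fast end-to-end runs that skip SAM serialization.
#'
#' @param config `herv_sim_config`.
#' @return List with `sheet`, `reads_list`, `ledgers`, `reference`.
#' @export
simulate_study <- function(config) {
  ref <- build_reference(config)
  ids <- config$design$sample_id
  sims <- lapply(ids, function(sid) simulate_sample(config, sid))
  names(sims) <- ids
  sheet <- config$design[, c("sample_id", "patient_id", "group",
                             "fraction", "nominal_read_length")]
  sheet$alignment_path <- NA_character_
  list(sheet = sheet,
       reads_list = lapply(sims, `[[`, "reads"),
       ledgers = lapply(sims, `[[`, "ledger"),
       reference = ref)
}

#' Write a complete simulated study fixture to disk
#'
#' Materializes a profile's study as files: annotation BED, assumed-length
#' table (YAML), one SAM and truth-ledger TSV per sample, the sample
#' sheet, and a YAML echo of the configuration. The fixture is runnable
#' end-to-end by [run_pipeline()].
#'
#' @param profile Study profile (see [simulation_config()]), or a ready
#'   `herv_sim_config` passed via `config`.
#' @param dir Output directory (created if needed).
#' @param seed Seed forwarded to [simulation_config()] when `config` is
#'   not supplied.
#' @param config Optional `herv_sim_config` overriding `profile`/`seed`.
#' @param ... Further arguments to [simulation_config()].
#' @return List with `sheet_path`, `bed_path`, `assumed_lengths_path`,
#'   `config`, `ledgers` (per sample), `dir`.
#' @export
make_study_fixture <- function(profile = "BALF", dir, seed = 1,
                               config = NULL, ...) {
  if (is.null(config)) {
    config <- simulation_config(profile = profile, seed = seed, ...)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- build_reference(config)
  bed_path <- file.path(dir, "annotation.bed")
  write_bed(ref$intervals, bed_path)
  al_path <- file.path(dir, "assumed_lengths.yaml")
  yaml::write_yaml(as.list(config$assumed_lengths), al_path)
  sheet <- config$design[, c("sample_id", "patient_id", "group",
                             "fraction", "nominal_read_length")]
  sheet$alignment_path <- file.path(dir,
                                    paste0(sheet$sample_id, ".sam"))
  ledgers <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    sim <- simulate_sample(config, sid)
    write_sam(sim$reads, ref$contigs, sheet$alignment_path[i])
    utils::write.table(sim$ledger,
                       file.path(dir, paste0(sid, ".ledger.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ledgers[[sid]] <- sim$ledger
  }
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(sheet, sheet_path)
  cfg_echo <- config[c("profile", "seed", "base_family_reads",
                       "background_rate", "low_mapq_fraction",
                       "edge_read_rate", "depth_sdlog",
                       "target_fraction", "mapq_threshold")]
  cfg_echo$planted_fold_changes <- as.list(config$planted_fold_changes)
  cfg_echo$hk_reads <- as.list(config$hk_reads)
  yaml::write_yaml(cfg_echo, file.path(dir, "config.yaml"))
  list(sheet_path = sheet_path, bed_path = bed_path,
       assumed_lengths_path = al_path, config = config,
       ledgers = ledgers, dir = dir)
}

#' Simulate a count table directly from the noise model
#'
#' Draws the post-filter feature counts without placing reads: each
#' locus's emitted reads are Poisson and the MAPQ filter and overlap rule
#' thin them independently, so the counted reads are Poisson with mean
#' equal to the analytic expectation from [expected_counts()]. The result
#' is distributionally identical to counting a simulated read file, at a
#' small fraction of the cost; use it for replicated calibration studies.
#'
#' @param config `herv_sim_config`.
#' @return Samples-by-features integer matrix, like [count_table()].
#' @export
simulate_count_table <- function(config) {
  mu <- expected_counts(config)
  set.seed(config$seed + 65537L)
  counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Analytic expected counted reads per sample and feature
#'
#' The exact expectation of the ledger's `counted` column under the
#' configured rates: Poisson locus means thinned by the MAPQ pass rate
#' and, for boundary-straddling reads, by the probability that a uniform
#' 1..(read length - 1) bp overlap meets the minimum-overlap requirement.
#' Used to check analytically that the realized case/control expectation
#' ratio equals the planted fold change.
#'
#' @param config `herv_sim_config`.
#' @return Matrix `samples x features` of expected counted reads.
#' @export
expected_counts <- function(config) {
  loci <- config$loci
  features <- unique(loci$feature)
  design <- config$design
  out <- matrix(0, nrow(design), length(features),
                dimnames = list(design$sample_id, features))
  for (i in seq_len(nrow(design))) {
    sample <- design[i, ]
    rl <- sample$nominal_read_length
    means <- .locus_means(config, sample)
    required <- ifelse(
      loci$kind == "family",
      config$target_fraction * rl / config$assumed_lengths[loci$feature] *
        loci$length,
      config$target_fraction * rl
    )
    # edge reads: overlap uniform on {1, ..., rl-1}
    n_pass <- pmax(0, rl - 1 - ceiling(required) + 1)
    p_edge <- n_pass / (rl - 1)
    p_keep <- (1 - config$low_mapq_fraction) *
      ((1 - config$edge_read_rate) + config$edge_read_rate * p_edge)
    expc <- means * p_keep
    out[i, ] <- tapply(expc, factor(loci$feature, levels = features), sum)
  }
  out
}
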