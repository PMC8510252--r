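test_that("the toy reference lays out all loci without overlap", {
  cfg <- simulation_config("PBMC", seed = 2)
  ref <- build_reference(cfg)
  # 13 families x 3 loci + 4 genes
  expect_equal(nrow(ref$intervals), 13 * 3 + 4)
  expect_equal(ref$intervals$end - ref$intervals$start, cfg$loci$length)
  # no overlaps within a contig
  for (ctg in ref$contigs$name) {
    sub <- ref$intervals[ref$intervals$chrom == ctg, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(diff(rbind(sub$start, sub$end)) > 0))
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)] + 150))
    expect_lte(max(sub$end),
               ref$contigs$length[ref$contigs$name == ctg])
  }
  # same config -> byte-identical BED
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bed(ref$intervals, p1)
  write_bed(build_reference(cfg)$intervals, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config("PBMC", seed = 77, base_family_reads = 50)
  a <- simulate_sample(cfg, "S01")
  b <- simulate_sample(cfg, "S01")
  expect_identical(a, b)
  other <- simulate_sample(simulation_config("PBMC", seed = 78,
                                             base_family_reads = 50),
                           "S01")
  expect_false(identical(a$reads, other$reads))
  # byte-identical SAM output
  ref <- build_reference(cfg)
  p1 <- withr::local_tempfile(fileext = ".sam")
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(a$reads, ref$contigs, p1)
  write_sam(b$reads, ref$contigs, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("counting simulated reads reproduces the truth ledger exactly", {
  # noise on: low-MAPQ reads, boundary-straddling reads, background reads
  cfg <- simulation_config("PBMC", seed = 13, base_family_reads = 150,
                           low_mapq_fraction = 0.4, edge_read_rate = 0.3,
                           background_rate = 0.1)
  ref <- build_reference(cfg)
  ann <- build_annotation(ref$intervals)
  for (sid in c("S01", "S05")) {
    sim <- simulate_sample(cfg, sid)
    rl <- cfg$design$nominal_read_length[cfg$design$sample_id == sid]
    kept <- filter_mapq(sim$reads, cfg$mapq_threshold)
    counts <- count_sample(kept, ann, read_length = rl,
                           target_fraction = cfg$target_fraction)
    truth <- sim$ledger[sim$ledger$feature != "background", ]
    expect_equal(unname(counts[truth$feature]), truth$counted)
    # the 40% low-MAPQ plant is visible in emitted vs counted
    expect_lt(sum(truth$counted), sum(truth$emitted) * 0.75)
  }
})

test_that("per-locus draws match their Poisson means", {
  cfg <- simulation_config("PBMC", seed = 31, base_family_reads = 400,
                           low_mapq_fraction = 0, edge_read_rate = 0,
                           background_rate = 0)
  sim <- simulate_sample(cfg, "S04")  # control, depth factor known
  depth <- cfg$design$depth_factor[cfg$design$sample_id == "S04"]
  truth <- sim$ledger[sim$ledger$feature != "background", ]
  fam <- truth$feature %in% names(cfg$planted_fold_changes)
  mu_fam <- cfg$base_family_reads * depth
  # 4-sigma Poisson band around the planted expectation, per family
  expect_true(all(abs(truth$emitted[fam] - mu_fam) <= 4 * sqrt(mu_fam)))
  mu_hk <- cfg$hk_reads[truth$feature[!fam]] * depth
  expect_true(all(abs(truth$emitted[!fam] - mu_hk) <= 4 * sqrt(mu_hk)))
})

test_that("the realized expectation ratio equals the planted fold change", {
  plants <- stats::setNames(rep(c(0.5, 1, 2, 8, 40), length.out = 13),
                            names(default_assumed_lengths()))
  cfg <- simulation_config("PBMC", seed = 1, planted_fold_changes = plants,
                           edge_read_rate = 0)
  mu <- expected_counts(cfg)
  d <- cfg$design
  case <- which(d$group == "case")[1]
  ctrl <- which(d$group == "control")[1]
  scale <- (d$depth_factor[case] * d$fraction_share[case]) /
    (d$depth_factor[ctrl] * d$fraction_share[ctrl])
  fams <- names(plants)
  expect_equal(mu[case, fams] / mu[ctrl, fams] / scale, plants)
})

test_that("study fixtures mirror the study designs", {
  dir <- withr::local_tempdir()
  fx <- make_study_fixture("BALF", dir = file.path(dir, "balf"), seed = 4,
                           base_family_reads = 40, hk_reads = c(
                             SDHA = 300, HPRT1 = 240, RBX1 = 200,
                             RRAGA = 360))
  sheet <- parse_sample_sheet(fx$sheet_path)
  expect_equal(nrow(sheet), 16L)
  expect_equal(length(unique(sheet$patient_id)), 10L)  # 7 cases + 3 controls
  dup_patients <- names(which(table(sheet$patient_id[
    sheet$fraction == "bulk"]) == 2))
  expect_equal(length(dup_patients), 3L)
  expect_equal(sum(sheet$fraction == "CD3pos"), 3L)
  expect_equal(sum(sheet$fraction == "CD3neg"), 3L)
  expect_setequal(unique(sheet$nominal_read_length), c(150L, 76L, 100L, 50L))
  expect_true(all(file.exists(sheet$alignment_path)))
  expect_true(file.exists(fx$bed_path))

  hbec <- simulation_config("HBEC", seed = 4)
  expect_equal(nrow(hbec$design), 24L)
  expect_equal(as.integer(table(hbec$design$group)), c(12L, 12L))
  expect_true(all(hbec$design$nominal_read_length == 38L))
})

test_that("count-level simulation matches the analytic expectation", {
  cfg <- simulation_config("HBEC", seed = 19, base_family_reads = 500)
  counts <- simulate_count_table(cfg)
  mu <- expected_counts(cfg)
  expect_equal(dim(counts), dim(mu))
  # every cell within a 5-sigma Poisson band of its mean
  expect_true(all(abs(counts - mu) <= 5 * sqrt(mu) + 1))
})
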