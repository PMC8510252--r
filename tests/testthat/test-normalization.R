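test_that("cell fractions are pooled at the raw-count level, before ratios", {
  sheet <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P1", "C1"),
    group = c("case", "case", "control"),
    fraction = c("CD3pos", "CD3neg", "bulk"),
    nominal_read_length = 150L,
    alignment_path = NA_character_,
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    S1 = c("HERV-W" = 10L, SDHA = 100L),
    S2 = c("HERV-W" = 30L, SDHA = 300L),
    S3 = c("HERV-W" = 5L, SDHA = 50L)
  )
  pooled <- pool_cell_fractions(counts, sheet)
  expect_equal(nrow(pooled$counts), 2L)
  expect_equal(pooled$counts["P1.pooled", ], c("HERV-W" = 40L, SDHA = 400L))
  # downstream ratio reflects the pooled counts
  expect_equal(unname(normalize_counts(
    c("HERV-W" = pooled$counts["P1.pooled", "HERV-W"]),
    c(SDHA = pooled$counts["P1.pooled", "SDHA"]))[1, 1]), 0.1)
  # one all-zero fraction leaves the other unchanged
  counts0 <- counts; counts0["S2", ] <- 0L
  pooled0 <- pool_cell_fractions(counts0, sheet)
  expect_equal(pooled0$counts["P1.pooled", ], counts["S1", ])
  # a missing fraction names the patient
  expect_error(pool_cell_fractions(counts[-2, , drop = FALSE], sheet[-2, ]),
               "P1.*unmatched")
})

test_that("pooled counts equal counting the concatenation of both fraction files", {
  ann <- tiny_annotation()
  set.seed(21)
  mk <- function(n) {
    ints <- ann$intervals[sample.int(nrow(ann$intervals), n, replace = TRUE), ]
    st <- ints$start + floor(runif(n) * (ints$end - ints$start - 100))
    make_reads(ints$chrom, st, st + 100L)
  }
  pos <- mk(300); neg <- mk(500)
  sheet <- data.frame(
    sample_id = c("S1", "S2"), patient_id = "P1", group = "case",
    fraction = c("CD3pos", "CD3neg"), nominal_read_length = 100L,
    alignment_path = NA_character_, stringsAsFactors = FALSE
  )
  counts <- rbind(S1 = count_sample(pos, ann, 100L),
                  S2 = count_sample(neg, ann, 100L))
  pooled <- pool_cell_fractions(counts, sheet)
  concat <- count_sample(rbind(pos, neg), ann, 100L)
  expect_equal(pooled$counts["P1.pooled", ], concat[colnames(counts)],
               ignore_attr = TRUE)
})

test_that("per-gene ratios are raw-count quotients with a hard zero guard", {
  ratios <- normalize_counts(
    c("HERV-W" = 200),
    c(SDHA = 100, HPRT1 = 80, RBX1 = 50, RRAGA = 400)
  )
  expect_equal(ratios["HERV-W", ],
               c(SDHA = 2.0, HPRT1 = 2.5, RBX1 = 4.0, RRAGA = 0.5))
  expect_equal(unname(normalize_counts(c(X = 0), c(SDHA = 10))[1, 1]), 0)
  expect_error(normalize_counts(c(X = 5), c(SDHA = 0)), "zero reads")
  # explicit pseudocount mode is the only escape hatch
  expect_equal(unname(normalize_counts(c(X = 5), c(SDHA = 0),
                                       pseudocount = 1)[1, 1]), 6)
})

test_that("biological duplicates are averaged arithmetically per gene", {
  ratios <- array(
    c(2, 4, 10, 1, 3, 20),
    dim = c(3, 1, 2),
    dimnames = list(c("d1", "d2", "d3"), "HERV-H", c("SDHA", "HPRT1"))
  )
  avg <- average_duplicates(ratios, c("P1", "P1", "P2"))
  expect_equal(dim(avg), c(2L, 1L, 2L))
  expect_equal(avg["P1", "HERV-H", "SDHA"], 3)    # mean(2, 4)
  expect_equal(avg["P1", "HERV-H", "HPRT1"], 2)   # mean(1, 3)
  expect_equal(avg["P2", "HERV-H", "SDHA"], 10)   # single sample: identity
  three <- array(c(1, 2, 6), dim = c(3, 1, 1),
                 dimnames = list(c("a", "b", "c"), "F", "SDHA"))
  expect_equal(unname(average_duplicates(three, rep("P", 3))[1, 1, 1]), 3)
})

test_that("median combination behaves as the even/odd median", {
  expect_equal(median_combine(c(2.0, 2.5, 4.0, 0.5)), 2.25)
  expect_equal(median_combine(c(1, 2, 3)), 2)
  expect_equal(median_combine(rep(3.7, 4)), 3.7)
  expect_error(median_combine(numeric(0)), "no per-gene ratios")
})

test_that("NEVs are scale-invariant and median-bounded on a simulated study", {
  cfg <- simulation_config("PBMC", seed = 5, base_family_reads = 80)
  counts <- simulate_count_table(cfg)
  sheet <- cfg$design
  sheet$alignment_path <- NA_character_
  ann <- build_annotation(build_reference(cfg)$intervals)
  nev <- normalize_expression(counts, sheet, ann)
  for (k in c(2L, 3L, 5L)) {
    nev_k <- normalize_expression(counts * k, sheet, ann)
    expect_equal(nev_k$per_gene, nev$per_gene)
    expect_equal(nev_k$combined, nev$combined)
  }
  # combined value lies between the per-gene extremes on every unit
  lo <- apply(nev$per_gene, c(1, 2), min)
  hi <- apply(nev$per_gene, c(1, 2), max)
  expect_true(all(nev$combined >= lo & nev$combined <= hi))
  # with 4 genes the median is the mean of the two middle ratios
  u <- nev$units$unit_id[1]; fam <- colnames(nev$combined)[1]
  expect_equal(nev$combined[u, fam],
               mean(sort(nev$per_gene[u, fam, ])[2:3]))
})

test_that("normalization order is pool -> ratio -> average -> median", {
  # a case where averaging duplicates before vs after the median differs
  counts <- rbind(
    S1 = c(F1 = 100L, SDHA = 10L, HPRT1 = 100L, RBX1 = 100L, RRAGA = 100L),
    S2 = c(F1 = 100L, SDHA = 100L, HPRT1 = 10L, RBX1 = 100L, RRAGA = 100L),
    S3 = c(F1 = 50L, SDHA = 50L, HPRT1 = 50L, RBX1 = 50L, RRAGA = 50L)
  )
  sheet <- flat_sheet(n_case = 2, n_control = 1)
  sheet$sample_id <- c("S1", "S2", "S3")
  sheet$patient_id <- c("P1", "P1", "C1")
  ints <- rbind(make_intervals("chr1", 0, 1000, "F1"),
                make_intervals("chr1", c(2000, 4000, 6000, 8000),
                               c(3000, 5000, 7000, 9000),
                               c("SDHA", "HPRT1", "RBX1", "RRAGA")))
  ann <- build_annotation(ints, assumed_lengths = c(F1 = 10000))
  nev <- normalize_expression(counts, sheet, ann)
  # per-gene ratios averaged first: SDHA (10+1)/2=5.5, HPRT1 5.5, others 1
  expect_equal(nev$per_gene["P1", "F1", "SDHA"], 5.5)
  expect_equal(nev$combined["P1", "F1"], median(c(5.5, 5.5, 1, 1)))
  # median-then-average would instead give mean(1, 1) = 1
  expect_false(isTRUE(all.equal(nev$combined["P1", "F1"], 1)))
})
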