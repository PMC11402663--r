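test_that("event counting is per-case and per-drug", {
  # 3 cases of drug X with the event, 1 without
  demo <- demo_df(as.character(1:5))
  drug <- rbind(drug_df(as.character(1:4), "X"),
                # the same PS drug listed twice in one report counts once
                drug_df("1", "X", drug_seq = "2"),
                drug_df("5", "Y"))
  reac <- reac_df(c("1", "2", "3", "5"), "CONSTIPATION")
  ds <- build_event_dataset(list(DEMO = demo, DRUG = drug, REAC = reac))
  counts <- count_event_by_drug(ds)
  expect_equal(counts[["X"]], 3L)
  expect_equal(counts[["Y"]], 1L)

  expect_length(count_event_by_drug(ds, "NO SUCH PT"), 0L)

  # a case with two PS drugs contributes once to each
  drug2 <- rbind(drug_df("1", "X"), drug_df("1", "Y", drug_seq = "2"))
  ds2 <- build_event_dataset(list(DEMO = demo_df("1"), DRUG = drug2,
                                  REAC = reac_df("1", "CONSTIPATION")))
  counts2 <- count_event_by_drug(ds2)
  expect_equal(unname(counts2[c("X", "Y")]), c(1L, 1L))
})

test_that("ranking sorts by frequency, ties by name, with half-up percent", {
  counts <- c(X = 5L, Y = 9L, Z = 5L)
  r <- rank_top(counts, n = 2, event_total = 100)
  expect_equal(r$drug, c("Y", "X"))
  expect_equal(r$frequency, c(9L, 5L))
  expect_equal(r$percentage, c(9, 5))

  # published percentages reproduce at 2 decimals
  r <- rank_top(c(LENALIDOMIDE = 7730L, NIRAPARIB = 3651L), n = 30,
                event_total = 169897)
  expect_equal(r$percentage, c(4.55, 2.15))

  # stable under permutation of the input mapping
  perm <- sample(length(counts))
  expect_equal(rank_top(counts[perm], 3, 100), rank_top(counts, 3, 100))

  # n beyond the number of drugs returns all, no padding
  expect_equal(nrow(rank_top(counts, 10, 100)), 3L)
})

test_that("2x2 table construction matches direct enumeration", {
  ds <- tiny_dataset()
  t <- build_table(ds, "X")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 3, b = 1, c = 1, d = 5))
  expect_equal(t$N, 10)

  # absent drug: a = b = 0, still a valid table
  t0 <- build_table(ds, "ABSENT")
  expect_equal(unlist(t0[c("a", "b")]), c(a = 0, b = 0))
})

test_that("table margins reconcile with dataset totals for every drug", {
  cfg <- suppressWarnings(synthetic_config(seed = 11, n_reports = 3000,
                          duplicate_case_rate = 0.1))
  dir <- withr::local_tempdir()
  generate_faers(cfg, dir)
  ds <- build_event_dataset(read_faers_dir(dir))
  n_event <- length(unique(ds$events$caseid[ds$events$pt == "CONSTIPATION"]))
  for (dr in unique(ds$drug_mentions$drugname)) {
    t <- build_table(ds, dr)
    expect_equal(t$a + t$c, n_event)
    expect_equal(t$a + t$b,
                 length(unique(ds$drug_mentions$caseid[
                   ds$drug_mentions$drugname == dr])))
    expect_equal(t$N, nrow(ds$cases))
  }
  # single-PS generator: per-drug a counts partition the event cases
  counts <- count_event_by_drug(ds)
  expect_equal(sum(counts), n_event)
})

test_that("table reconstruction from published margins and ROR", {
  t <- reconstruct_table_from_ror(a = 2369, n_total = 50659288,
                                  event_total = 169897, ror = 115.51)
  expect_equal(t$a, 2369)
  expect_equal(t$b, 6180)
  expect_equal(t$c, 167528)
  expect_equal(t$d, 50483211)
  # the reconstruction reproduces the ROR it was solved from
  expect_equal(ror_estimate(t)$ror, 115.51, tolerance = 1e-4)
})

test_that("trend series covers all periods and computes percentages", {
  demo <- demo_df(as.character(1:6),
                  fda_dt = c("20200101", "20200301", "20210501", "20210601",
                             "20210701", "20210801"))
  drug <- drug_df(as.character(1:6), "X")
  reac <- rbind(reac_df(c("1", "3"), "CONSTIPATION"),
                reac_df(c("2", "4", "5", "6"), "NAUSEA"))
  ds <- build_event_dataset(list(DEMO = demo, DRUG = drug, REAC = reac))

  y <- trend_series(ds, granularity = "year")
  expect_equal(y$period, c("2020", "2021"))
  expect_equal(y$event_count, c(1L, 1L))
  expect_equal(y$percentage, c(50, 25))

  q <- trend_series(ds, granularity = "quarter")
  # every quarter between first and last is present, empty ones at zero
  expect_equal(q$period, c("2020Q1", "2020Q2", "2020Q3", "2020Q4",
                           "2021Q1", "2021Q2", "2021Q3"))
  expect_equal(q$total_count[q$period == "2020Q2"], 0L)
  expect_true(is.na(q$percentage[q$period == "2020Q2"]))
  expect_equal(q$percentage[q$period == "2021Q2"], 50)

  # single-period overall percentage: 2 events of 200 ADEs -> 1.00%
  demo2 <- demo_df(as.character(1:200), fda_dt = "20200101")
  reac2 <- rbind(reac_df(c("1", "2"), "CONSTIPATION"),
                 reac_df(as.character(3:200), "NAUSEA"))
  ds2 <- build_event_dataset(list(DEMO = demo2,
                                  DRUG = drug_df("1", "X"), REAC = reac2))
  tr <- trend_series(ds2, granularity = "year")
  expect_equal(tr$percentage, 1)

  # per-drug scope: 3 event reports among 100 of the drug's ADEs -> 3.00%
  demo3 <- demo_df(as.character(1:100), fda_dt = "20200101")
  drug3 <- drug_df(as.character(1:100), "X")
  reac3 <- rbind(reac_df(c("1", "2", "3"), "CONSTIPATION"),
                 reac_df(as.character(4:100), "NAUSEA"))
  ds3 <- build_event_dataset(list(DEMO = demo3, DRUG = drug3, REAC = reac3))
  tr3 <- trend_series(ds3, granularity = "year", scope = "per_drug",
                      drug = "X")
  expect_equal(tr3$percentage, 3)
})

test_that("demographic summary reproduces half-up percentages", {
  # all-unknown-sex input: unknown row at 100.0
  demo <- demo_df(as.character(1:4), sex = "")
  ds <- build_event_dataset(list(DEMO = demo, DRUG = drug_df("1", "X"),
                                 REAC = reac_df(as.character(1:4),
                                                "CONSTIPATION")))
  s <- demographic_summary(ds)
  sex <- s[s$category == "sex", ]
  expect_equal(sex$percentage[sex$level == "unknown"], 100)
  expect_equal(sum(sex$count), 4L)

  # percentages within a category sum to ~100 under rounding slack
  cfg <- suppressWarnings(synthetic_config(seed = 3, n_reports = 4000))
  dir <- withr::local_tempdir()
  generate_faers(cfg, dir)
  ds2 <- build_event_dataset(read_faers_dir(dir))
  s2 <- demographic_summary(ds2)
  for (cat in c("age", "sex")) {
    expect_lt(abs(sum(s2$percentage[s2$category == cat]) - 100), 0.2)
  }
})

test_that("half-up rounding matches published table conventions", {
  expect_equal(round_half_up(0.345, 2), 0.35)
  expect_equal(round_half_up(2.145, 2), 2.15)
  expect_equal(round_half_up(-0.345, 2), -0.35)
  expect_equal(round_half_up(56.6183, 1), 56.6)
})
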