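test_that("FAERS table reader parses the $-delimited dialect", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt$sex",
               "1001$100$20200101$M",
               "1002$101$20200215$F"), path)
  df <- read_faers_table(path, "DEMO")
  expect_equal(nrow(df), 2L)
  expect_equal(df$sex, c("M", "F"))
  expect_equal(attr(df, "n_malformed"), 0L)

  # embedded "$" breaks the field count: logged as malformed, excluded
  writeLines(c("primaryid$caseid$fda_dt$sex",
               "1001$100$20200101$M",
               "1002$10$1$20200215$F"), path)
  expect_warning(df <- read_faers_table(path, "DEMO"), "malformed")
  expect_equal(nrow(df), 1L)
  expect_equal(attr(df, "n_malformed"), 1L)

  # trailing empty field must be preserved
  writeLines(c("primaryid$caseid$sex", "1001$100$"), path)
  df <- read_faers_table(path, "DEMO")
  expect_equal(df$sex, "")

  expect_error(read_faers_table(file.path(tempdir(), "nope.txt"), "DEMO"),
               "not found")
  writeLines(c("foo$bar", "1$2"), path)
  expect_error(read_faers_table(path, "DEMO"), "primaryid")
})

test_that("legacy ISR/CASE headers are aliased to primaryid/caseid", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ISR$CASE$FDA_DT", "7001$700$20101010"), path)
  df <- read_faers_table(path, "DEMO")
  expect_named(df, c("primaryid", "caseid", "fda_dt"))
  expect_equal(df$primaryid, "7001")
})

test_that("drug role codes are preserved for downstream PS filtering", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$drug_seq$role_cod$drugname",
               "1001$1$PS$LENALIDOMIDE",
               "1001$2$C$ASPIRIN"), path)
  df <- read_faers_table(path, "DRUG")
  expect_equal(df$role_cod, c("PS", "C"))
})

test_that("partial-precision dates parse by digit count", {
  d <- parse_faers_date(c("20200104", "202001", "2020", "", "20201340",
                          "2020010", "abc", NA))
  expect_equal(d$precision,
               c("day", "month", "year", "missing", "invalid", "invalid",
                 "invalid", "missing"))
  expect_equal(d$date[1], as.Date("2020-01-04"))
  expect_true(all(is.na(d$date[-1])))
  # invalid calendar day at day precision
  expect_equal(parse_faers_date("20200230")$precision, "invalid")
})

test_that("case deduplication keeps latest fda_dt, ties broken by primaryid", {
  demo <- demo_df(primaryid = c("1001", "1002"), caseid = c("X", "X"),
                  fda_dt = c("20210101", "20210301"))
  kept <- dedup_cases(demo)
  expect_equal(kept$primaryid, "1002")

  demo <- demo_df(primaryid = c("1002", "1010"), caseid = "X",
                  fda_dt = "20210101")
  expect_equal(dedup_cases(demo)$primaryid, "1010")

  # numeric comparison when both parse: 1010 > 999 despite "999" > "1010"
  demo <- demo_df(primaryid = c("999", "1010"), caseid = "X",
                  fda_dt = "20210101")
  expect_equal(dedup_cases(demo)$primaryid, "1010")

  # lexicographic fallback
  demo <- demo_df(primaryid = c("A-2", "A-10"), caseid = "X",
                  fda_dt = "20210101")
  expect_equal(dedup_cases(demo)$primaryid, "A-2")

  # missing caseid: singleton cases, warned
  demo <- demo_df(primaryid = c("1", "2"), caseid = c("", "X"))
  expect_warning(kept <- dedup_cases(demo), "caseid")
  expect_equal(nrow(kept), 2L)
})

test_that("deduplication is idempotent and keyed by distinct caseids", {
  set.seed(42)
  n <- 300
  demo <- demo_df(
    primaryid = as.character(sample(1e5, n)),
    caseid = as.character(sample(80, n, replace = TRUE)),
    fda_dt = format(as.Date("2015-01-01") + sample(2000, n, TRUE), "%Y%m%d")
  )
  once <- dedup_cases(demo)
  twice <- dedup_cases(once)
  attr(once, "n_removed") <- NULL
  attr(twice, "n_removed") <- NULL
  expect_identical(once, twice)
  expect_equal(nrow(once), length(unique(demo$caseid)))
  expect_lte(nrow(once), nrow(demo))
})

test_that("drug names normalize and map through synonyms", {
  expect_equal(normalize_drug_name("  Lenalidomide "), "LENALIDOMIDE")
  expect_equal(normalize_drug_name("sevelamer   carbonate"),
               "SEVELAMER CARBONATE")
  expect_equal(
    normalize_drug_name("REVLIMID", synonyms = c(Revlimid = "lenalidomide")),
    "LENALIDOMIDE"
  )
})

test_that("event dataset joins tables, keeps only PS drugs, counts drops", {
  demo <- demo_df(c("1", "2"), fda_dt = c("20200101", "20200202"))
  drug <- rbind(drug_df("1", "X", role_cod = "PS"),
                drug_df("2", "Y", role_cod = "C"))
  reac <- rbind(reac_df("1", "Constipation"), reac_df("3", "NAUSEA"))
  ther <- ther_df("1", "20191220")
  ds <- build_event_dataset(list(DEMO = demo, DRUG = drug, REAC = reac,
                                 THER = ther))
  expect_s3_class(ds, "faers_dataset")
  expect_equal(nrow(ds$cases), 2L)
  # only the PS mention survives; the C-role case has none
  expect_equal(ds$drug_mentions$drugname, "X")
  expect_equal(ds$drug_mentions$caseid, "1")
  # therapy start attached by dsg_drug_seq
  expect_equal(ds$drug_mentions$start_dt, "20191220")
  # orphan REAC row dropped and counted
  expect_equal(unname(ds$drops$REAC[["orphan_or_superseded"]]), 1L)
  expect_equal(nrow(ds$events), 1L)
  expect_equal(ds$events$pt, "CONSTIPATION")
  # drop accounting partitions input rows
  expect_equal(sum(ds$drops$DRUG), nrow(drug))
  expect_equal(sum(ds$drops$REAC), nrow(reac))
})

test_that("age units convert to years and demographics normalize", {
  demo <- demo_df(as.character(1:6),
                  age = c("5", "60", "18", "104", "730.5", ""),
                  age_cod = c("DEC", "YR", "MON", "WK", "DY", ""),
                  sex = c("M", "F", "f", "U", "", "M"))
  ds <- build_event_dataset(list(DEMO = demo))
  expect_equal(ds$cases$age_years, c(50, 60, 1.5, 2, 2, NA))
  # sex matching is case-insensitive; anything else is unknown
  expect_equal(ds$cases$sex, c("M", "F", "F", "unknown", "unknown", "M"))
})

test_that("write/read round-trip reproduces normalized records", {
  dir <- withr::local_tempdir()
  demo <- demo_df(c("11", "12"), caseid = c("C1", "C2"),
                  fda_dt = c("20200115", "20200220"),
                  event_dt = c("20200101", ""), sex = c("M", "F"))
  drug <- drug_df(c("11", "12"), c("X", "Y"))
  reac <- reac_df(c("11", "12"), c("CONSTIPATION", "NAUSEA"))
  ther <- ther_df(c("11", "12"), c("20191230", "20200101"))
  write_faers_table(demo, file.path(dir, "DEMO20Q1.txt"))
  write_faers_table(drug, file.path(dir, "DRUG20Q1.txt"))
  write_faers_table(reac, file.path(dir, "REAC20Q1.txt"))
  write_faers_table(ther, file.path(dir, "THER20Q1.txt"))
  raw <- read_faers_dir(dir)
  expect_equal(attr(raw, "quarters"), "2020Q1")
  ds1 <- build_event_dataset(raw)

  # write the dataset back out in the same dialect and re-read
  dir2 <- withr::local_tempdir()
  write_faers_table(raw$DEMO[names(demo)], file.path(dir2, "DEMO20Q1.txt"))
  write_faers_table(raw$DRUG[names(drug)], file.path(dir2, "DRUG20Q1.txt"))
  write_faers_table(raw$REAC[names(reac)], file.path(dir2, "REAC20Q1.txt"))
  write_faers_table(raw$THER[names(ther)], file.path(dir2, "THER20Q1.txt"))
  ds2 <- build_event_dataset(read_faers_dir(dir2))
  expect_identical(ds1$cases, ds2$cases)
  expect_identical(ds1$drug_mentions, ds2$drug_mentions)
  expect_identical(ds1$events, ds2$events)
})
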