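# In-code fixtures shared across test files.

demo_df <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                    event_dt = "", age = "", age_cod = "", sex = "",
                    reporter_country = "US") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = fda_dt, event_dt = event_dt, age = age,
             age_cod = age_cod, sex = sex,
             reporter_country = reporter_country,
             stringsAsFactors = FALSE)
}

drug_df <- function(primaryid, drugname, role_cod = "PS", drug_seq = "1") {
  data.frame(primaryid = as.character(primaryid), drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname,
             stringsAsFactors = FALSE)
}

reac_df <- function(primaryid, pt) {
  data.frame(primaryid = as.character(primaryid), pt = pt,
             stringsAsFactors = FALSE)
}

ther_df <- function(primaryid, start_dt, dsg_drug_seq = "1", end_dt = "") {
  data.frame(primaryid = as.character(primaryid),
             dsg_drug_seq = dsg_drug_seq, start_dt = start_dt,
             end_dt = end_dt, stringsAsFactors = FALSE)
}

# 10 cases: 4 name drug X (3 of them with the event), 6 do not (1 with the
# event) -> 2x2 table (a,b,c,d) = (3,1,1,5)
tiny_dataset <- function() {
  ids <- as.character(101:110)
  demo <- demo_df(ids)
  drug <- drug_df(as.character(101:104), "X")
  reac <- reac_df(c("101", "102", "103", "105"), "CONSTIPATION")
  build_event_dataset(list(DEMO = demo, DRUG = drug, REAC = reac))
}

# uniform random strictly-positive 2x2 tables for oracle comparisons
random_tables <- function(n, seed, max_cell = 1e6) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cells <- 1 + floor(runif(4) * max_cell)
    contingency_table(cells[1], cells[2], cells[3], cells[4])
  })
}

# direct-formula oracle, deliberately naive (no log-space tricks)
oracle_stats <- function(t) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- a + b + c + d
  list(
    ror = (a * d) / (b * c),
    ror_lo = exp(log((a * d) / (b * c)) -
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    ror_hi = exp(log((a * d) / (b * c)) +
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
    rrr = a * n / ((a + b) * (a + c)),
    ic = log2(a * n / ((a + b) * (a + c))),
    ic_noren = log2((a + 0.5) / ((a + b) * (a + c) / n + 0.5))
  )
}

rel_err <- function(x, y) abs(x - y) / abs(y)
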