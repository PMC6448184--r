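# records_io: readers, NPI validation, directory round trip.

test_that("licensure reader returns one record per row and drops/dedups with counts", {
  rows <- data.frame(
    license_number = c("000001", "000002", "005577", "005577", "000009"),
    first_name = c("Helen", "Mary", "Ann", "Ann", "Ghost"),
    middle_name = "", last_name = c("Black", "Quinn", "Lee", "Lee", ""),
    suffix = "", street = "1 Main St", city = "Hartford", state = "ct",
    zip = "06100", stringsAsFactors = FALSE)
  p <- write_lic_csv(rows)
  lic <- read_licensure_list(p, "certified_nurse_midwife", 2017)

  # 5 rows in: 1 empty-last dropped, 1 duplicate license collapsed
  expect_equal(nrow(lic), 3L)
  expect_equal(attr(lic, "rows_in"), 5L)
  expect_equal(attr(lic, "n_dropped_empty_last"), 1L)
  expect_equal(attr(lic, "n_duplicates"), 1L)
  # conservation: rows_in == out + dropped + dedup
  expect_equal(attr(lic, "rows_in"),
               nrow(lic) + attr(lic, "n_dropped_empty_last") +
                 attr(lic, "n_duplicates"))
  # state uppercased and validated
  expect_true(all(lic$state == "CT"))
  # first occurrence wins
  expect_equal(lic$first[lic$license_number == "005577"], "Ann")
})

test_that("licensure reader error modes", {
  expect_error(read_licensure_list(tempfile(), "dentist", 2017),
               class = "provlink_io_error")
  p <- write_lic_csv(data.frame(license_number = "1", first_name = "A",
                                last_name = "B", street = "", city = "",
                                state = "CT"))
  expect_error(read_licensure_list(p, "astronaut", 2017),
               class = "provlink_config_error")
  bad <- tempfile(fileext = ".csv")
  writeLines("licnum,first_name,last_name,street,city,state\n1,A,B,,,CT",
             bad)
  expect_error(read_licensure_list(bad, "dentist", 2017),
               regexp = "license_number",
               class = "provlink_format_error")
})

test_that("validate_npi accepts exactly one check digit per base", {
  # oracle: brute-force the 10th digit over an independent Luhn check
  for (base in c("123456789", "990000001", "808401234")) {
    candidates <- paste0(base, 0:9)
    oracle_ok <- vapply(candidates, npi_oracle_valid, TRUE)
    expect_equal(sum(oracle_ok), 1L)
    expect_equal(validate_npi(candidates), unname(oracle_ok))
    # flipping the valid check digit invalidates
    valid <- candidates[oracle_ok]
    flipped <- paste0(base, (as.integer(substr(valid, 10, 10)) + 1) %% 10)
    expect_false(validate_npi(flipped))
  }
  expect_false(validate_npi("123456789"))   # 9 digits
  expect_false(validate_npi("12345678XX"))
  expect_false(validate_npi(NA_character_))
})

test_that("NPPES reader quarantines bad NPIs and normalizes gender", {
  cols <- nppes_puf_columns()
  good <- mk_npi("990000001")
  bad <- paste0(substr(good, 1, 9),
                (as.integer(substr(good, 10, 10)) + 1) %% 10)
  df <- data.frame(a = c(good, bad), b = c("Black", "Gold"),
                   c = c("Helen", "X"), d = c("367A00000X", "367A00000X"),
                   e = "Farmington", f = "CT", g = "Hartford", h = "CT",
                   i = c("", "F"), stringsAsFactors = FALSE)
  names(df) <- unlist(cols[c("npi", "last", "first", "taxonomy_primary",
                             "p_city", "p_state", "m_city", "m_state",
                             "gender")])
  p <- tempfile(fileext = ".csv")
  data.table::fwrite(df, p)
  rej <- tempfile(fileext = ".csv")
  np <- read_nppes_puf(p, 2017, reject_path = rej)

  expect_equal(nrow(np), 1L)
  expect_equal(np$npi, good)
  expect_equal(np$gender, "unknown")      # empty gender field
  q <- attr(np, "quarantine")
  expect_equal(nrow(q), 1L)
  expect_equal(q$npi, bad)
  expect_true(file.exists(rej))
  # conservation
  expect_equal(attr(np, "rows_in"), nrow(np) + nrow(q))
})

test_that("directory write/read round-trips value-identically", {
  expect_equal(write_directory(NULL, tempfile(fileext = ".csv")), 0L)

  recs <- data.frame(
    last_name = c("Black", "O'Neil"), first_name = c("Helen", "Mary"),
    npi = c(mk_npi("990000001"), mk_npi("990000002")),
    gender = c("F", "F"), phone = c("8605550000", ""),
    taxonomy_code = "367A00000X",
    practice_street = c("1705 Park Ave", "37 Collins Rd"),
    practice_city = "Farmington", practice_state = "CT",
    practice_zip = "06030",
    mailing_street = "1705 Park Ave", mailing_city = "Farmington",
    mailing_state = "CT", mailing_zip = "06030",
    license_number = c("000001", "000002"),
    match_type = c("FL_CS", "L_C"), total_score = c(20L, 12L),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  expect_equal(write_directory(recs, p), 2L)
  back <- read_directory(p)
  expect_equal(back, recs)

  # empty write yields header-only file readable as 0 rows
  p0 <- tempfile(fileext = ".csv")
  write_directory(recs[0, ], p0)
  expect_equal(nrow(read_directory(p0)), 0L)
})
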