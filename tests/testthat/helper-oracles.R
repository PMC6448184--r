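# Independent oracles and fixture builders. Oracles deliberately use
# different algorithms from the package implementation.

# Brute-force recursive Levenshtein (exponential; only for short strings).
lev_oracle <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_oracle(substr(a, 2, nchar(a)), b) + 1L,
      lev_oracle(a, substr(b, 2, nchar(b))) + 1L,
      lev_oracle(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# Independent Luhn validity check over a full digit string (payload +
# check digit), written as a running loop rather than matrix arithmetic.
luhn_valid_oracle <- function(digits_string) {
  d <- as.integer(strsplit(digits_string, "", fixed = TRUE)[[1]])
  total <- 0L
  double_it <- FALSE
  for (i in rev(seq_along(d))) {
    x <- d[i]
    if (double_it) {
      x <- x * 2L
      if (x > 9L) x <- x - 9L
    }
    total <- total + x
    double_it <- !double_it
  }
  total %% 10L == 0L
}

npi_oracle_valid <- function(npi10) {
  nchar(npi10) == 10L && grepl("^[0-9]{10}$", npi10) &&
    luhn_valid_oracle(paste0("80840", npi10))
}

# A valid synthetic NPI from a 9-digit base, via the package helper.
mk_npi <- function(base9) paste0(base9, npi_check_digit(base9))

# One-row licensure record with overridable fields.
mk_lic <- function(...) {
  row <- list(license_number = "000001",
              provider_type = "certified_nurse_midwife",
              first = "Helen", middle = "A", last = "Black", suffix = "",
              street = "1705 Park Avenue", city = "Farmington",
              state = "CT", zip = "06030", year = 2017L,
              name_raw = "", addr_raw = "")
  ov <- list(...)
  row[names(ov)] <- ov
  as.data.frame(row, stringsAsFactors = FALSE)
}

# One-row registry record with overridable fields.
mk_np <- function(...) {
  row <- list(npi = mk_npi("990000001"), first = "Helen", middle = "A",
              last = "Black", suffix = "", gender = "F",
              phone = "8605550000",
              taxonomy_primary = "367A00000X", taxonomy_secondary = "",
              m_street = "1705 Park Ave", m_city = "Farmington",
              m_state = "CT", m_zip = "06030",
              p_street = "1705 Park Ave", p_city = "Farmington",
              p_state = "CT", p_zip = "06030",
              other_identifiers = "", year = 2017L, name_raw = "")
  ov <- list(...)
  row[names(ov)] <- ov
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Write a minimal licensure CSV under the default column map.
write_lic_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(rows, path)
  path
}

# Random small matching instances for blocking-completeness checks:
# surname pools rigged with near-collisions (typos, compounds) so fuzzy
# comparison and the subset rule are both exercised.
random_instance <- function(n_lic, n_np, seed) {
  set.seed(seed)
  base <- c("BLACK", "BLAKE", "BLACKE", "GOLD", "GOLDE", "BROWN",
            "SMITH", "BROWN SMITH", "BROWN JACKSON SMITH", "QUINN",
            "QUIN", "HENDERSON", "HENDERSEN", "NG", "LI", "LIU")
  firsts <- c("HELEN", "HELLAN", "H", "ANDREW", "HOWARD", "MARY", "M")
  towns <- c("FARMINGTON", "HARTFORD", "STORRS")
  streets <- c("37 COLLINS ROAD", "1705 PARK AVE", "857 HIGH ROAD", "")
  lic <- data.frame(
    license_number = sprintf("%06d", seq_len(n_lic)),
    provider_type = "certified_nurse_midwife",
    first = sample(firsts, n_lic, TRUE), middle = "",
    last = sample(base, n_lic, TRUE), suffix = "",
    street = sample(streets, n_lic, TRUE),
    city = sample(towns, n_lic, TRUE), state = "CT", zip = "",
    year = 2017L, stringsAsFactors = FALSE)
  np <- data.frame(
    npi = vapply(seq_len(n_np),
                 function(i) mk_npi(sprintf("99%07d", i)), ""),
    first = sample(firsts, n_np, TRUE), middle = "",
    last = sample(base, n_np, TRUE), suffix = "",
    gender = "F", phone = "",
    taxonomy_primary = "367A00000X", taxonomy_secondary = "",
    m_street = sample(streets, n_np, TRUE),
    m_city = sample(towns, n_np, TRUE), m_state = "CT", m_zip = "",
    p_street = sample(streets, n_np, TRUE),
    p_city = sample(towns, n_np, TRUE), p_state = "CT", p_zip = "",
    other_identifiers = "", year = 2017L, stringsAsFactors = FALSE)
  list(lic = lic, np = np)
}
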