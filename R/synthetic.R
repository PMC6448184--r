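# Synthetic paired licensure/registry cohorts with ground truth and
# error-channel injection, so the whole pipeline is testable offline.

# Bundled lexicons. The generator targets structural realism (field
# formats, error channels, temporal staging), not demographic realism.
.FIRST_NAMES <- c(
  "Helen", "James", "Mary", "Robert", "Patricia", "John", "Jennifer",
  "Michael", "Linda", "David", "Barbara", "William", "Susan", "Richard",
  "Jessica", "Joseph", "Sarah", "Thomas", "Karen", "Charles", "Nancy",
  "Christopher", "Lisa", "Daniel", "Betty", "Matthew", "Margaret",
  "Anthony", "Sandra", "Mark", "Ashley", "Donald", "Kimberly", "Steven",
  "Emily", "Paul", "Donna", "Andrew", "Michelle", "Joshua", "Carol",
  "Kenneth", "Amanda", "Kevin", "Dorothy", "Brian", "Melissa", "George",
  "Deborah", "Edward", "Stephanie", "Ronald", "Rebecca", "Timothy",
  "Sharon", "Jason", "Laura", "Jeffrey", "Cynthia", "Ryan", "Kathleen",
  "Jacob", "Amy", "Gary", "Angela", "Nicholas", "Shirley", "Eric",
  "Anna", "Jonathan", "Brenda", "Stephen", "Pamela", "Larry", "Emma",
  "Justin", "Nicole", "Scott", "Katherine", "Brandon")

.SURNAMES <- c(
  "Abbott", "Alvarez", "Anderson", "Baldwin", "Barnes", "Bennett",
  "Blackwell", "Bowman", "Bradley", "Brennan", "Brooks", "Burgess",
  "Cameron", "Carlson", "Carter", "Chambers", "Chandler", "Coleman",
  "Collins", "Conway", "Cooper", "Crawford", "Dawson", "Delgado",
  "Donovan", "Douglas", "Duncan", "Elliott", "Emerson", "Erickson",
  "Farrell", "Fischer", "Fleming", "Foster", "Franklin", "Fraser",
  "Gallagher", "Gardner", "Gibson", "Graham", "Griffin", "Hansen",
  "Harmon", "Harper", "Harrington", "Hawkins", "Hayden", "Henderson",
  "Hoffman", "Holland", "Hopkins", "Hudson", "Ingram", "Jacobs",
  "Jennings", "Keller", "Kennedy", "Lambert", "Lawson", "Mackenzie",
  "Maldonado", "Marshall", "Matthews", "Mcbride", "Mcdonald", "Mercer",
  "Mitchell", "Monroe", "Morgan", "Morrison", "Nichols", "Norton",
  "Osborne", "Palmer", "Parsons", "Patterson", "Pearson", "Peterson",
  "Quinn", "Ramsey")

.DISTRACTOR_SURNAMES <- c(
  "Szczepanski", "Vanderbilt", "Wojciechowski", "Xiong", "Yamamoto",
  "Zablocki", "Ziegler", "Oyelaran", "Nakamura", "Lindqvist",
  "Kowalczyk", "Ivanenko", "Huang", "Gustafsson", "Fitzwilliam",
  "Eriksdottir")

.STREET_NAMES <- c(
  "Park", "Collins", "High", "Maple", "Oak", "Cedar", "Elm", "Main",
  "Church", "School", "Mill", "River", "Lake", "Hill", "Spring",
  "Franklin", "Washington", "Prospect", "Chestnut", "Willow", "Birch",
  "Meadow", "Orchard", "Sunset")

.STREET_SUFFIX_STYLES <- list(
  c("Avenue", "Ave"), c("Street", "St"), c("Road", "Rd"),
  c("Drive", "Dr"), c("Lane", "Ln"), c("Boulevard", "Blvd"))

.TOWNS <- list(
  CT = c("Farmington", "Hartford", "New Haven", "Stamford", "Bridgeport",
         "Norwalk", "Danbury", "Waterbury", "Storrs", "Middletown",
         "New Britain", "Greenwich", "Torrington", "Bristol", "Meriden",
         "Manchester"),
  MA = c("Springfield", "Worcester", "Boston", "Pittsfield", "Lowell",
         "Amherst"),
  NY = c("Albany", "White Plains", "Yonkers", "Poughkeepsie", "Syracuse",
         "Rochester"),
  RI = c("Providence", "Warwick", "Cranston", "Newport"),
  FL = c("Miami", "Orlando", "Tampa", "Naples", "Sarasota", "Jacksonville"))

.DISTRACTOR_TOWNS <- list(
  CT = c("Ledyard Corners", "Quiet Harbor"),
  MA = c("Stonefield"), NY = c("Milltown Falls"), RI = c("Gullport"),
  FL = c("Palm Hollow"))

.OUT_REGION <- list(
  NJ = c("Newark", "Trenton", "Princeton"),
  PA = c("Philadelphia", "Scranton"),
  VT = c("Burlington", "Montpelier"),
  NH = c("Concord", "Nashua"))

.OUT_OF_SET_TAXONOMIES <- c("204E00000X", "207Q00000X", "104100000X",
                            "152W00000X")

#' Error-injection configuration
#'
#' Per-identity probabilities of the qualitative error channels observed in
#' real roster/registry comparisons: name misspellings, legal name changes,
#' moves to different addresses, inaccurate specialty taxonomies in the
#' national registry, a middle name used as the first name in one source,
#' and roster entries with no national record at all (deceased/retired
#' providers). Channels are mutually exclusive per identity. The 2% default
#' per channel is this package's choice — no field estimate of per-channel
#' rates exists — and is documented as such.
#'
#' @param p_misspelling,p_name_change,p_moved,p_bad_taxonomy,
#'   p_middle_as_first,p_unmatched_licensure Probabilities in \[0, 1\]
#'   summing to at most 1.
#' @return Object of class `error_config`.
#' @export
error_config <- function(p_misspelling = 0.02, p_name_change = 0.02,
                         p_moved = 0.02, p_bad_taxonomy = 0.02,
                         p_middle_as_first = 0.02,
                         p_unmatched_licensure = 0.02) {
  p <- c(misspelling = p_misspelling, name_change = p_name_change,
         moved = p_moved, bad_taxonomy = p_bad_taxonomy,
         middle_as_first = p_middle_as_first,
         unmatched = p_unmatched_licensure)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    .config_error("error probabilities must lie in [0, 1]")
  }
  if (sum(p) > 1) .config_error("error probabilities must sum to at most 1")
  structure(as.list(p), class = "error_config")
}

#' @noRd
.error_channels <- function() {
  c("misspelling", "name_change", "moved", "bad_taxonomy",
    "middle_as_first", "unmatched")
}

# 1-2 random character edits (substitute / insert / delete / duplicate) at
# positions past the first letter; retried until the Levenshtein distance
# to the original is exactly the requested number of edits.
#' @noRd
.typo <- function(word, n_edits) {
  for (attempt in 1:25) {
    w <- word
    for (e in seq_len(n_edits)) {
      nc <- nchar(w)
      if (nc < 3L) break
      pos <- sample(2:nc, 1L)
      op <- sample(c("sub", "ins", "del", "dup"), 1L)
      ch <- sample(letters, 1L)
      w <- switch(op,
        sub = paste0(substr(w, 1, pos - 1), ch, substr(w, pos + 1, nc)),
        ins = paste0(substr(w, 1, pos - 1), ch, substr(w, pos, nc)),
        del = paste0(substr(w, 1, pos - 1), substr(w, pos + 1, nc)),
        dup = paste0(substr(w, 1, pos), substr(w, pos, nc)))
    }
    if (utils::adist(toupper(w), toupper(word))[1, 1] == n_edits) return(w)
  }
  word
}

# A surname at normalized edit distance > 2 from `avoid` (so a name change
# can never be absorbed by the fuzzy misspelling tolerance).
#' @noRd
.pick_distant_surname <- function(avoid) {
  pool <- .SURNAMES[utils::adist(toupper(.SURNAMES), toupper(avoid)) > 2]
  pool[sample.int(length(pool), 1L)]
}

#' Inject one error channel into a synthetic identity
#'
#' Mutates the registry side of an identity according to the named channel
#' and reports the truth label. Name changes and moves are staged at a
#' uniformly drawn window year: snapshots before the change year keep the
#' original surname/address, which is what lets temporal scoring recover
#' such identities. Draws use the current RNG state.
#'
#' @param identity List with at least `first`, `middle`, `last`, `street`,
#'   `city`, `state`, `taxonomy_primary`, `taxonomy_secondary`.
#' @param channel One of `"misspelling"`, `"name_change"`, `"moved"`,
#'   `"bad_taxonomy"`, `"middle_as_first"`, `"unmatched"`, `"none"`.
#' @param window A [scoring_window()].
#' @return List: `overrides` (per-year named lists of registry field
#'   overrides), `drop_nppes` (logical), `label`, `detail` (e.g. the change
#'   year).
#' @export
inject_error <- function(identity, channel, window = scoring_window()) {
  years <- window_years(window)
  ov <- setNames(rep(list(list()), length(years)), as.character(years))
  detail <- ""
  drop <- FALSE
  if (channel == "none") {
    return(list(overrides = ov, drop_nppes = FALSE, label = "none",
                detail = ""))
  }
  if (!channel %in% .error_channels()) {
    .config_error(sprintf("unknown error channel '%s'", channel))
  }
  if (channel == "misspelling") {
    target <- if (runif(1) < 0.5) "last" else "first"
    mutated <- .typo(identity[[target]], sample(1:2, 1L))
    for (y in as.character(years)) ov[[y]][[target]] <- mutated
    detail <- sprintf("target=%s", target)
  } else if (channel == "name_change") {
    change_year <- sample(years, 1L)
    jackson_style <- runif(1) < 0.5
    new_last <- if (jackson_style) {
      paste(identity$last, .pick_distant_surname(identity$last))
    } else {
      .pick_distant_surname(identity$last)
    }
    for (y in as.character(years[years >= change_year])) {
      ov[[y]][["last"]] <- new_last
    }
    detail <- sprintf("change_year=%d;style=%s", change_year,
                      if (jackson_style) "token_insert" else "replace")
  } else if (channel == "moved") {
    move_year <- sample(years, 1L)
    new_city <- {
      pool <- setdiff(.TOWNS[[identity$state]] %||% .TOWNS$CT,
                      identity$city)
      pool[sample.int(length(pool), 1L)]
    }
    sfx <- .STREET_SUFFIX_STYLES[[sample.int(
      length(.STREET_SUFFIX_STYLES), 1L)]]
    new_street <- paste(sample(1:9999, 1L),
                        sample(setdiff(.STREET_NAMES,
                                       strsplit(identity$street,
                                                " ")[[1]]), 1L),
                        sfx[2])
    for (y in as.character(years[years >= move_year])) {
      ov[[y]][["p_street"]] <- new_street
      ov[[y]][["m_street"]] <- new_street
      ov[[y]][["p_city"]] <- new_city
      ov[[y]][["m_city"]] <- new_city
    }
    detail <- sprintf("move_year=%d", move_year)
  } else if (channel == "bad_taxonomy") {
    bad <- .OUT_OF_SET_TAXONOMIES[sample.int(
      length(.OUT_OF_SET_TAXONOMIES), 1L)]
    for (y in as.character(years)) {
      ov[[y]][["taxonomy_primary"]] <- bad
      ov[[y]][["taxonomy_secondary"]] <- ""
    }
    detail <- sprintf("code=%s", bad)
  } else if (channel == "middle_as_first") {
    for (y in as.character(years)) ov[[y]][["first"]] <- identity$middle
  } else if (channel == "unmatched") {
    drop <- TRUE
  }
  list(overrides = ov, drop_nppes = drop, label = channel, detail = detail)
}

#' @noRd
.draw_identity <- function(i, seed, name_idx, provider_type, tax_codes) {
  set.seed(.substream_seed(seed, i))
  nf <- length(.FIRST_NAMES)
  first <- .FIRST_NAMES[(name_idx - 1L) %% nf + 1L]
  last <- .SURNAMES[(name_idx - 1L) %/% nf + 1L]
  middle <- sample(setdiff(.FIRST_NAMES, first), 1L)
  if (runif(1) < 0.05) {   # compound surname
    last <- paste(last, .pick_distant_surname(last))
  }
  state <- if (runif(1) < 0.8) "CT" else sample(c("MA", "NY", "RI", "FL"), 1L)
  city <- sample(.TOWNS[[state]], 1L)
  sfx <- .STREET_SUFFIX_STYLES[[sample.int(
    length(.STREET_SUFFIX_STYLES), 1L)]]
  street_core <- paste(sample(1:9999, 1L), sample(.STREET_NAMES, 1L))
  list(
    i = i, first = first, middle = middle, last = last,
    suffix = if (runif(1) < 0.05) "Jr" else "",
    street_full = paste(street_core, sfx[1]),   # roster spells it out
    street_abbr = paste(street_core, sfx[2]),   # registry abbreviates
    street = paste(street_core, sfx[1]),
    city = city, state = state,
    zip = sprintf("0%04d", sample(1000:9999, 1L)),
    gender = sample(c("M", "F"), 1L),
    phone = sprintf("860555%04d", sample(0:9999, 1L)),
    taxonomy_primary = tax_codes[sample.int(length(tax_codes), 1L)],
    taxonomy_secondary = if (runif(1) < 0.3) {
      tax_codes[sample.int(length(tax_codes), 1L)]
    } else "",
    license_number = sprintf("%06d", i),
    npi = {
      base <- sprintf("99%07d", i)
      paste0(base, npi_check_digit(base))
    }
  )
}

#' Generate a synthetic licensure/registry cohort with ground truth
#'
#' Writes one licensure roster CSV, one registry snapshot CSV per window
#' year (official PUF headers, valid check-digit NPIs), a ground-truth link
#' table (TSV) and a JSON manifest of all parameters. Identities carry
#' CT-dominated addresses with an MA/NY/RI/FL minority; distractor
#' registry rows (in-region with out-of-cohort towns and surnames, plus
#' out-of-region rows) exercise the location filter and precision. Errors
#' are injected per [error_config()] with labels recorded. Output is
#' deterministic for a fixed seed, and identity attributes are drawn from
#' per-identity substreams so earlier identities are stable as `n` grows.
#'
#' @param n Number of roster identities (1 to 6400).
#' @param provider_type One of [supported_provider_types()].
#' @param window A [scoring_window()].
#' @param errors An [error_config()].
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed).
#' @param distractor_frac Fraction of `n` added as registry-only rows,
#'   split evenly between in-region and out-of-region.
#' @param taxonomy_table Taxonomy table for drawing in-set codes.
#' @return List: `licensure_path`, `nppes_paths` (named by year),
#'   `truth_path`, `manifest_path`, and the `truth` data.frame, invisibly
#'   usable for evaluation.
#' @export
generate_cohort <- function(n, provider_type = "certified_nurse_midwife",
                            window = scoring_window(),
                            errors = error_config(), seed = 1L,
                            out_dir = tempfile("cohort_"),
                            distractor_frac = 0.2,
                            taxonomy_table = load_taxonomy_table()) {
  n <- as.integer(n)
  pool_n <- length(.FIRST_NAMES) * length(.SURNAMES)
  if (is.na(n) || n < 1L) .config_error("n must be a positive integer")
  if (n > pool_n) {
    .config_error(sprintf("n must be at most %d (name-pair pool)", pool_n))
  }
  if (!inherits(errors, "error_config")) errors <- do.call(error_config,
                                                           as.list(errors))
  tax_codes <- taxonomy_set_for(provider_type, taxonomy_table)$codes
  years <- window_years(window)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # unique (first, last) pairs via a seed-keyed affine index walk;
  # multiplier coprime to the pool size so the walk is a permutation
  coprimes <- c(7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L, 47L)
  a <- coprimes[(as.integer(seed) %% length(coprimes)) + 1L]
  b <- as.integer(seed) %% pool_n
  name_idx <- ((a * (seq_len(n) - 1L) + b) %% pool_n) + 1L

  p <- unlist(errors)
  cum <- cumsum(p)
  channels <- .error_channels()

  lic_rows <- vector("list", n)
  np_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- .draw_identity(i, seed, name_idx[i], provider_type, tax_codes)
    u <- runif(1)
    channel <- if (u < cum[length(cum)]) {
      channels[findInterval(u, c(0, cum), rightmost.closed = TRUE)]
    } else "none"
    inj <- inject_error(id, channel, window)

    lic_rows[[i]] <- data.frame(
      license_number = id$license_number, first_name = id$first,
      middle_name = id$middle, last_name = id$last, suffix = id$suffix,
      street = id$street_full, city = id$city, state = id$state,
      zip = id$zip, stringsAsFactors = FALSE)

    if (!inj$drop_nppes) {
      yr_rows <- lapply(as.character(years), function(y) {
        o <- inj$overrides[[y]]
        data.frame(
          year = y, npi = id$npi,
          first = o$first %||% id$first, middle = id$middle,
          last = o$last %||% id$last, suffix = id$suffix,
          gender = id$gender, phone = id$phone,
          taxonomy_primary = o$taxonomy_primary %||% id$taxonomy_primary,
          taxonomy_secondary = o$taxonomy_secondary %||%
            id$taxonomy_secondary,
          m_street = o$m_street %||% id$street_abbr,
          m_city = o$m_city %||% id$city,
          m_state = id$state, m_zip = id$zip,
          p_street = o$p_street %||% id$street_abbr,
          p_city = o$p_city %||% id$city,
          p_state = id$state, p_zip = id$zip,
          other_id = id$license_number, other_id_type = "01",
          stringsAsFactors = FALSE)
      })
      np_rows[[i]] <- data.table::rbindlist(yr_rows)
    }
    truth_rows[[i]] <- data.frame(
      license_number = id$license_number,
      npi = if (inj$drop_nppes) "" else id$npi,
      error_labels = inj$label, detail = inj$detail,
      stringsAsFactors = FALSE)
  }

  # registry-only distractor rows
  n_dis <- round(distractor_frac * n)
  dis_rows <- vector("list", n_dis)
  for (k in seq_len(n_dis)) {
    set.seed(.substream_seed(seed, 700000L + k))
    in_region <- k <= n_dis / 2
    if (in_region) {
      state <- sample(names(.DISTRACTOR_TOWNS), 1L)
      city <- sample(.DISTRACTOR_TOWNS[[state]], 1L)
    } else {
      state <- sample(names(.OUT_REGION), 1L)
      city <- sample(.OUT_REGION[[state]], 1L)
    }
    sfx <- .STREET_SUFFIX_STYLES[[sample.int(
      length(.STREET_SUFFIX_STYLES), 1L)]]
    street <- paste(sample(10001:19999, 1L), sample(.STREET_NAMES, 1L),
                    sfx[2])
    base <- sprintf("88%07d", k)
    dis_rows[[k]] <- data.frame(
      year = "ALL", npi = paste0(base, npi_check_digit(base)),
      first = sample(.FIRST_NAMES, 1L), middle = "",
      last = sample(.DISTRACTOR_SURNAMES, 1L), suffix = "",
      gender = sample(c("M", "F"), 1L),
      phone = sprintf("203555%04d", sample(0:9999, 1L)),
      taxonomy_primary = tax_codes[sample.int(length(tax_codes), 1L)],
      taxonomy_secondary = "",
      m_street = street, m_city = city, m_state = state,
      m_zip = sprintf("0%04d", sample(1000:9999, 1L)),
      p_street = street, p_city = city, p_state = state,
      p_zip = sprintf("0%04d", sample(1000:9999, 1L)),
      other_id = "", other_id_type = "",
      stringsAsFactors = FALSE)
  }

  lic <- as.data.frame(data.table::rbindlist(lic_rows))
  np_cols <- c("year", "npi", "first", "middle", "last", "suffix",
               "gender", "phone", "taxonomy_primary", "taxonomy_secondary",
               "m_street", "m_city", "m_state", "m_zip",
               "p_street", "p_city", "p_state", "p_zip",
               "other_id", "other_id_type")
  np_all <- data.table::rbindlist(np_rows[!vapply(np_rows, is.null, TRUE)])
  if (nrow(np_all) == 0L) {
    np_all <- data.table::as.data.table(
      setNames(rep(list(character(0)), length(np_cols)), np_cols))
  }
  dis <- if (n_dis > 0L) {
    as.data.frame(data.table::rbindlist(dis_rows))
  } else NULL
  truth <- as.data.frame(data.table::rbindlist(truth_rows))

  lic_path <- file.path(out_dir,
                        sprintf("licensure_%s.csv", provider_type))
  data.table::fwrite(lic, lic_path)

  cols <- nppes_puf_columns()
  puf_names <- unlist(cols)
  internal <- names(cols)
  nppes_paths <- character(0)
  for (y in as.character(years)) {
    snap <- as.data.frame(np_all[np_all$year == y, ])
    if (!is.null(dis)) {
      d <- dis; d$year <- y
      snap <- rbind(snap, d)
    }
    snap$year <- NULL
    out <- snap[, internal[internal != "npi"], drop = FALSE]
    out <- cbind(npi = snap$npi, out)
    names(out) <- puf_names[match(names(out), internal)]
    p <- file.path(out_dir, sprintf("nppes_%s.csv", y))
    data.table::fwrite(out, p)
    nppes_paths[y] <- p
  }

  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t")

  manifest <- list(
    generator = "provlink::generate_cohort",
    n = n, provider_type = provider_type,
    window = list(start = window$start_year, end = window$end_year),
    errors = unclass(errors), seed = as.integer(seed),
    distractor_frac = distractor_frac,
    files = c(licensure = lic_path, nppes = unname(nppes_paths),
              truth = truth_path))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  list(licensure_path = lic_path, nppes_paths = nppes_paths,
       truth_path = truth_path, manifest_path = manifest_path,
       truth = truth, out_dir = out_dir)
}

#' Read a ground-truth link table
#' @param path TSV written by [generate_cohort()].
#' @return data.frame with `license_number`, `npi`, `error_labels`, `detail`.
#' @export
read_truth <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = "character",
                                        na.strings = NULL))
  required <- c("license_number", "npi", "error_labels")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    .format_error(sprintf("truth table missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(names(dt), c(required, "detail"))
  if (length(unknown)) {
    .format_error(sprintf("truth table has unknown column(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  if (!"detail" %in% names(dt)) dt$detail <- ""
  dt
}
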