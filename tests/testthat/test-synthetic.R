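# synthetic_data: generator contracts, error injection, determinism.

test_that("generated files parse cleanly and truth covers every roster row", {
  co <- generate_cohort(n = 50, seed = 3, errors = error_config(),
                        out_dir = tempfile())
  lic <- read_licensure_list(co$licensure_path, "certified_nurse_midwife",
                             2017)
  expect_equal(nrow(lic), 50L)
  # every roster row has exactly one truth row
  expect_setequal(co$truth$license_number, lic$license_number)
  expect_equal(anyDuplicated(co$truth$license_number), 0L)
  # registry files pass the reader with zero quarantined rows
  for (p in co$nppes_paths) {
    np <- read_nppes_puf(p, 2017)
    expect_equal(nrow(attr(np, "quarantine")), 0L)
    expect_true(all(validate_npi(np$npi)))
  }
  # truth npi empty iff unmatched channel
  expect_equal(!nzchar(co$truth$npi),
               co$truth$error_labels == "unmatched")
  # manifest records the parameters
  man <- jsonlite::read_json(co$manifest_path)
  expect_equal(man$n, 50L)
  expect_equal(man$seed, 3L)
})

test_that("the same seed reproduces byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(n = 30, seed = 17, out_dir = d1)
  c2 <- generate_cohort(n = 30, seed = 17, out_dir = d2)
  for (f in c("licensure_certified_nurse_midwife.csv", "truth.tsv",
              "nppes_2013.csv", "nppes_2017.csv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
})

test_that("error channels mutate records as specified", {
  id <- list(first = "Helen", middle = "Howard", last = "Blackwell",
             street = "1705 Park Avenue", city = "Farmington",
             state = "CT", taxonomy_primary = "367A00000X",
             taxonomy_secondary = "367A00000X")
  w <- scoring_window(2013, 2017)
  set.seed(1)

  # misspelling: normalized edit distance to the original in {1, 2}
  for (i in 1:10) {
    inj <- inject_error(id, "misspelling", w)
    o <- inj$overrides[["2017"]]
    target <- if (!is.null(o$last)) "last" else "first"
    d <- name_edit_distance(toupper(o[[target]]), toupper(id[[target]]))
    expect_true(d %in% 1:2)
  }

  # name change: post-change surname beyond fuzzy tolerance of original,
  # staged so pre-change years keep the original
  for (i in 1:10) {
    inj <- inject_error(id, "name_change", w)
    cy <- as.integer(sub(".*change_year=([0-9]+);.*", "\\1", inj$detail))
    expect_true(cy %in% 2013:2017)
    pre <- window_years(w)[window_years(w) < cy]
    for (y in as.character(pre)) {
      expect_null(inj$overrides[[y]]$last)
    }
    post <- inj$overrides[[as.character(cy)]]$last
    if (grepl("style=replace", inj$detail)) {
      expect_gt(name_edit_distance(toupper(post), toupper(id$last)), 2L)
    } else {
      # token insertion: original tokens survive as a subset
      expect_true(grepl(id$last, post, fixed = TRUE))
    }
  }

  # moved: both street and city keys differ from the original
  for (i in 1:10) {
    inj <- inject_error(id, "moved", w)
    my <- as.integer(sub(".*move_year=([0-9]+)", "\\1", inj$detail))
    o <- inj$overrides[[as.character(my)]]
    orig <- normalize_address(id$street, id$city)
    new <- normalize_address(o$p_street, o$p_city)
    expect_false(new$street_key == orig$street_key)
    expect_false(new$city_key == orig$city_key)
  }

  # bad taxonomy: primary replaced with an out-of-set code, secondary emptied
  inj <- inject_error(id, "bad_taxonomy", w)
  o <- inj$overrides[["2015"]]
  cnm <- taxonomy_set_for("certified_nurse_midwife")
  expect_false(o$taxonomy_primary %in% cnm$codes)
  expect_equal(o$taxonomy_secondary, "")

  # middle as first: registry first name becomes the (distinct) middle name
  inj <- inject_error(id, "middle_as_first", w)
  expect_equal(inj$overrides[["2013"]]$first, "Howard")

  # unmatched: registry side dropped entirely
  expect_true(inject_error(id, "unmatched", w)$drop_nppes)
  expect_error(inject_error(id, "chaos", w),
               class = "provlink_config_error")
})

test_that("error label frequencies converge to configured probabilities", {
  # law of large numbers at n = 5000, tolerance 3 binomial sigmas
  p <- 0.05
  co <- generate_cohort(n = 5000, seed = 29,
                        errors = error_config(p_misspelling = p,
                                              p_name_change = 0,
                                              p_moved = 0,
                                              p_bad_taxonomy = 0,
                                              p_middle_as_first = 0,
                                              p_unmatched_licensure = 0),
                        distractor_frac = 0, out_dir = tempfile())
  frac <- mean(co$truth$error_labels == "misspelling")
  sigma <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(frac - p), 3 * sigma)
})

test_that("invalid error configuration is rejected", {
  expect_error(error_config(p_misspelling = 1.5),
               class = "provlink_config_error")
  expect_error(error_config(p_misspelling = -0.1),
               class = "provlink_config_error")
  expect_error(error_config(0.5, 0.5, 0.5, 0, 0, 0),
               class = "provlink_config_error")
})
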