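# matching_engine: the seven match types, pair classification, blocking
# completeness, multi-year aggregation.

test_that("exactly seven match types in strict rank order", {
  mt <- enumerate_match_types()
  expect_equal(nrow(mt), 7L)
  expect_equal(mt$rank, 1:7)                        # strict total order
  expect_equal(anyDuplicated(mt$code), 0L)
  expect_equal(mt$code[1], "FL_CS")
  # bare-surname cell (last only, no address) is absent
  bare <- !mt$first_required & !mt$city_required & !mt$street_required
  expect_false(any(bare))
  # family structure: 4 full-name cells, 3 last-only cells
  expect_equal(sum(mt$first_required), 4L)
})

test_that("classify_match returns the strongest type whose entities agree", {
  cfg <- linkage_config()
  lic <- mk_lic()
  expect_equal(classify_match(lic, mk_np(), cfg), "FL_CS")
  # same last+city, different first and street -> L_C
  expect_equal(classify_match(
    lic, mk_np(first = "Roberta", p_street = "9 Elm St",
               m_street = "9 Elm St"), cfg), "L_C")
  # last names BLACK vs GOLD: NONE regardless of address agreement
  expect_equal(classify_match(lic, mk_np(last = "Gold"), cfg), "NONE")
  # bare surname agreement (no first, city, street) -> NONE
  expect_equal(classify_match(
    lic, mk_np(first = "Roberta", p_street = "9 Elm St",
               m_street = "9 Elm St", p_city = "Albany",
               m_city = "Albany"), cfg), "NONE")
  # misspelled last bridged under fuzzy, not under exact
  hellan <- mk_np(last = "Hellan")
  lic_helen <- mk_lic(last = "Helen")
  expect_equal(classify_match(lic_helen, hellan, cfg), "FL_CS")
  expect_equal(classify_match(lic_helen, hellan,
                              linkage_config(fuzzy = FALSE)), "NONE")
  # compound surname subset rule
  expect_equal(classify_match(mk_lic(last = "Brown Smith"),
                              mk_np(last = "Brown Jackson Smith"), cfg),
               "FL_CS")
  # initial-vs-full first name
  expect_equal(classify_match(mk_lic(first = "H"), mk_np(), cfg), "FL_CS")
  # middle-as-first remains a first-name disagreement (L_CS, not FL_CS)
  expect_equal(classify_match(mk_lic(first = "Andrew"),
                              mk_np(first = "Howard"), cfg), "L_CS")
})

test_that("classification is symmetric in the pair and monotone in agreement", {
  cfg <- linkage_config()
  # symmetry of the equality rule: swap which side carries the typo
  expect_equal(classify_match(mk_lic(last = "Hellan"),
                              mk_np(last = "Helen"), cfg),
               classify_match(mk_lic(last = "Helen"),
                              mk_np(last = "Hellan"), cfg))
  # monotonicity: adding an agreeing entity never weakens the type
  mt <- enumerate_match_types()
  rank_of <- function(code) {
    if (code == "NONE") 99L else mt$rank[mt$code == code]
  }
  base <- mk_np(first = "Roberta", p_city = "Albany", m_city = "Albany",
                p_street = "9 Elm St", m_street = "9 Elm St")
  lic <- mk_lic()
  weaker <- rank_of(classify_match(lic, base, cfg))
  stronger_first <- rank_of(classify_match(
    lic, mk_np(p_city = "Albany", m_city = "Albany",
               p_street = "9 Elm St", m_street = "9 Elm St"), cfg))
  stronger_city <- rank_of(classify_match(
    lic, mk_np(first = "Roberta", p_street = "9 Elm St",
               m_street = "9 Elm St"), cfg))
  expect_lte(stronger_first, weaker)
  expect_lte(stronger_city, weaker)
})

test_that("blocking emits the Table-1-style misspelling pair and is complete on random instances", {
  cfg <- linkage_config()
  lic <- mk_lic(first = "Helen", last = "Black")
  np <- mk_np(first = "Hellan", last = "Black")
  pairs <- block_candidates(lic, np, cfg)
  expect_equal(nrow(pairs), 1L)
  # disjoint surname lists -> empty
  expect_equal(nrow(block_candidates(mk_lic(last = "Quinn"),
                                     mk_np(last = "Patterson"), cfg)), 0L)

  # completeness oracle on adversarial random instances: every pair that
  # exhaustive classification accepts is produced by blocking
  for (s in 1:20) {
    inst <- random_instance(n_lic = 25, n_np = 25, seed = 1000 + s)
    fuzzy <- s %% 2 == 0
    cfg_s <- linkage_config(fuzzy = fuzzy)
    lic_k <- provlink:::.add_lic_keys(inst$lic)
    np_k <- provlink:::.add_np_keys(inst$np)
    all_pairs <- expand.grid(li = seq_len(25), ni = seq_len(25))
    cl <- provlink:::.classify_pairs(lic_k[all_pairs$li, ],
                                     np_k[all_pairs$ni, ], fuzzy)
    accepted <- all_pairs[cl$type != "NONE", ]
    blocked <- block_candidates(lic_k, np_k, cfg_s)
    key <- function(d) paste(d$li, d$ni)
    expect_true(all(key(accepted) %in% key(blocked)),
                info = sprintf("seed %d fuzzy=%s", s, fuzzy))
  }
})

test_that("match_all aggregates entity years across snapshots per (license, NPI)", {
  cfg <- linkage_config()
  lic <- mk_lic()
  years <- window_years(cfg$window)
  # present in all 5 snapshots -> one candidate, 5 matched years
  snaps <- setNames(lapply(years, function(y) mk_np(year = y)),
                    as.character(years))
  cand <- match_all(lic, snaps, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$years_last, paste(years, collapse = ","))
  expect_equal(cand$match_type, "FL_CS")

  # present only in the oldest snapshot
  snaps1 <- setNames(lapply(years, function(y) {
    if (y == min(years)) mk_np(year = y) else mk_np(year = y)[0, ]
  }), as.character(years))
  cand1 <- match_all(lic, snaps1, cfg)
  expect_equal(cand1$years_last, as.character(min(years)))
  expect_equal(cand1$recent_year, min(years))

  # two registry rows both matching -> two candidates
  snaps2 <- setNames(lapply(years, function(y) {
    rbind(mk_np(year = y),
          mk_np(year = y, npi = mk_npi("990000777"), first = "Roberta"))
  }), as.character(years))
  cand2 <- match_all(lic, snaps2, cfg)
  expect_equal(nrow(cand2), 2L)

  # missing snapshot year -> configuration error
  expect_error(match_all(lic, snaps[1:3], cfg),
               class = "provlink_config_error")
})

test_that("blocked matching equals exhaustive matching end to end", {
  # small window keeps the exhaustive side cheap
  for (s in 1:10) {
    inst <- random_instance(n_lic = 30, n_np = 30, seed = 2000 + s)
    win <- scoring_window(2016, 2017)
    snaps <- list(`2016` = inst$np, `2017` = inst$np)
    for (fuzzy in c(TRUE, FALSE)) {
      cfg_b <- linkage_config(window = win, fuzzy = fuzzy, block = TRUE)
      cfg_e <- linkage_config(window = win, fuzzy = fuzzy, block = FALSE)
      expect_equal(match_all(inst$lic, snaps, cfg_b),
                   match_all(inst$lic, snaps, cfg_e),
                   info = sprintf("seed %d fuzzy=%s", s, fuzzy))
    }
  }
})
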