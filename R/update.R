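# Update module: resolve accepted candidates one-to-one, merge roster and
# registry fields, and emit the final provider directory.

#' Resolve accepted candidates to one winner per license
#'
#' Per license number, the candidate with the highest total score wins;
#' ties break on stronger match type, then on the more recent registry
#' snapshot. A license whose best candidates remain tied across different
#' NPIs is ambiguous: it is excluded from the output and logged, never
#' guessed. Linkage is one-to-one globally — candidates are processed in
#' descending score order and an NPI already won is removed from contention
#' for every other license, which then falls back to its next-best
#' candidate.
#'
#' @param accepted Scored, thresholded candidate data.frame.
#' @return List with `winners` (one row per linked license) and
#'   `ambiguous` (license numbers excluded, with a reason).
#' @export
resolve_candidates <- function(accepted) {
  empty_amb <- data.frame(license_number = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  if (is.null(accepted) || nrow(accepted) == 0L) {
    return(list(winners = accepted, ambiguous = empty_amb))
  }
  dt <- data.table::as.data.table(accepted)
  total <- rank <- recent_year <- license_number <- npi <- NULL
  data.table::setorder(dt, -total, rank, -recent_year, license_number, npi)
  winners <- vector("list", nrow(dt))
  amb <- character(0)
  k <- 0L
  while (nrow(dt) > 0L) {
    top <- dt[1L]
    tied <- dt[license_number == top$license_number & total == top$total &
                 rank == top$rank & recent_year == top$recent_year]
    if (length(unique(tied$npi)) > 1L) {
      amb <- c(amb, top$license_number)
      dt <- dt[license_number != top$license_number]
    } else {
      k <- k + 1L
      winners[[k]] <- top
      dt <- dt[license_number != top$license_number & npi != top$npi]
    }
  }
  winners <- if (k > 0L) {
    as.data.frame(data.table::rbindlist(winners[seq_len(k)]))
  } else {
    as.data.frame(accepted[0L, , drop = FALSE])
  }
  ambiguous <- if (length(amb)) {
    data.frame(license_number = amb, reason = "tied candidates",
               stringsAsFactors = FALSE)
  } else empty_amb
  list(winners = winners, ambiguous = ambiguous)
}

#' Merge one resolved candidate into a directory record
#'
#' The registry record supplies the legal name, NPI, gender, phone,
#' taxonomy and both addresses (the registry is treated as the
#' legal-name source: licensure rosters often retain a pre-marriage
#' surname); the roster supplies the license number. The match type and
#' total score are carried through as provenance columns.
#'
#' @param lic One-row licensure data.frame.
#' @param rec One-row registry data.frame.
#' @param candidate One-row resolved candidate.
#' @return One-row data.frame with [directory_columns()], or `NULL` when
#'   an invariant (valid NPI, non-empty license number) fails; rejections
#'   are reported with reasons by [merge_records()].
#' @export
merge_record <- function(lic, rec, candidate) {
  if (!isTRUE(validate_npi(rec$npi[1L]))) return(NULL)
  if (!nzchar(trimws(lic$license_number[1L]))) return(NULL)
  tax <- if (nzchar(rec$taxonomy_primary[1L])) rec$taxonomy_primary[1L]
         else rec$taxonomy_secondary[1L]
  data.frame(
    last_name = rec$last[1L],
    first_name = rec$first[1L],
    npi = rec$npi[1L],
    gender = rec$gender[1L],
    phone = rec$phone[1L],
    taxonomy_code = tax,
    practice_street = rec$p_street[1L],
    practice_city = rec$p_city[1L],
    practice_state = rec$p_state[1L],
    practice_zip = rec$p_zip[1L],
    mailing_street = rec$m_street[1L],
    mailing_city = rec$m_city[1L],
    mailing_state = rec$m_state[1L],
    mailing_zip = rec$m_zip[1L],
    license_number = lic$license_number[1L],
    match_type = candidate$match_type[1L],
    total_score = as.integer(candidate$total[1L]),
    stringsAsFactors = FALSE
  )
}

#' Merge all resolved winners
#'
#' @param winners Winner table from [resolve_candidates()].
#' @param lic_df Licensure data.frame.
#' @param nppes_snapshots Named list of registry snapshots by year.
#' @return data.frame of directory records; rejected merges (invariant
#'   failures) are recorded in attribute `rejected`.
#' @export
merge_records <- function(winners, lic_df, nppes_snapshots) {
  rejected <- character(0)
  rows <- vector("list", nrow(winners))
  for (i in seq_len(nrow(winners))) {
    w <- winners[i, , drop = FALSE]
    lic <- lic_df[match(w$license_number, lic_df$license_number), ,
                  drop = FALSE]
    np <- nppes_snapshots[[as.character(w$recent_year)]]
    rec <- np[match(w$npi, np$npi), , drop = FALSE]
    m <- merge_record(lic, rec, w)
    if (is.null(m)) {
      reason <- if (!isTRUE(validate_npi(rec$npi[1L]))) "invalid npi"
                else "empty license number"
      rejected <- c(rejected, sprintf("%s: %s", w$license_number, reason))
    } else {
      rows[[i]] <- m
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) {
    as.data.frame(data.table::rbindlist(rows))
  } else {
    df <- as.data.frame(setNames(
      rep(list(character(0)), length(directory_columns())),
      directory_columns()))
    df$total_score <- integer(0)
    df
  }
  attr(out, "rejected") <- rejected
  out
}

#' Run the full linkage pipeline
#'
#' read roster -> read registry snapshots -> taxonomy filter -> location
#' filter -> multi-year matching -> temporal scoring -> threshold ->
#' one-to-one resolution -> merge -> write. Every stage's in/out/dropped
#' counts are recorded in the run report, so no record is ever lost
#' silently.
#'
#' @param lic_path Licensure roster CSV.
#' @param nppes_paths Named character vector/list, `"<year>"` -> registry
#'   snapshot CSV; must cover the scoring window.
#' @param provider_type One of [supported_provider_types()]; defaults to
#'   the config's.
#' @param config A [linkage_config()].
#' @param out_path Output directory CSV path.
#' @param report_path Optional path for the machine-readable (JSON-lines)
#'   stage report.
#' @return List: `out_path`, `directory` (the merged data.frame), `report`
#'   (class `provlink_report`), `n_written`.
#' @export
build_directory <- function(lic_path, nppes_paths,
                            provider_type = NULL,
                            config = linkage_config(),
                            out_path = tempfile(fileext = ".csv"),
                            report_path = NULL) {
  provider_type <- provider_type %||% config$provider_type
  years <- window_years(config$window)
  missing_years <- setdiff(as.character(years), names(nppes_paths))
  if (length(missing_years)) {
    .config_error(sprintf("no snapshot path for window year(s): %s",
                          paste(missing_years, collapse = ", ")))
  }
  stages <- list()
  log_stage <- function(stage, n_in, n_out, note = "") {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      n_dropped = n_in - n_out, note = note, stringsAsFactors = FALSE)
  }

  lic <- read_licensure_list(lic_path, provider_type, max(years),
                             config$licensure_columns)
  log_stage("read_licensure", attr(lic, "rows_in"), nrow(lic),
            sprintf("empty_last=%d dup=%d",
                    attr(lic, "n_dropped_empty_last"),
                    attr(lic, "n_duplicates")))

  snapshots <- list()
  n_in_np <- 0L; n_out_np <- 0L; n_quar <- 0L
  for (y in years) {
    np <- read_nppes_puf(nppes_paths[[as.character(y)]], y)
    n_in_np <- n_in_np + attr(np, "rows_in")
    n_out_np <- n_out_np + nrow(np)
    n_quar <- n_quar + nrow(attr(np, "quarantine"))
    snapshots[[as.character(y)]] <- np
  }
  log_stage("read_nppes", n_in_np, n_out_np,
            sprintf("quarantined=%d", n_quar))

  tax_dropped_npis <- character(0)
  n_in <- 0L; n_out <- 0L
  for (y in names(snapshots)) {
    n_in <- n_in + nrow(snapshots[[y]])
    f <- filter_by_taxonomy(snapshots[[y]], provider_type,
                            config$taxonomy_table)
    tax_dropped_npis <- union(tax_dropped_npis, attr(f, "dropped_npis"))
    snapshots[[y]] <- f
    n_out <- n_out + nrow(f)
  }
  log_stage("taxonomy_filter", n_in, n_out)

  n_in <- n_out; n_out <- 0L
  for (y in names(snapshots)) {
    snapshots[[y]] <- filter_by_location(snapshots[[y]], config$states)
    n_out <- n_out + nrow(snapshots[[y]])
  }
  log_stage("location_filter", n_in, n_out)

  candidates <- match_all(lic, snapshots, config)
  log_stage("match", nrow(lic), length(unique(candidates$license_number)),
            sprintf("candidates=%d", nrow(candidates)))

  scored <- score_candidates(candidates, config$window)
  accepted <- apply_threshold(scored, config$threshold)
  log_stage("score_threshold", nrow(scored), nrow(accepted))

  res <- resolve_candidates(accepted)
  log_stage("resolve", length(unique(accepted$license_number)),
            nrow(res$winners),
            sprintf("ambiguous=%d", nrow(res$ambiguous)))

  directory <- merge_records(res$winners, lic, snapshots)
  log_stage("merge", nrow(res$winners), nrow(directory),
            if (length(attr(directory, "rejected"))) "rejections" else "")

  n_written <- write_directory(directory, out_path)
  log_stage("write", nrow(directory), n_written)

  report <- structure(list(
    stages = do.call(rbind, stages),
    taxonomy_dropped_npis = tax_dropped_npis,
    ambiguous = res$ambiguous,
    provider_type = provider_type,
    config = .config_as_list(config)
  ), class = "provlink_report")
  if (!is.null(report_path)) {
    con <- file(report_path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(report$stages))) {
      writeLines(jsonlite::toJSON(as.list(report$stages[i, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  list(out_path = out_path, directory = directory, report = report,
       n_written = n_written)
}

#' @export
print.provlink_report <- function(x, ...) {
  cat(sprintf("<provlink_report> provider_type=%s\n", x$provider_type))
  print(x$stages, row.names = FALSE)
  if (nrow(x$ambiguous)) {
    cat(sprintf("ambiguous licenses: %d\n", nrow(x$ambiguous)))
  }
  invisible(x)
}
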