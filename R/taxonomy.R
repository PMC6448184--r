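# Specialty taxonomy filtering: restrict national registry records to the
# NUCC code family of the provider type being linked, before any matching.

#' Load a provider-type taxonomy table
#'
#' The table maps each provider type to its NUCC taxonomy code set. The
#' shipped default covers the three supported provider types: advanced
#' practice / regular midwife codes for certified nurse midwives, the 363L
#' nurse-practitioner family, and the 1223 dentist family. The file is a
#' plain editable TSV (`provider_type`, `code`, `label`) because NUCC
#' revises codes between releases.
#'
#' @param path TSV path; defaults to the table bundled with the package.
#' @return data.frame with columns `provider_type`, `code`, `label`.
#' @export
load_taxonomy_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxonomy_default.tsv",
                        package = "provlink", mustWork = TRUE)
  }
  if (!file.exists(path)) .io_error(sprintf("taxonomy table not found: %s",
                                            path))
  tab <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = "character"))
  .assert(all(c("provider_type", "code") %in% names(tab)),
          "taxonomy table must have columns provider_type, code",
          "provlink_format_error")
  tab$code <- toupper(trimws(tab$code))
  bad <- !grepl("^[A-Z0-9]{9}X$", tab$code)
  .assert(!any(bad), sprintf(
    "taxonomy table has malformed codes (10 chars ending in X): %s",
    paste(unique(tab$code[bad]), collapse = ", ")),
    "provlink_format_error")
  if (!"label" %in% names(tab)) tab$label <- ""
  tab
}

#' Taxonomy code set for a provider type
#'
#' @param provider_type One of the types present in the table.
#' @param table Taxonomy table; see [load_taxonomy_table()].
#' @return Object of class `taxonomy_set`: list with `provider_type` and a
#'   character vector `codes`.
#' @export
taxonomy_set_for <- function(provider_type, table = load_taxonomy_table()) {
  types <- unique(table$provider_type)
  if (!provider_type %in% types) {
    .config_error(sprintf(
      "no taxonomy set for provider_type '%s'; supported: %s",
      provider_type, paste(types, collapse = ", ")))
  }
  codes <- unique(table$code[table$provider_type == provider_type])
  .assert(length(codes) > 0L,
          sprintf("taxonomy set for '%s' is empty", provider_type),
          "provlink_config_error")
  structure(list(provider_type = provider_type, codes = codes),
            class = "taxonomy_set")
}

#' Filter registry records by taxonomy set
#'
#' Keeps a record iff its primary OR secondary taxonomy code belongs to the
#' provider type's code set. Secondary codes must be consulted: a provider
#' can carry an in-scope specialty only as the secondary entry. Input order
#' is preserved; the operation is idempotent.
#'
#' @param records NPPES-style data.frame from [read_nppes_puf()].
#' @param provider_type Provider type whose code set applies.
#' @param table Taxonomy table.
#' @return Filtered data.frame, with attribute `n_dropped`.
#' @export
filter_by_taxonomy <- function(records, provider_type,
                               table = load_taxonomy_table()) {
  set <- taxonomy_set_for(provider_type, table)
  keep <- records$taxonomy_primary %in% set$codes |
    records$taxonomy_secondary %in% set$codes
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_npis") <- unique(records$npi[!keep])
  out
}
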