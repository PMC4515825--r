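#' Read a TSV table against a schema
#'
#' Canonical tabular input: tab-separated, UTF-8, `#` comments, header
#' row. Columns named in `schema` must be present and parse cleanly to the
#' declared type; violations raise a `SchemaError` naming the offending
#' column and row.
#'
#' @param path Input path.
#' @param schema Named character vector mapping column name to type
#'   (`"character"`, `"double"`, `"integer"`).
#' @param delim Field delimiter (`"\t"` by default; pass `","` for CSV).
#' @return A tibble with the declared column types; extra columns are kept
#'   as character.
#' @export
read_table_checked <- function(path, schema, delim = "\t") {
  if (!file.exists(path)) {
    tt_abort(paste0("No such file: ", path), "schema_error")
  }
  raw <- readr::read_delim(
    path,
    delim = delim, comment = "#", trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0L) {
    tt_abort(
      paste0("Missing column(s): ", paste(missing, collapse = ", ")),
      "schema_error"
    )
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("double", "integer")) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(parsed))
      if (length(bad) > 0L) {
        tt_abort(
          paste0(
            "Column '", col, "' is not numeric at row ", bad[1],
            " (value '", raw[[col]][bad[1]], "')."
          ),
          "schema_error"
        )
      }
      raw[[col]] <- if (type == "integer") as.integer(parsed) else parsed
    }
  }
  raw
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

tt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "thiamintargets")
  if (path == "") {
    tt_abort(paste0("Packaged fixture not found: ", file), "schema_error")
  }
  path
}

#' Packaged affinity-purification table
#'
#' Step-wise elution of the thiamin-phosphate-hydrolyzing activity from
#' the thiamin- and DMHT-modified sorbents: protein applied, per-step
#' eluted mg and percent, and the eluate's specific ThDPase activity
#' (nmol phosphate per min per mg protein). The load fraction's specific
#' activity is not recorded, so a fold-purification cannot be computed
#' from this table.
#'
#' @return Tibble, one row per bait and elution step.
#' @export
load_purification_table <- function() {
  read_table_checked(
    tt_extdata("table1_purification.tsv"),
    c(
      bait = "character", protein_applied_mg = "double", step = "integer",
      eluant = "character", eluted_mg = "double", eluted_pct = "double",
      specific_activity = "double"
    )
  )
}

#' Packaged known-binder table
#'
#' Proteins documented to bind thiamin compounds (or to partner with such
#' proteins) among the affinity eluates, with `+`/`-` membership flags for
#' the thiamin- and thiazolium (DMHT)-eluted proteomes and the documented
#' interaction partner.
#'
#' @return Tibble with columns `protein_id`, `protein_name`, `thiamin`,
#'   `thiazolium`, `partner`.
#' @export
load_known_binders <- function() {
  read_table_checked(
    tt_extdata("table2_known_binders.tsv"),
    c(
      protein_id = "character", protein_name = "character",
      thiamin = "character", thiazolium = "character", partner = "character"
    )
  )
}

#' Packaged literature interaction table
#'
#' Published physical/functional interactions among eluted proteins,
#' shipped as a data fixture only (no analysis is performed on it).
#'
#' @return Tibble with columns `protein`, `partner`, `thiamin`,
#'   `thiazolium`, `interaction_type`.
#' @export
load_literature_interactions <- function() {
  read_table_checked(
    tt_extdata("table3_interactions.tsv"),
    c(
      protein = "character", partner = "character", thiamin = "character",
      thiazolium = "character", interaction_type = "character"
    )
  )
}

#' Packaged toy FASTA file
#'
#' Three short synthetic records, one of which carries a planted
#' `ISSTN` instance of the hybrid serine-stretch pattern.
#'
#' @return Path to the FASTA file.
#' @export
example_fasta <- function() {
  tt_extdata("toy_sequences.fasta")
}

#' Default concentration grids of the inhibition assays
#'
#' The six inhibitor levels (0, 1, 2.5, 5, 9, 15 mM) used in the
#' pyridoxal-kinase inhibition series, and substrate grids spanning up to
#' the quasi-saturating assay concentrations (0.6 mM pyridoxal, 1.8 mM
#' MgATP).
#'
#' @return List with `I`, `S_pyridoxal`, `S_mgatp` (all mM).
#' @export
assay_grids <- function() {
  list(
    I = c(0, 1, 2.5, 5, 9, 15),
    S_pyridoxal = c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
    S_mgatp = c(0.2, 0.4, 0.8, 1.2, 1.5, 1.8)
  )
}

#' Reference inhibition constants of pyridoxal kinase
#'
#' The fitted inhibition mechanisms and constants for human pyridoxal
#' kinase inhibited by thiamin and ThDP, used as generating truth for the
#' simulation-based recovery checks.
#'
#' @return Tibble: `inhibitor`, `varied_substrate`, `fixed_substrate`,
#'   `mechanism`, `Ki_mM`.
#' @export
pdxk_inhibition_constants <- function() {
  tibble::tibble(
    inhibitor = c("thiamin", "thiamin", "ThDP", "ThDP"),
    varied_substrate = c("pyridoxal", "MgATP", "pyridoxal", "MgATP"),
    fixed_substrate = c("MgATP", "pyridoxal", "MgATP", "pyridoxal"),
    mechanism = c("competitive", "non-competitive", "non-competitive", "competitive"),
    Ki_mM = c(2.2, 6.6, 10.4, 3.3)
  )
}
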