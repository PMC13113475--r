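#' Diet composition tables
#'
#' A diet profile describes one ration by its metabolisable energy intake
#' (MEI, MJ/day) and nutrient concentrations as percent of dietary dry
#' matter (DM): crude protein (CP), fatty acids (FA), ether extract (EE),
#' neutral and acid detergent fibre (NDF, ADF) and forage proportion.
#' Profiles belong to a cohort, `"lactating"` or `"dry"`.
#'
#' @name diet-profiles
#' @keywords internal
NULL

DIET_COLUMNS <- c("diet_id", "cohort", "mei", "cp_pct", "fa_pct", "ee_pct",
                  "ndf_pct", "adf_pct", "forage_pct")

#' Default column-name map for diet CSV files
#'
#' Maps the on-disk CSV header (`diet_id, cohort, mei_mj_d, cp_pct, ...`)
#' to the internal field names.
#'
#' @return Named character vector, names are internal fields, values the
#'   CSV column names.
#' @export
diet_csv_schema <- function() {
  c(diet_id = "diet_id", cohort = "cohort", mei = "mei_mj_d",
    cp_pct = "cp_pct", fa_pct = "fa_pct", ee_pct = "ee_pct",
    ndf_pct = "ndf_pct", adf_pct = "adf_pct", forage_pct = "forage_pct")
}

validate_diets <- function(diets) {
  stopifnot(is.data.frame(diets))
  missing <- setdiff(DIET_COLUMNS, names(diets))
  if (length(missing) > 0L) {
    stop("diet table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(diets$diet_id)) {
    stop("duplicate diet_id in diet table")
  }
  bad_cohort <- !diets$cohort %in% c("lactating", "dry")
  if (any(bad_cohort)) {
    stop("diet ", diets$diet_id[which(bad_cohort)[1]],
         ": cohort must be 'lactating' or 'dry'")
  }
  pct_cols <- c("cp_pct", "fa_pct", "ee_pct", "ndf_pct", "adf_pct",
                "forage_pct")
  for (col in pct_cols) {
    bad <- !is.finite(diets[[col]]) | diets[[col]] < 0 | diets[[col]] > 100
    if (any(bad)) {
      stop("diet ", diets$diet_id[which(bad)[1]], ": field ", col,
           " must lie in [0, 100]")
    }
  }
  bad_mei <- !is.finite(diets$mei) | diets$mei <= 0
  if (any(bad_mei)) {
    stop("diet ", diets$diet_id[which(bad_mei)[1]], ": field mei must be > 0")
  }
  # ADF is a subset of the NDF fibre fraction
  bad_fibre <- diets$adf_pct > diets$ndf_pct
  if (any(bad_fibre)) {
    stop("diet ", diets$diet_id[which(bad_fibre)[1]],
         ": field adf_pct exceeds ndf_pct")
  }
  invisible(diets)
}

new_diet_set <- function(df) {
  df$diet_id <- as.character(df$diet_id)
  df <- df[DIET_COLUMNS]
  validate_diets(df)
  rownames(df) <- NULL
  class(df) <- c("diet_set", "data.frame")
  df
}

#' Read diet profiles from a CSV file
#'
#' @param path Path to a comma-separated file with a header row.
#' @param schema Named character vector mapping internal field names to CSV
#'   column names; defaults to [diet_csv_schema()].
#' @return A `diet_set` data frame, one validated row per input row, in
#'   file order. An empty file yields an empty set with a warning.
#' @export
load_diets <- function(path, schema = diet_csv_schema()) {
  if (!file.exists(path)) stop("diet file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(diet_id = "character"))
  if (nrow(raw) == 0L) {
    warning("diet file ", path, " contains no rows")
    empty <- as.data.frame(
      stats::setNames(
        c(list(character(0), character(0)), rep(list(numeric(0)), 7)),
        DIET_COLUMNS))
    class(empty) <- c("diet_set", "data.frame")
    return(empty)
  }
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0L) {
    stop("diet file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- raw[unname(schema)]
  names(df) <- names(schema)
  new_diet_set(df)
}

#' Write diet profiles to CSV
#'
#' Round-trips through [load_diets()]: re-reading the file reproduces the
#' identical profile set.
#'
#' @param diets A `diet_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diets <- function(diets, path) {
  df <- as.data.frame(diets)[DIET_COLUMNS]
  names(df) <- unname(diet_csv_schema())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged set of 15 UK dairy diets
#'
#' Fifteen rations representative of UK commercial dairy systems: diets
#' 1--13 for lactating cows, diets 14--15 for dry cows. Shipped as a CSV
#' fixture inside the package and read verbatim.
#'
#' @return A `diet_set` with 15 rows.
#' @export
packaged_diets <- function() {
  path <- system.file("extdata", "uk_dairy_diets.csv", package = "ch4combine",
                      mustWork = TRUE)
  load_diets(path)
}
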