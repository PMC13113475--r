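#' Unit-aware registry of published methane prediction equations
#'
#' Each registry record is a linear (or linear-times-DMI) form in diet
#' variables with per-term unit metadata, evaluated to g CH4/day and
#' normalised to g CH4/kg DM by the diet's dry matter intake.
#'
#' @name equation-registry
#' @keywords internal
NULL

#' Megajoules of energy per gram of methane
#' @keywords internal
MJ_PER_G_CH4 <- 0.05565

EQ_VARIABLES <- c("DMI", "MEI", "NDF", "ADF", "EE", "FA", "CP", "ASH",
                  "FORAGE")
EQ_UNITS <- c("kg_dm_per_day", "mj_per_day", "pct_dm", "kg_per_day_intake")
EQ_SHAPES <- c("LINEAR", "LINEAR_TIMES_DMI")
EQ_OUTPUT_UNITS <- c("MJ_PER_DAY", "G_PER_DAY")

#' Convert daily methane energy to mass
#'
#' Methane carries 55.65 kJ/g, so 0.05565 MJ of methane energy is one gram.
#'
#' @param e Methane emission as MJ/day (finite, vectorised).
#' @return The same emission as g CH4/day (`e / 0.05565`).
#' @export
energy_to_mass <- function(e) {
  if (any(!is.finite(e))) stop("energy value must be finite")
  e / MJ_PER_G_CH4
}

validate_record <- function(rec) {
  req <- c("eq_id", "source", "shape", "output_unit", "intercept", "terms")
  missing <- setdiff(req, names(rec))
  if (length(missing) > 0L) {
    stop("equation record is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  if (!rec$shape %in% EQ_SHAPES) {
    stop("equation ", rec$eq_id, ": unknown shape '", rec$shape, "'")
  }
  if (!rec$output_unit %in% EQ_OUTPUT_UNITS) {
    stop("equation ", rec$eq_id, ": unknown output unit '", rec$output_unit,
         "'")
  }
  if (!is.numeric(rec$intercept)) {
    stop("equation ", rec$eq_id, ": intercept must be numeric")
  }
  for (term in rec$terms) {
    if (!is.numeric(term$coef)) {
      stop("equation ", rec$eq_id, ": term coefficient must be numeric")
    }
    if (!term$var %in% EQ_VARIABLES) {
      stop("equation ", rec$eq_id, ": unknown variable '", term$var, "'")
    }
    if (!term$unit %in% EQ_UNITS) {
      stop("equation ", rec$eq_id, ": unknown unit '", term$unit, "'")
    }
  }
  rec
}

#' Load an equation registry file
#'
#' The registry is a YAML document with a `metadata` block (equation and
#' source counts, literature-screening cascade) and an `equations` list;
#' see the packaged copy returned by [packaged_registry()] for the format.
#'
#' @param path Path to a registry YAML file.
#' @return An `equation_registry`: a list of validated records with the
#'   metadata attached as attribute `metadata`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$equations)) stop("registry file has no 'equations' list")
  records <- lapply(doc$equations, validate_record)
  ids <- vapply(records, `[[`, "", "eq_id")
  if (anyDuplicated(ids)) {
    stop("duplicate eq_id in registry: ", ids[duplicated(ids)][1])
  }
  names(records) <- ids
  structure(records, metadata = doc$metadata, class = "equation_registry")
}

#' The packaged 32-equation registry
#'
#' Thirty-two published enteric methane prediction equations from five
#' source publications, transcribed with per-term unit metadata.
#'
#' @return An `equation_registry` of 32 records.
#' @export
packaged_registry <- function() {
  path <- system.file("extdata", "equation_registry.yaml",
                      package = "ch4combine", mustWork = TRUE)
  load_registry(path)
}

resolve_variable <- function(var, unit, diet, eq_id) {
  conc <- switch(var,
                 DMI = NA_real_, MEI = NA_real_,
                 NDF = diet$ndf_pct, ADF = diet$adf_pct, EE = diet$ee_pct,
                 FA = diet$fa_pct, CP = diet$cp_pct, ASH = diet$ash_pct,
                 FORAGE = diet$forage_pct)
  value <- switch(unit,
                  kg_dm_per_day = if (var == "DMI") diet$dmi else NA_real_,
                  mj_per_day = if (var == "MEI") diet$mei else NA_real_,
                  pct_dm = conc,
                  kg_per_day_intake = conc / 100 * diet$dmi)
  if (is.null(value) || any(is.na(value))) {
    stop("equation ", eq_id, ": cannot resolve variable ", var,
         " (unit ", unit, ") from the diet")
  }
  value
}

#' Evaluate one equation on one completed diet
#'
#' Resolves each term's variable at the unit the source publication used
#' (daily intakes are derived as `pct/100 * DMI`), applies the
#' linear-times-DMI shape where declared, and converts MJ/day outputs to
#' g/day by [energy_to_mass()]. Negative predictions are returned with a
#' warning rather than clamped.
#'
#' @param eq A validated equation record.
#' @param diet One row of a `completed_diet_set`.
#' @return Predicted emission, g CH4/day.
#' @export
evaluate_daily <- function(eq, diet) {
  linear <- eq$intercept
  for (term in eq$terms) {
    value <- resolve_variable(term$var, term$unit, diet, eq$eq_id)
    contrib <- term$coef * value
    if (isTRUE(term$energy_to_mass)) contrib <- energy_to_mass(contrib)
    linear <- linear + contrib
  }
  out <- if (eq$shape == "LINEAR_TIMES_DMI") linear * diet$dmi else linear
  if (eq$output_unit == "MJ_PER_DAY") out <- energy_to_mass(out)
  if (any(out < 0)) {
    warning("equation ", eq$eq_id, " predicts negative emissions; ",
            "value returned unclamped")
  }
  out
}

#' Apply every registry equation to every completed diet
#'
#' @param registry An `equation_registry`.
#' @param diets A `completed_diet_set`.
#' @return A `prediction_set`: one row per (equation, diet) pair carrying
#'   the daily and per-kg-DM emission plus all candidate predictors.
#' @export
apply_all <- function(registry, diets) {
  if (!inherits(diets, "completed_diet_set")) {
    stop("diets must be completed (see complete_diets) before evaluation")
  }
  rows <- lapply(registry, function(eq) {
    daily <- vapply(seq_len(nrow(diets)),
                    function(i) evaluate_daily(eq, diets[i, ]), 0)
    data.frame(eq_id = eq$eq_id, diet_id = diets$diet_id,
               ch4_g_per_day = daily,
               ch4_g_per_kg_dm = daily / diets$dmi,
               dmi = diets$dmi, mei = diets$mei, me_conc = diets$me_conc,
               ge_conc = diets$ge_conc, ndf_pct = diets$ndf_pct,
               adf_pct = diets$adf_pct, cp_pct = diets$cp_pct,
               ee_pct = diets$ee_pct, fa_pct = diets$fa_pct,
               ash_pct = diets$ash_pct, forage_pct = diets$forage_pct,
               stringsAsFactors = FALSE)
  })
  new_prediction_set(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

PREDICTION_COLUMNS <- c("eq_id", "diet_id", "ch4_g_per_day",
                        "ch4_g_per_kg_dm", "dmi", "mei", "me_conc",
                        "ge_conc", "ndf_pct", "adf_pct", "cp_pct", "ee_pct",
                        "fa_pct", "ash_pct", "forage_pct")

new_prediction_set <- function(df) {
  missing <- setdiff(PREDICTION_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("prediction table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[PREDICTION_COLUMNS]
  num <- df[setdiff(PREDICTION_COLUMNS, c("eq_id", "diet_id"))]
  if (!all(vapply(num, function(x) all(is.finite(x)), TRUE))) {
    stop("prediction table contains non-finite values")
  }
  # per-kg-DM response is the daily emission normalised by intake, exactly
  if (max(abs(df$ch4_g_per_kg_dm - df$ch4_g_per_day / df$dmi)) > 1e-8) {
    stop("ch4_g_per_kg_dm is not ch4_g_per_day / dmi")
  }
  rownames(df) <- NULL
  class(df) <- c("prediction_set", "data.frame")
  df
}

#' Per-diet emission extremes
#'
#' @param preds A `prediction_set`, or any data frame with `diet_id` and
#'   `ch4_g_per_kg_dm` columns (e.g. a published per-diet envelope recast
#'   as records).
#' @return Data frame of per-diet `min` and `max` (g CH4/kg DM) in first-
#'   appearance diet order, with attributes `global_min`, `global_max` and
#'   `spread = global_max - global_min`.
#' @export
diet_extremes <- function(preds) {
  if (nrow(preds) == 0L) stop("prediction set is empty")
  ids <- unique(preds$diet_id)
  out <- data.frame(
    diet_id = ids,
    min = vapply(ids, function(d)
      min(preds$ch4_g_per_kg_dm[preds$diet_id == d]), 0),
    max = vapply(ids, function(d)
      max(preds$ch4_g_per_kg_dm[preds$diet_id == d]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "global_min") <- min(out$min)
  attr(out, "global_max") <- max(out$max)
  attr(out, "spread") <- max(out$max) - min(out$min)
  out
}

#' Published per-diet emission envelope
#'
#' The per-diet minimum and maximum emissions over the 32-equation library
#' as published for the 15 packaged diets, recast as a two-record-per-diet
#' `prediction_set`-like table usable with [diet_extremes()].
#'
#' @return Data frame with columns `diet_id`, `ch4_g_per_kg_dm`.
#' @export
reference_extremes_records <- function() {
  path <- system.file("extdata", "reference_extremes.csv",
                      package = "ch4combine", mustWork = TRUE)
  env <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(diet_id = "character"))
  data.frame(diet_id = rep(env$diet_id, 2L),
             ch4_g_per_kg_dm = c(env$min_g_kg_dm, env$max_g_kg_dm),
             stringsAsFactors = FALSE)
}
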