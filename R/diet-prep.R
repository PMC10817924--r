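#' Default mapping from the 9-level FFQ frequency scale to times per day
#'
#' The instrument records intake on a 9-level ordinal scale anchored at
#' "never" (level 1) and ">= 4 times per day" (level 9). Only the endpoints
#' are fixed by the instrument; the interior values follow common FFQ
#' conventions (0.5/month, 1-3/month, 1/week, 2-3/week, 4-6/week, 1/day,
#' 2-3/day) and can be overridden.
#'
#' @format Named numeric vector of length 9 (times/day).
#' @export
default_frequency_map <- c(
  never = 0,
  half_per_month = 0.5 / 30,
  one_three_per_month = 2 / 30,
  one_per_week = 1 / 7,
  two_three_per_week = 2.5 / 7,
  four_six_per_week = 5 / 7,
  one_per_day = 1,
  two_three_per_day = 2.5,
  four_plus_per_day = 4)

#' Map ordinal FFQ frequency levels to frequencies per day
#'
#' @param level Integer vector of ordinal levels in 1..9.
#' @param mapping Monotone non-decreasing numeric vector of length 9 with
#'   `mapping[1] == 0` and `mapping[9] == 4` by default.
#' @return Numeric vector of frequencies per day.
#' @export
map_frequency_levels <- function(level, mapping = default_frequency_map) {
  if (length(mapping) != 9L || is.unsorted(mapping))
    stop("mapping must be a monotone non-decreasing vector of length 9")
  lv <- level[!is.na(level)]
  if (any(lv != as.integer(lv)) || any(lv < 1L) || any(lv > 9L))
    stop("frequency levels must be integers in 1..9")
  unname(mapping[level])
}

#' Energy-density adjustment of a dietary exposure
#'
#' Expresses intake per `per` kcal of total energy (default 1000 kcal), the
#' energy-density method of energy adjustment. Linear in intake and invariant
#' to jointly rescaling intake and energy.
#'
#' @param intake Amount (g/day) or frequency (times/day).
#' @param energy Total energy intake, kcal/day; must be positive.
#' @param per Reference energy, kcal (default 1000).
#' @return Intake per `per` kcal.
#' @export
energy_adjust <- function(intake, energy, per = 1000) {
  if (any(!is.na(energy) & energy <= 0))
    stop("energy must be positive for energy-density adjustment")
  intake / energy * per
}

#' Build hypothesis-driven dietary components from per-food amounts
#'
#' Each component is the sum of its constituent foods' amounts (g/day), as in
#' food-group tables that define e.g. red meat, processed meat, or their
#' union. Precomputed nutrient totals (calcium, fiber) are carried as their
#' own columns and referenced directly.
#'
#' @param diet Diet matrix with `amt_<food>` columns (and possibly nutrient
#'   total columns).
#' @param defs Named list: component name -> character vector of food names
#'   (matched against `amt_` columns) or of full column names.
#' @return Data frame: `participant_id` plus one amount column per component.
#' @export
build_apriori_components <- function(diet, defs) {
  out <- data.frame(participant_id = diet$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(defs)) {
    cols <- defs[[nm]]
    resolved <- ifelse(paste0("amt_", cols) %in% names(diet),
                       paste0("amt_", cols),
                       cols)
    bad <- resolved[!resolved %in% names(diet)]
    if (length(bad))
      stop("component '", nm, "' references unknown foods: ",
           paste(bad, collapse = ", "))
    out[[nm]] <- rowSums(as.matrix(diet[, resolved, drop = FALSE]))
  }
  out
}

#' Categorize alcohol intake at three levels
#'
#' Zero intake forms its own category (a mixed group of abstainers and former
#' consumers); non-zero intakes are split at the sex-specific median of the
#' non-zero intakes. Values exactly at the median are classed "below"
#' (a documented convention, controlled by `ties`).
#'
#' @param intakes Non-negative alcohol intakes, g/day.
#' @param sex Character/factor vector of the same length.
#' @param ties Either "below" (default) or "above": category for intakes
#'   exactly equal to the sex-specific median.
#' @return Factor with levels `zero`, `below`, `above`.
#' @export
categorize_alcohol <- function(intakes, sex, ties = c("below", "above")) {
  ties <- match.arg(ties)
  if (any(intakes < 0, na.rm = TRUE)) stop("alcohol intakes must be >= 0")
  stopifnot(length(intakes) == length(sex))
  out <- rep(NA_character_, length(intakes))
  for (s in unique(sex[!is.na(sex)])) {
    idx <- which(sex == s & !is.na(intakes))
    nz <- intakes[idx][intakes[idx] > 0]
    if (!length(nz))
      stop("no non-zero alcohol intakes in sex stratum '", s,
           "'; median undefined")
    med <- stats::median(nz)
    x <- intakes[idx]
    out[idx] <- ifelse(x == 0, "zero",
                       if (ties == "below") ifelse(x <= med, "below", "above")
                       else ifelse(x < med, "below", "above"))
  }
  factor(out, levels = c("zero", "below", "above"))
}

#' Table of hypothesis-driven dietary component constituents
#'
#' The food-group definitions used for real FFQ data: dairy products, dietary
#' calcium, wholegrain, fiber, fruit and vegetables, red meat, processed
#' meat, red and processed meat (which additionally includes hamburger), and
#' total alcohol. Names must match the diet matrix's food or nutrient
#' columns; calcium, wholegrain and fiber reference precomputed totals.
#'
#' @return Named list of character vectors of constituent column names.
#' @export
table_components <- function() {
  list(
    dairy_products = c("creme_fraiche", "cheese", "filmjolk_yoghurt",
                       "milk_0_5", "milk_1_5", "milk_3", "filmjolk_1_5"),
    dietary_calcium = "calcium_mg",
    wholegrain = "wholegrain_g",
    fiber = "fiber_g",
    fruit_and_vegetables = c("berries", "apple_pear", "citrus", "banana",
                             "cabbage", "root_vegetables", "tomato_cucumber",
                             "lettuce", "spinach_broccoli"),
    red_meat = c("minced_meat_dishes", "meat_stew", "steak_chop"),
    processed_meat = c("bacon_sausage_main", "sausage", "meat_liver_pate"),
    red_and_processed_meat = c("minced_meat_dishes", "meat_stew",
                               "steak_chop", "hamburger",
                               "bacon_sausage_main", "sausage",
                               "meat_liver_pate"),
    total_alcohol = c("light_beer", "medium_beer", "strong_beer", "wine",
                      "spirits"))
}

#' Read component definitions from a YAML file
#'
#' @param path YAML file mapping component names to lists of food names.
#' @return Named list of character vectors.
#' @export
read_component_defs <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML component definitions")
  defs <- yaml::read_yaml(path)
  lapply(defs, as.character)
}

#' Assemble analysis-ready dietary exposures
#'
#' Convenience wrapper used by the pipeline: maps frequency levels to
#' frequencies/day, energy-adjusts them (per 1000 kcal), builds a priori
#' component amounts (also energy-adjusted), and returns both raw and
#' adjusted versions.
#'
#' @param diet Diet matrix from [generate_cohort()] or read from TSV.
#' @param defs Component definitions (food-index lists are translated to the
#'   synthetic food names).
#' @return List with `freq_level` (the reported 9-level codes, the input to
#'   pattern derivation), `freq_day`, `freq_adj` (participants x foods
#'   matrices) and `components`, `components_adj` (data frames).
#' @export
derive_exposures <- function(diet, defs = NULL) {
  freq_cols <- grep("^freq_", names(diet), value = TRUE)
  freq_level <- as.matrix(diet[freq_cols])
  colnames(freq_level) <- sub("^freq_", "", freq_cols)
  rownames(freq_level) <- diet$participant_id
  freq_day <- vapply(diet[freq_cols], map_frequency_levels,
                     numeric(nrow(diet)))
  colnames(freq_day) <- sub("^freq_", "", freq_cols)
  rownames(freq_day) <- diet$participant_id
  freq_adj <- energy_adjust(freq_day, diet$energy_kcal)
  comps <- comps_adj <- NULL
  if (!is.null(defs)) {
    defs <- lapply(defs, function(d)
      if (is.numeric(d)) sprintf("food_%02d", d) else d)
    comps <- build_apriori_components(diet, defs)
    comps_adj <- comps
    for (nm in names(defs))
      comps_adj[[nm]] <- energy_adjust(comps[[nm]], diet$energy_kcal)
  }
  list(freq_level = freq_level, freq_day = freq_day, freq_adj = freq_adj,
       components = comps, components_adj = comps_adj)
}
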