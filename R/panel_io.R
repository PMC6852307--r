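#' Crop-area panels
#'
#' A crop-area panel is a tibble with one row per (entity, crop, year)
#' holding the harvested area in hectares. It is the universal input of the
#' package: every analysis function takes a panel (or something derived from
#' one) as its first argument. `as_crop_area_panel()` validates an arbitrary
#' data frame; [read_crop_area_table()] builds one from a FAOSTAT-style CSV.
#'
#' Invariants enforced: columns `entity` (character), `crop` (character),
#' `year` (integer), `area` (double, hectares); `area >= 0`; no duplicate
#' (entity, crop, year) keys; at least one record. Missing combinations are
#' interpreted as zero area during aggregation but are never materialised as
#' rows, mirroring how FAOSTAT omits non-cultivated crops.
#'
#' @param x A data frame with columns `entity`, `crop`, `year`, `area`.
#' @param provenance Free-text note on where the records came from.
#' @return A tibble of class `crop_area_panel` with attributes `provenance`
#'   and `unit` (always `"ha"`).
#' @examples
#' as_crop_area_panel(data.frame(
#'   entity = "Atlantis", crop = "wheat", year = 1961:1963, area = c(1, 2, 3)
#' ))
#' @export
as_crop_area_panel <- function(x, provenance = "user") {
  required <- c("entity", "crop", "year", "area")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_cropdivr(
      paste0("panel is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "cropdivr_schema_error"
    )
  }
  out <- as_tibble(x)[required]
  out$entity <- trimws(as.character(out$entity))
  out$crop <- trimws(as.character(out$crop))
  out$year <- as.integer(out$year)
  out$area <- as.double(out$area)
  if (nrow(out) == 0) {
    stop_cropdivr("panel must contain at least one record", "cropdivr_validation_error")
  }
  if (anyNA(out$area) || anyNA(out$year)) {
    stop_cropdivr("panel contains missing year or area values", "cropdivr_validation_error")
  }
  if (any(out$area < 0)) {
    bad <- out[out$area < 0, ][1, ]
    stop_cropdivr(
      sprintf("negative area for (%s, %s, %d)", bad$entity, bad$crop, bad$year),
      "cropdivr_validation_error"
    )
  }
  key <- paste(out$entity, out$crop, out$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), ][1, ]
    stop_cropdivr(
      sprintf("duplicate key (%s, %s, %d)", dup$entity, dup$crop, dup$year),
      "cropdivr_duplicate_key_error"
    )
  }
  structure(
    out,
    class = c("crop_area_panel", class(out)),
    provenance = provenance,
    unit = "ha"
  )
}

# Reattach panel class/attributes after dplyr verbs strip them.
restore_panel <- function(x, template) {
  structure(
    as_tibble(x),
    class = c("crop_area_panel", class(as_tibble(x))),
    provenance = attr(template, "provenance", exact = TRUE) %||% "derived",
    unit = "ha"
  )
}

#' Read a FAOSTAT-dialect crop-area table
#'
#' Parses a delimited text file (or literal text) in the FAOSTAT bulk
#' "Production_Crops" long layout and returns a validated crop-area panel.
#' Rows with a blank/missing value are dropped (a count is reported via a
#' message); an optional element filter keeps only harvested-area rows when
#' the file mixes elements.
#'
#' @param source Path to a delimited file, or a literal character vector of
#'   CSV text (anything containing a newline is treated as literal text).
#' @param schema Named list mapping panel fields to column names. Defaults
#'   follow the FAOSTAT bulk dialect: `entity = "Area"`, `crop = "Item"`,
#'   `year = "Year"`, `area = "Value"`, plus optional `element` (column) and
#'   `element_keep` (values to retain, e.g. `"Area harvested"`), and
#'   `unit_factor` — multiplier to hectares when the source is not already
#'   in ha (default 1).
#' @param delim Field delimiter, default `","`.
#' @return A [crop_area_panel][as_crop_area_panel].
#' @seealso [write_crop_area_table()] for the inverse.
#' @export
read_crop_area_table <- function(source,
                                 schema = list(),
                                 delim = ",") {
  schema <- modifyList(
    list(entity = "Area", crop = "Item", year = "Year", area = "Value",
         element = NULL, element_keep = NULL, unit_factor = 1),
    schema
  )
  raw <- readr::read_delim(
    if (length(source) == 1 && !grepl("\n", source)) source else I(paste(source, collapse = "\n")),
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  needed <- unlist(schema[c("entity", "crop", "year", "area")], use.names = FALSE)
  if (!is.null(schema$element)) needed <- c(needed, schema$element)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_cropdivr(
      paste0("input is missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "cropdivr_schema_error"
    )
  }
  if (!is.null(schema$element) && !is.null(schema$element_keep)) {
    raw <- raw[raw[[schema$element]] %in% schema$element_keep, , drop = FALSE]
  }
  value <- suppressWarnings(as.numeric(raw[[schema$area]]))
  blank <- is.na(value) | !nzchar(trimws(raw[[schema$area]] %||% ""))
  n_dropped <- sum(blank)
  if (n_dropped > 0) {
    inform(sprintf("read_crop_area_table: dropped %d row(s) with blank/non-numeric values", n_dropped))
  }
  keep <- !blank
  out <- tibble(
    entity = raw[[schema$entity]][keep],
    crop = raw[[schema$crop]][keep],
    year = as.integer(raw[[schema$year]][keep]),
    area = value[keep] * schema$unit_factor
  )
  panel <- as_crop_area_panel(out, provenance = if (length(source) == 1 && !grepl("\n", source)) source else "inline text")
  attr(panel, "n_dropped") <- n_dropped
  panel
}

#' Write a crop-area panel as tidy CSV
#'
#' Writes `entity, crop, year, area` with `.` decimal separator and UTF-8
#' encoding so that [read_crop_area_table()] with
#' `schema = list(entity = "entity", crop = "crop", year = "year",
#' area = "area")` round-trips exactly.
#'
#' @param panel A crop-area panel.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crop_area_table <- function(panel, path) {
  panel <- as_crop_area_panel(panel)
  df <- as_tibble(panel)[c("entity", "crop", "year", "area")]
  readr::write_csv(df[order(df$entity, df$crop, df$year), ], path)
  invisible(path)
}

#' Bundled successor-state harmonization rules
#'
#' Entities that subdivided after 1961 report later years under successor
#' names; to compare endpoints, successor areas are re-aggregated under the
#' 1961 reporting entity. The bundled set covers the six standard merges:
#' Czechoslovakia, Ethiopia PDR, Sudan (former), USSR (14 republics),
#' Yugoslav SFR, and Belgium-Luxembourg.
#'
#' @return A tibble with columns `target` and `source`, one row per
#'   successor entity.
#' @export
default_harmonization_rules <- function() {
  path <- system.file("extdata", "harmonization_rules.csv", package = "cropdivr", mustWork = TRUE)
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_harmonization_rules(rules)
  rules
}

validate_harmonization_rules <- function(rules) {
  if (!all(c("target", "source") %in% names(rules))) {
    stop_cropdivr("harmonization rules need columns target, source", "cropdivr_schema_error")
  }
  if (nrow(rules) > 0 && anyDuplicated(rules$source)) {
    stop_cropdivr(
      sprintf("entity '%s' appears as source in more than one rule",
              rules$source[duplicated(rules$source)][1]),
      "cropdivr_validation_error"
    )
  }
  invisible(rules)
}

#' Merge successor entities into their historical reporting entity
#'
#' For each rule, areas of the successor entities are summed (per crop and
#' year) into the target entity; successor rows are removed. Entities not
#' named by any rule pass through untouched. Total area over all (crop,
#' year) cells is conserved exactly.
#'
#' @param panel A crop-area panel.
#' @param rules Tibble with columns `target`, `source` (one row per
#'   successor); defaults to [default_harmonization_rules()]. An empty
#'   tibble is the identity.
#' @return A harmonized crop-area panel.
#' @export
harmonize_entities <- function(panel, rules = default_harmonization_rules()) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  validate_harmonization_rules(rules)
  if (nrow(rules) == 0) {
    return(panel)
  }
  affected <- panel$entity %in% rules$source
  if (!any(affected)) {
    return(panel)
  }
  to_merge <- as_tibble(panel)[affected, ]
  to_merge$target <- rules$target[match(to_merge$entity, rules$source)]
  # a successor record clashing with a record already filed under the target
  # for the same (crop, year) would double-count: refuse
  existing_target <- as_tibble(panel)[panel$entity %in% unique(rules$target), ]
  clash <- inner_join(
    distinct(to_merge[c("target", "crop", "year")]),
    existing_target[c("entity", "crop", "year")],
    by = c(target = "entity", "crop", "year")
  )
  if (nrow(clash) > 0) {
    stop_cropdivr(
      sprintf("merge conflict: target '%s' already has a record for (%s, %d)",
              clash$target[1], clash$crop[1], clash$year[1]),
      "cropdivr_merge_conflict_error"
    )
  }
  merged <- to_merge %>%
    group_by(entity = .data$target, .data$crop, .data$year) %>%
    summarise(area = sum(.data$area), .groups = "drop")
  out <- bind_rows(as_tibble(panel)[!affected, ], merged)
  restore_panel(out[order(out$entity, out$crop, out$year), ], panel)
}

#' Exclude entities below a minimum agricultural area at a baseline year
#'
#' Removes (for all years) every entity whose total harvested area across
#' crops at `baseline_year` falls strictly below `threshold_km2` square
#' kilometres (converted internally: 1 km^2 = 100 ha). Entities with no
#' records at the baseline year are likewise excluded and reported
#' separately. Small reporting units distort growth-rate analyses because a
#' few km^2 of baseline agriculture produce wildly unstable rates.
#'
#' @param panel A crop-area panel.
#' @param threshold_km2 Exclusion threshold in km^2 (default 1000, i.e.
#'   100,000 ha).
#' @param baseline_year Year at which baseline areas are measured (default
#'   1961).
#' @return A list with elements `panel` (the filtered panel) and `report`
#'   (a tibble: `entity`, `baseline_area_ha`, `status` in retained /
#'   excluded_small / excluded_absent), plus attribute-free summary columns
#'   usable downstream.
#' @export
filter_min_area <- function(panel, threshold_km2 = 1000, baseline_year = 1961) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  if (threshold_km2 <= 0) {
    stop_cropdivr("threshold_km2 must be > 0", "cropdivr_validation_error")
  }
  if (!baseline_year %in% panel$year) {
    stop_cropdivr(sprintf("baseline year %d absent from panel", baseline_year),
                  "cropdivr_validation_error")
  }
  threshold_ha <- threshold_km2 * 100
  baseline <- as_tibble(panel) %>%
    filter(.data$year == baseline_year) %>%
    group_by(.data$entity) %>%
    summarise(baseline_area_ha = sum(.data$area), .groups = "drop")
  all_entities <- tibble(entity = unique(panel$entity))
  report <- left_join(all_entities, baseline, by = "entity") %>%
    mutate(status = case_when(
      is.na(.data$baseline_area_ha) ~ "excluded_absent",
      .data$baseline_area_ha < threshold_ha ~ "excluded_small",
      TRUE ~ "retained"
    )) %>%
    arrange(.data$entity)
  keep <- report$entity[report$status == "retained"]
  kept <- as_tibble(panel)[panel$entity %in% keep, ]
  if (nrow(kept) == 0) {
    stop_cropdivr("no entity passes the minimum-area filter", "cropdivr_validation_error")
  }
  list(
    panel = restore_panel(kept, panel),
    report = report
  )
}

#' Area coverage of a crop subset
#'
#' Share of total harvested area accounted for by a subset of crops, per
#' year — the usual way of stating how much of world agriculture a
#' classified crop list covers.
#'
#' @param panel A crop-area panel.
#' @param crop_subset Character vector of crop names (non-empty).
#' @param years Years to evaluate; default all years present.
#' @return Tibble `year`, `subset_area`, `total_area`, `share` (in
#'   `[0, 1]`; `NA` with a warning for a year whose total area is zero).
#' @export
coverage_stats <- function(panel, crop_subset, years = NULL) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  if (length(crop_subset) == 0) {
    stop_cropdivr("crop_subset must be non-empty", "cropdivr_validation_error")
  }
  years <- years %||% sort(unique(panel$year))
  df <- as_tibble(panel) %>% filter(.data$year %in% years)
  totals <- df %>%
    group_by(.data$year) %>%
    summarise(total_area = sum(.data$area), .groups = "drop")
  subset_totals <- df %>%
    filter(.data$crop %in% crop_subset) %>%
    group_by(.data$year) %>%
    summarise(subset_area = sum(.data$area), .groups = "drop")
  out <- tibble(year = as.integer(years)) %>%
    left_join(totals, by = "year") %>%
    left_join(subset_totals, by = "year") %>%
    mutate(
      total_area = dplyr::coalesce(.data$total_area, 0),
      subset_area = dplyr::coalesce(.data$subset_area, 0),
      share = if_else(.data$total_area > 0, .data$subset_area / .data$total_area, NA_real_)
    ) %>%
    select("year", "subset_area", "total_area", "share")
  if (anyNA(out$share)) {
    warn(sprintf("coverage_stats: %d year(s) with zero total area; share undefined",
                 sum(is.na(out$share))))
  }
  out
}
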