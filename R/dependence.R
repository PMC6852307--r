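#' Pollinator-dependence categories and brackets
#'
#' Crops are classified by the percent reduction in fruit or seed production
#' observed when animal pollinators are experimentally excluded. Five
#' classes partition the scale: `none` is exactly 0% reduction; the four
#' dependent classes are half-open brackets `little` (0, 10],
#' `modest` (10, 40], `high` (40, 90] and `essential` (90, 100].
#' "moderate" is accepted everywhere as an alias of "modest".
#'
#' @return A tibble with columns `category`, `lower`, `upper` (bracket
#'   bounds, lower-exclusive / upper-inclusive except `none` which is the
#'   single point 0), and `dependent` (logical).
#' @export
dependence_categories <- function() {
  tibble(
    category = c("none", "little", "modest", "high", "essential"),
    lower = c(0, 0, 10, 40, 90),
    upper = c(0, 10, 40, 90, 100),
    dependent = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

canonical_category <- function(x) {
  x <- tolower(trimws(x))
  x[x == "moderate"] <- "modest"
  x
}

#' Classify a percent yield reduction into its dependence category
#'
#' @param percent_reduction Numeric vector of percent yield reductions in
#'   `[0, 100]`.
#' @return Character vector of category names; `0` maps to `"none"`,
#'   bracket boundaries are upper-inclusive (10 is `little`, 10.0001 is
#'   `modest`, anything above 90 is `essential`).
#' @examples
#' category_from_reduction(c(0, 10, 10.0001, 95))
#' @export
category_from_reduction <- function(percent_reduction) {
  if (!is.numeric(percent_reduction) || anyNA(percent_reduction) ||
      any(percent_reduction < 0 | percent_reduction > 100)) {
    stop_cropdivr("percent_reduction must lie in [0, 100]", "cropdivr_validation_error")
  }
  brackets <- dependence_categories()[-1, ] # dependent brackets only
  out <- rep("none", length(percent_reduction))
  for (i in seq_len(nrow(brackets))) {
    hit <- percent_reduction > brackets$lower[i] & percent_reduction <= brackets$upper[i]
    out[hit] <- brackets$category[i]
  }
  out
}

#' Load and validate a crop dependence table
#'
#' The table maps crop names to dependence categories, with an optional
#' percent yield reduction that must lie inside the category's bracket.
#' The bundled default (`load_dependence_table()` with no arguments) is a
#' synthetic stand-in covering ~50 major crops with categories consistent
#' with the published classification; it is not a reproduction of any
#' compiled crop list, and user tables override it.
#'
#' @param source Path to a CSV with columns `crop`, `category` and
#'   optionally `percent_reduction`; `NULL` loads the bundled default.
#' @param strict If `TRUE`, an unknown category name aborts; otherwise the
#'   offending rows are dropped with a warning.
#' @return A tibble `crop`, `category`, `percent_reduction`, `dependent`,
#'   of class `dependence_table`.
#' @export
load_dependence_table <- function(source = NULL, strict = TRUE) {
  source <- source %||% system.file("extdata", "dependence_default_synthetic.csv",
                                    package = "cropdivr", mustWork = TRUE)
  raw <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  as_dependence_table(raw, strict = strict)
}

#' @rdname load_dependence_table
#' @param x Data frame with columns `crop`, `category`, and optionally
#'   `percent_reduction`.
#' @export
as_dependence_table <- function(x, strict = TRUE) {
  if (!all(c("crop", "category") %in% names(x))) {
    stop_cropdivr("dependence table needs columns crop, category", "cropdivr_schema_error")
  }
  out <- as_tibble(x)
  out$crop <- trimws(as.character(out$crop))
  out$category <- canonical_category(out$category)
  if (!"percent_reduction" %in% names(out)) out$percent_reduction <- NA_real_
  out$percent_reduction <- as.double(out$percent_reduction)
  valid <- dependence_categories()$category
  unknown <- !out$category %in% valid
  if (any(unknown)) {
    msg <- sprintf("unknown dependence categor%s: %s",
                   if (sum(unknown) > 1) "ies" else "y",
                   paste(unique(out$category[unknown]), collapse = ", "))
    if (strict) stop_cropdivr(msg, "cropdivr_validation_error")
    warn(paste0(msg, " (rows dropped)"))
    out <- out[!unknown, ]
  }
  # a stated percent must fall in its own category's bracket
  has_pct <- !is.na(out$percent_reduction)
  if (any(has_pct)) {
    implied <- category_from_reduction(out$percent_reduction[has_pct])
    bad <- implied != out$category[has_pct]
    if (any(bad)) {
      i <- which(has_pct)[which(bad)[1]]
      stop_cropdivr(
        sprintf("crop '%s': percent_reduction %g is outside the '%s' bracket",
                out$crop[i], out$percent_reduction[i], out$category[i]),
        "cropdivr_consistency_error"
      )
    }
  }
  if (anyDuplicated(out$crop)) {
    stop_cropdivr(
      sprintf("crop '%s' classified more than once", out$crop[duplicated(out$crop)][1]),
      "cropdivr_duplicate_key_error"
    )
  }
  out$dependent <- out$category != "none"
  out <- out[c("crop", "category", "percent_reduction", "dependent")]
  class(out) <- c("dependence_table", class(out))
  out
}

# Join panel rows to their dependence class; unclassified crops are either
# dropped (with one warning) or an error, per `unclassified`.
classify_panel <- function(panel, table, unclassified = c("exclude", "error")) {
  unclassified <- match.arg(unclassified)
  df <- as_tibble(panel)
  df$category <- table$category[match(df$crop, table$crop)]
  miss <- is.na(df$category)
  if (any(miss)) {
    crops <- sort(unique(df$crop[miss]))
    msg <- sprintf("%d crop(s) not in the dependence table: %s",
                   length(crops), paste(head(crops, 5), collapse = ", "))
    if (unclassified == "error") stop_cropdivr(msg, "cropdivr_validation_error")
    warn(paste0(msg, " (excluded from dependence computations)"))
    df <- df[!miss, ]
  }
  df$dependent <- df$category != "none"
  df
}

#' Pollinator-dependence share of agriculture
#'
#' For each entity-year, the proportion of total classified harvested area
#' under pollinator-dependent crops (categories little through essential),
#' together with the per-category area decomposition. Denominators are
#' restricted to classified crops.
#'
#' @param panel A crop-area panel.
#' @param table A [dependence table][load_dependence_table].
#' @param entities,years Optional filters; default all present.
#' @param unclassified `"exclude"` (default) drops unclassified crops with
#'   a warning; `"error"` aborts.
#' @return Tibble `entity`, `year`, `total_area`, `dependent_area`,
#'   `share`, plus one `area_<category>` column per category. Entity-years
#'   whose classified total area is zero are dropped with a warning.
#' @export
dependence_share <- function(panel, table = load_dependence_table(),
                             entities = NULL, years = NULL,
                             unclassified = c("exclude", "error")) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  df <- classify_panel(panel, table, unclassified)
  if (!is.null(entities)) df <- df[df$entity %in% entities, ]
  if (!is.null(years)) df <- df[df$year %in% years, ]
  if (nrow(df) == 0) {
    stop_cropdivr("no classified records for the requested entity-years",
                  "cropdivr_validation_error")
  }
  wide <- df %>%
    group_by(.data$entity, .data$year, .data$category) %>%
    summarise(area = sum(.data$area), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "area",
                       names_prefix = "area_", values_fill = 0)
  for (cat in paste0("area_", dependence_categories()$category)) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0
  }
  dep_cols <- paste0("area_", c("little", "modest", "high", "essential"))
  wide$total_area <- wide$area_none + rowSums(wide[dep_cols])
  wide$dependent_area <- rowSums(wide[dep_cols])
  zero <- wide$total_area <= 0
  if (any(zero)) {
    warn(sprintf("dependence_share: %d entity-year(s) with zero classified area dropped", sum(zero)))
    wide <- wide[!zero, ]
    if (nrow(wide) == 0) {
      stop_cropdivr("all requested entity-years have zero classified area",
                    "cropdivr_undefined_share_error")
    }
  }
  wide$share <- wide$dependent_area / wide$total_area
  wide %>%
    select("entity", "year", "total_area", "dependent_area", "share",
           dplyr::all_of(paste0("area_", dependence_categories()$category))) %>%
    arrange(.data$entity, .data$year)
}

#' Per-category area series and percent change from a base year
#'
#' Aggregates classified area globally (over all entities) per dependence
#' category and year, and expresses each category's series as a percent
#' change from the base year, `100 * (x_t - x_base) / x_base`.
#'
#' @param panel A crop-area panel.
#' @param table A dependence table.
#' @param years Years to include; default all present.
#' @param base_year Base year for percent change; default the earliest of
#'   `years`.
#' @inheritParams dependence_share
#' @return Tibble `category`, `year`, `area`, `pct_change`. Categories with
#'   zero base-year area carry `NA` percent change and raise a warning.
#' @export
category_area_series <- function(panel, table = load_dependence_table(),
                                 years = NULL, base_year = NULL,
                                 unclassified = c("exclude", "error")) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  df <- classify_panel(panel, table, unclassified)
  years <- sort(years %||% unique(df$year))
  if (length(years) == 0) {
    stop_cropdivr("years must be non-empty", "cropdivr_validation_error")
  }
  base_year <- base_year %||% min(years)
  grid <- tidyr::expand_grid(category = dependence_categories()$category,
                             year = as.integer(years))
  series <- df %>%
    filter(.data$year %in% years) %>%
    group_by(.data$category, .data$year) %>%
    summarise(area = sum(.data$area), .groups = "drop") %>%
    right_join(grid, by = c("category", "year")) %>%
    mutate(area = dplyr::coalesce(.data$area, 0)) %>%
    group_by(.data$category) %>%
    mutate(base = .data$area[.data$year == base_year][1],
           pct_change = if_else(.data$base > 0,
                                100 * (.data$area - .data$base) / .data$base,
                                NA_real_)) %>%
    ungroup() %>%
    select("category", "year", "area", "pct_change") %>%
    arrange(match(.data$category, dependence_categories()$category), .data$year)
  undef <- unique(series$category[is.na(series$pct_change)])
  if (length(undef) > 0) {
    warn(sprintf("category_area_series: zero base-year area for: %s",
                 paste(undef, collapse = ", ")))
  }
  series
}
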