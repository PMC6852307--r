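#' Run the full trend analysis from a configuration
#'
#' Sequences the whole procedure — read (or simulate) the panel, harmonize
#' successor states, apply the minimum-area filter, classify dependence,
#' compute diversity, global trends, country growth rates and
#' vulnerability indices, rank crop expansion with the G-test, and fit
#' the region models — and writes a tidy CSV bundle plus a JSON run
#' manifest with per-stage row accounting.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `input`: either `list(panel = <path>, schema = <list>)` or
#'     `list(preset = <name>, seed = <int>, noise_sd = <num>)` —
#'     exactly one of `panel` / `preset`;
#'   * `dependence_table`: optional path (preset runs use the scenario's
#'     own table; file runs default to the bundled table);
#'   * `harmonization_rules`: optional path, `"default"`, or `"none"`;
#'   * `regions`: optional path to an entity,region CSV (presets supply
#'     their own);
#'   * `year_start`, `year_end` (defaults 1961, 2016);
#'   * `min_area_km2` (default 1000);
#'   * `models`: character vector of responses to model against region
#'     (default the five growth rates);
#'   * `out`: output directory (created if needed).
#' @return Invisibly, a list with every computed object (`panel`,
#'   `exclusion`, `growth`, `vulnerability`, `trends`, `ranking`,
#'   `g_tests`, `models`, `manifest`) alongside the files written.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(year_start = 1961, year_end = 2016, min_area_km2 = 1000,
                   models = c("d_area", "d_dependence", "d_diversity",
                              "d_richness", "d_evenness"),
                   harmonization_rules = "default")
  config <- modifyList(defaults, config)
  if (is.null(config$out)) {
    stop_cropdivr("config$out (output directory) is required", "cropdivr_validation_error")
  }
  input <- config$input
  if (is.null(input) || (is.null(input$panel) == is.null(input$preset))) {
    stop_cropdivr("config$input must name exactly one of panel/preset",
                  "cropdivr_validation_error")
  }
  if (!is.null(input$panel) && !file.exists(input$panel)) {
    stop_cropdivr(sprintf("input panel '%s' not found", input$panel),
                  "cropdivr_validation_error")
  }
  if (!is.null(config$dependence_table) && !file.exists(config$dependence_table)) {
    stop_cropdivr(sprintf("dependence table '%s' not found", config$dependence_table),
                  "cropdivr_validation_error")
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config = config[setdiff(names(config), "out")],
                   stages = list())
  note <- function(stage, rows_in, rows_out) {
    manifest$stages[[stage]] <<- list(rows_in = rows_in, rows_out = rows_out,
                                      dropped = rows_in - rows_out)
  }

  regions <- NULL
  truth <- NULL
  if (!is.null(input$preset)) {
    presets <- preset_scenarios(seed = input$seed %||% 20160101,
                                noise_sd = input$noise_sd %||% 0)
    if (!input$preset %in% names(presets)) {
      stop_cropdivr(sprintf("unknown preset '%s'", input$preset),
                    "cropdivr_validation_error")
    }
    gen <- generate_panel(presets[[input$preset]])
    panel <- gen$panel
    dep_table <- gen$dependence
    regions <- gen$regions
    truth <- gen$truth
  } else {
    panel <- read_crop_area_table(input$panel, schema = input$schema %||% list())
    dep_table <- load_dependence_table(config$dependence_table)
    if (!is.null(config$regions)) {
      regions <- readr::read_csv(config$regions, show_col_types = FALSE, progress = FALSE)
    }
  }
  if (!is.null(config$dependence_table) && !is.null(input$preset)) {
    dep_table <- load_dependence_table(config$dependence_table)
  }
  n0 <- nrow(panel)
  note("read", n0, n0)

  rules <- config$harmonization_rules
  if (identical(rules, "default")) {
    rules <- default_harmonization_rules()
  } else if (identical(rules, "none")) {
    rules <- tibble(target = character(), source = character())
  } else if (is.character(rules)) {
    rules <- readr::read_csv(rules, show_col_types = FALSE, progress = FALSE)
  }
  panel <- harmonize_entities(panel, rules)
  note("harmonize", n0, nrow(panel))

  filtered <- filter_min_area(panel, threshold_km2 = config$min_area_km2,
                              baseline_year = config$year_start)
  note("min_area_filter", nrow(panel), nrow(filtered$panel))
  panel <- filtered$panel

  trends <- global_trends(panel, dep_table, base_year = config$year_start)
  categories <- suppressWarnings(
    category_area_series(panel, dep_table, base_year = config$year_start)
  )
  growth <- country_growth_table(panel, dep_table,
                                 year_start = config$year_start,
                                 year_end = config$year_end,
                                 regions = regions)
  vuln <- vulnerability_indices(growth)

  n_crops <- length(unique(panel$crop))
  k <- min(20, floor(n_crops / 2))
  ranking <- g_tests <- NULL
  if (k >= 2) {
    ranking <- rank_crop_expansion(panel, dep_table, k = k,
                                   year_start = config$year_start,
                                   year_end = config$year_end)
    g_tests <- bind_rows(lapply(c("none", "williams", "yates"), function(corr) {
      if (any(rowSums(ranking$counts) == 0) || any(colSums(ranking$counts) == 0)) {
        return(NULL)
      }
      g_test_2x2(ranking$counts, correction = corr)
    }))
  }

  models <- list()
  lsmeans_out <- contrasts_out <- comparison_out <- list()
  can_model <- !all(is.na(growth$region)) &&
    dplyr::n_distinct(growth$region[!is.na(growth$region)]) >= 2
  if (can_model) {
    covariates <- list(
      d_area = "d_area ~ region",
      d_dependence = "d_dependence ~ region + d_area",
      d_diversity = "d_diversity ~ region + d_area + d_dependence",
      d_richness = "d_richness ~ region + d_area + d_dependence",
      d_evenness = "d_evenness ~ region + d_area + d_dependence"
    )
    for (resp in intersect(config$models, names(covariates))) {
      fml <- stats::as.formula(covariates[[resp]])
      ok <- tryCatch({
        fit_het <- fit_gls(growth, fml, group = "region", variance = "per_group")
        fit_hom <- fit_gls(growth, fml, group = "region", variance = "homogeneous")
        cmp <- compare_variance_models(fit_hom, fit_het)
        best <- if (cmp$preferred == "per_group") fit_het else fit_hom
        tk <- tukey_contrasts(best)
        models[[resp]] <- list(het = fit_het, hom = fit_hom,
                               comparison = cmp, best = best, tukey = tk)
        lsmeans_out[[resp]] <- mutate(
          left_join(ls_means(best), tk$letters[c("level", "letters")], by = "level"),
          response = resp, .before = 1)
        contrasts_out[[resp]] <- mutate(tk$contrasts, response = resp, .before = 1)
        comparison_out[[resp]] <- mutate(cmp, response = resp, .before = 1)
        TRUE
      }, cropdivr_error = function(e) {
        warn(sprintf("model for %s skipped: %s", resp, conditionMessage(e)))
        FALSE
      })
    }
  }

  files <- list(
    global_trends = "global_trends.csv",
    category_series = "category_series.csv",
    country_growth = "country_growth.csv",
    vulnerability = "vulnerability.csv",
    exclusion_report = "exclusion_report.csv"
  )
  readr::write_csv(trends, file.path(config$out, files$global_trends))
  readr::write_csv(categories, file.path(config$out, files$category_series))
  readr::write_csv(as_tibble(growth), file.path(config$out, files$country_growth))
  readr::write_csv(vuln, file.path(config$out, files$vulnerability))
  readr::write_csv(filtered$report, file.path(config$out, files$exclusion_report))
  if (!is.null(ranking)) {
    readr::write_csv(ranking$ranking, file.path(config$out, "crop_ranking.csv"))
    files$crop_ranking <- "crop_ranking.csv"
    if (!is.null(g_tests) && nrow(g_tests) > 0) {
      readr::write_csv(g_tests, file.path(config$out, "g_tests.csv"))
      files$g_tests <- "g_tests.csv"
    }
  }
  if (length(lsmeans_out) > 0) {
    readr::write_csv(bind_rows(lsmeans_out), file.path(config$out, "region_lsmeans.csv"))
    readr::write_csv(bind_rows(contrasts_out), file.path(config$out, "contrasts.csv"))
    readr::write_csv(bind_rows(comparison_out), file.path(config$out, "model_comparison.csv"))
    files <- c(files, list(region_lsmeans = "region_lsmeans.csv",
                           contrasts = "contrasts.csv",
                           model_comparison = "model_comparison.csv"))
  }
  manifest$files <- unlist(files)
  manifest$n_entities <- length(unique(panel$entity))
  manifest$n_crops <- n_crops
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = panel, exclusion = filtered$report, trends = trends,
                 categories = categories, growth = growth, vulnerability = vuln,
                 ranking = ranking, g_tests = g_tests, models = models,
                 truth = truth, manifest = manifest))
}
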