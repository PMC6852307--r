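#' Scenario configuration for synthetic crop-area panels
#'
#' Describes a FAOSTAT-like world: regions with a number of countries
#' each, and a crop list in which every crop carries a dependence
#' category, a log-normal baseline-area distribution, a true compound
#' annual growth rate, and a multiplicative log-scale noise level. All
#' randomness flows from the single mandatory seed.
#'
#' @param regions Named integer vector: countries per region (names are
#'   region labels, e.g. `c(Africa = 25, Europe = 25)`).
#' @param crops Data frame with columns `crop`, `category`,
#'   `baseline_meanlog`, `baseline_sdlog` (log-normal parameters of the
#'   baseline area in ha), `growth_rate` (true %/yr), and optionally
#'   `noise_sd` (sd of the log-scale noise; default the scenario-level
#'   `noise_sd`).
#' @param years Year range (default `1961:2016`).
#' @param noise_sd Default multiplicative noise sd on log-areas (default
#'   0, i.e. noise-free).
#' @param seed Mandatory integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(regions, crops, years = 1961:2016, noise_sd = 0, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_cropdivr("a single integer seed is mandatory", "cropdivr_validation_error")
  }
  if (is.null(names(regions)) || any(!nzchar(names(regions))) || any(regions < 1)) {
    stop_cropdivr("regions must be a named vector of positive country counts",
                  "cropdivr_validation_error")
  }
  crops <- as_tibble(crops)
  needed <- c("crop", "category", "baseline_meanlog", "baseline_sdlog", "growth_rate")
  if (!all(needed %in% names(crops))) {
    stop_cropdivr(paste0("crops needs columns: ", paste(needed, collapse = ", ")),
                  "cropdivr_schema_error")
  }
  crops$category <- canonical_category(crops$category)
  if (!all(crops$category %in% dependence_categories()$category)) {
    stop_cropdivr("invalid dependence category in crops", "cropdivr_validation_error")
  }
  if (any(!is.finite(crops$growth_rate)) || any(crops$baseline_sdlog < 0)) {
    stop_cropdivr("growth rates must be finite and baseline_sdlog >= 0",
                  "cropdivr_validation_error")
  }
  if (!"noise_sd" %in% names(crops)) crops$noise_sd <- noise_sd
  crops$noise_sd[is.na(crops$noise_sd)] <- noise_sd
  if (any(crops$noise_sd < 0)) {
    stop_cropdivr("noise_sd must be >= 0", "cropdivr_validation_error")
  }
  structure(list(
    regions = regions, crops = crops, years = as.integer(years),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scenario_config")
}

# analytic per-country metrics from a baseline-area matrix and growth
# rates; deliberately independent of the panel/diversity/trend functions
truth_metrics <- function(base_areas, growth_rate, dependent, year0, year1) {
  gf <- (1 + growth_rate / 100)^(year1 - year0)
  a0 <- base_areas
  a1 <- base_areas * gf
  metr <- function(a) {
    a <- a[a > 0]
    p <- a / sum(a)
    H <- -sum(p * log(p))
    S <- length(a)
    list(area = sum(a), eH = exp(H), S = S,
         J = if (S >= 2) H / log(S) else NA_real_)
  }
  m0 <- metr(a0); m1 <- metr(a1)
  dep0 <- sum(a0[dependent]) / sum(a0)
  dep1 <- sum(a1[dependent]) / sum(a1)
  rate <- function(x0, x1) {
    if (is.na(x0) || is.na(x1) || x0 <= 0 || x1 <= 0) return(NA_real_)
    100 * (exp((log(x1) - log(x0)) / (year1 - year0)) - 1)
  }
  c(d_area = rate(m0$area, m1$area),
    d_dependence = rate(dep0, dep1),
    d_diversity = rate(m0$eH, m1$eH),
    d_richness = rate(m0$S, m1$S),
    d_evenness = rate(m0$J, m1$J))
}

#' Generate a synthetic crop-area panel with known ground truth
#'
#' Each country draws a baseline area per crop from the configured
#' log-normal, then areas follow
#' `x(t) = x(y0) * (1 + r/100)^(t - y0) * exp(e_t)` with
#' `e_t ~ N(0, noise_sd^2)` independently per (country, crop, year); the
#' base year carries no noise so baselines are exact. Ground truth growth
#' rates are computed in closed form from the drawn baselines and
#' configured rates (never by running the pipeline), so a noise-free run
#' of the full analysis must reproduce them to numerical precision.
#'
#' @param config A [scenario_config()].
#' @return List with `panel` (a crop-area panel), `truth` (tibble:
#'   `entity`, `region`, true `d_area`, `d_dependence`, `d_diversity`,
#'   `d_richness`, `d_evenness`), `regions` (tibble `entity`, `region`),
#'   and `dependence` (a dependence table for the scenario's crops).
#' @examples
#' cfg <- scenario_config(
#'   regions = c(Africa = 2),
#'   crops = data.frame(crop = c("a", "b"), category = c("none", "modest"),
#'                      baseline_meanlog = log(1000), baseline_sdlog = 0,
#'                      growth_rate = c(0, 2)),
#'   years = 1961:1963, seed = 1
#' )
#' generate_panel(cfg)$truth
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop_cropdivr("config must be a scenario_config", "cropdivr_validation_error")
  }
  set.seed(config$seed)
  years <- config$years
  y0 <- min(years); y1 <- max(years)
  crops <- config$crops
  n_crop <- nrow(crops)
  dependent <- crops$category != "none"
  countries <- unlist(lapply(names(config$regions), function(r) {
    sprintf("%s_%02d", r, seq_len(config$regions[[r]]))
  }))
  region_of <- rep(names(config$regions), times = config$regions)

  panels <- vector("list", length(countries))
  truths <- vector("list", length(countries))
  for (ci in seq_along(countries)) {
    base <- stats::rlnorm(n_crop, meanlog = crops$baseline_meanlog,
                          sdlog = crops$baseline_sdlog)
    growth <- outer(1 + crops$growth_rate / 100, years - y0, `^`) # crop x year
    eps <- matrix(rnorm(n_crop * length(years), 0, crops$noise_sd),
                  nrow = n_crop)
    eps[, years == y0] <- 0
    areas <- base * growth * exp(eps)
    panels[[ci]] <- tibble(
      entity = countries[ci],
      crop = rep(crops$crop, times = length(years)),
      year = rep(years, each = n_crop),
      area = as.vector(areas)
    )
    truths[[ci]] <- c(entity = countries[ci], region = region_of[ci],
                      truth_metrics(base, crops$growth_rate, dependent, y0, y1))
  }
  truth <- bind_rows(lapply(truths, function(x) {
    tibble(entity = x[["entity"]], region = x[["region"]],
           d_area = as.numeric(x[["d_area"]]),
           d_dependence = as.numeric(x[["d_dependence"]]),
           d_diversity = as.numeric(x[["d_diversity"]]),
           d_richness = as.numeric(x[["d_richness"]]),
           d_evenness = as.numeric(x[["d_evenness"]]))
  }))
  dep_table <- as_dependence_table(
    tibble(crop = crops$crop, category = crops$category)
  )
  list(
    panel = as_crop_area_panel(bind_rows(panels),
                               provenance = sprintf("synthetic scenario (seed %d)", config$seed)),
    truth = truth,
    regions = tibble(entity = countries, region = region_of),
    dependence = dep_table
  )
}

#' Bundled synthetic scenario presets
#'
#' Named scenario configurations exercising qualitatively distinct
#' regimes, each documenting its intended sign signature:
#'
#' * `global_mix`: 5 regions x 25 countries x 30 crops over 1961-2016 with
#'   mixed categories and rates — the general-purpose end-to-end preset.
#' * `expansion_without_diversification`: all crops expand at the same
#'   rate (shares frozen), so the area vulnerability index is positive
#'   while diversity is flat.
#' * `european_substitution`: total area contracts while dependent crops
#'   replace nondependent ones — `d_area < 0`, `d_dependence > 0`.
#' * `pacific_rim_diversifying`: minor crops expand faster than the
#'   dominant staple, so `d_diversity > 0`.
#' * `soy_takeover`: one modest-dependence oilseed at +8 %/yr against
#'   static staples collapses evenness — `d_evenness < 0` with
#'   `dependence_vulnerability > 0`.
#'
#' @param seed Integer seed stored in every preset (default 20160101).
#' @param noise_sd Log-scale noise sd applied to every preset (default 0).
#' @return Named list of [scenario_config()] objects.
#' @export
preset_scenarios <- function(seed = 20160101, noise_sd = 0) {
  crop_row <- function(crop, category, meanlog, rate) {
    tibble(crop = crop, category = category, baseline_meanlog = meanlog,
           baseline_sdlog = 0.5, growth_rate = rate)
  }
  staples <- bind_rows(
    crop_row("wheat", "none", log(5e5), 0.3),
    crop_row("rice", "none", log(4e5), 0.4),
    crop_row("maize", "none", log(4e5), 0.6),
    crop_row("barley", "none", log(2e5), 0.1),
    crop_row("potatoes", "none", log(1e5), 0.2)
  )
  mixed30 <- bind_rows(
    staples,
    crop_row(paste0("cereal_", 1:5), "none", log(8e4), c(0.0, 0.2, -0.2, 0.4, 0.1)),
    crop_row(paste0("legume_", 1:5), "little", log(5e4), c(0.8, 1.0, 0.5, 1.2, 0.6)),
    crop_row(c("soybean", "rapeseed", "sunflower", "oil_palm", "cotton"),
             "modest", log(1e5), c(3.0, 2.5, 2.0, 3.5, 0.8)),
    crop_row(c("apples", "pears", "almonds", "mango", "avocado"),
             "high", log(3e4), c(1.5, 1.2, 2.2, 1.8, 2.5)),
    crop_row(c("cocoa", "watermelon", "melon", "squash", "kiwi"),
             "essential", log(2e4), c(1.0, 1.4, 1.1, 0.9, 2.8))
  )
  list(
    global_mix = scenario_config(
      regions = c(Africa = 25, America = 25, Asia = 25, Europe = 25, Oceania = 25),
      crops = mixed30, years = 1961:2016, noise_sd = noise_sd, seed = seed
    ),
    expansion_without_diversification = scenario_config(
      regions = c(America = 10),
      crops = mutate(mixed30, growth_rate = 2),
      years = 1961:2016, noise_sd = noise_sd, seed = seed
    ),
    european_substitution = scenario_config(
      regions = c(Europe = 10),
      crops = bind_rows(
        crop_row(c("wheat", "barley", "rye"), "none", log(4e5), c(-1.5, -1.8, -2.0)),
        crop_row(c("rapeseed", "apples"), c("modest", "high"), log(5e4), c(1.5, 1.0))
      ),
      years = 1961:2016, noise_sd = noise_sd, seed = seed
    ),
    pacific_rim_diversifying = scenario_config(
      regions = c(America = 10),
      crops = bind_rows(
        crop_row("maize", "none", log(5e5), 0.2),
        crop_row(c("grapes_t", "cherries", "blueberry", "avocado", "citrus"),
                 c("little", "high", "high", "high", "little"),
                 log(2e4), c(2.5, 3.0, 3.5, 3.2, 2.0))
      ),
      years = 1961:2016, noise_sd = noise_sd, seed = seed
    ),
    soy_takeover = scenario_config(
      regions = c(America = 10),
      crops = bind_rows(
        crop_row(c("wheat", "maize", "sunflower_s"), c("none", "none", "modest"),
                 log(3e5), 0),
        crop_row("soybean", "modest", log(1e5), 8)
      ),
      years = 1961:2016, noise_sd = noise_sd, seed = seed
    )
  )
}
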