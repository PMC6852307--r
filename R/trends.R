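#' Percent-change series relative to a base year
#'
#' Expresses a yearly series as `100 * (x_t - x_base) / x_base`, the usual
#' way long-run agricultural change is plotted (0 at the base year by
#' construction).
#'
#' @param data Data frame with a year column and a value column.
#' @param base_year Base year; must be present with a positive value.
#' @param year,value Column names (strings) for year and value; defaults
#'   `"year"`, `"value"`.
#' @param variable Optional label stored in the output's `variable` column.
#' @return Tibble `variable`, `year`, `value`, `pct_change` of class
#'   `percent_change_series`.
#' @export
percent_change_series <- function(data, base_year, year = "year", value = "value",
                                  variable = "value") {
  df <- tibble(year = as.integer(data[[year]]), value = as.double(data[[value]]))
  if (anyDuplicated(df$year)) {
    stop_cropdivr("duplicate years in series", "cropdivr_duplicate_key_error")
  }
  base <- df$value[df$year == base_year]
  if (length(base) != 1 || !is.finite(base) || base <= 0) {
    stop_cropdivr(sprintf("base year %d absent or non-positive", base_year),
                  "cropdivr_validation_error")
  }
  out <- df %>%
    mutate(variable = variable,
           pct_change = 100 * (.data$value - base) / base) %>%
    select("variable", "year", "value", "pct_change") %>%
    arrange(.data$year)
  attr(out, "base_year") <- as.integer(base_year)
  class(out) <- c("percent_change_series", class(out))
  out
}

#' Compound annual growth rate between two endpoints
#'
#' `100 * (exp((log(x_end) - log(x_start)) / (year_end - year_start)) - 1)`,
#' in %/yr. Defined only for positive endpoints; a non-positive or missing
#' endpoint yields `NA` with a reason code rather than an error, because in
#' panel work undefined rates are data, not bugs.
#'
#' @param x_start,x_end Endpoint values.
#' @param year_start,year_end Endpoint years, `year_end > year_start`.
#' @return Tibble `rate` (%/yr, `NA` if undefined) and `reason`
#'   (`"ok"`, `"nonpositive_start"`, `"nonpositive_end"`, `"missing"`).
#'   For scalar input, convenient to use `$rate`.
#' @examples
#' annual_growth_rate(100, 200, 1961, 2016)$rate # 1.268 %/yr
#' @export
annual_growth_rate <- function(x_start, x_end, year_start, year_end) {
  if (any(year_end <= year_start)) {
    stop_cropdivr("year_end must exceed year_start", "cropdivr_validation_error")
  }
  n <- max(length(x_start), length(x_end))
  x_start <- rep_len(as.double(x_start), n)
  x_end <- rep_len(as.double(x_end), n)
  span <- rep_len(as.double(year_end - year_start), n)
  reason <- case_when(
    is.na(x_start) | is.na(x_end) ~ "missing",
    x_start <= 0 ~ "nonpositive_start",
    x_end <= 0 ~ "nonpositive_end",
    TRUE ~ "ok"
  )
  rate <- if_else(reason == "ok",
                  100 * (exp((log(x_end) - log(x_start)) / span) - 1),
                  NA_real_)
  tibble(rate = rate, reason = reason)
}

# endpoint metric values for one entity set, used by country_growth_table
endpoint_metrics <- function(panel, table, year, unclassified) {
  prof <- suppressWarnings(diversity_profile(panel, years = year))
  dep <- suppressWarnings(
    dependence_share(panel, table, years = year, unclassified = unclassified)
  )
  left_join(
    prof %>% select("entity", "S", "eH", "J"),
    dep %>% select("entity", "total_area", "share"),
    by = "entity"
  )
}

#' Country-level annualized growth rates
#'
#' For each entity, compound annual growth rates (%/yr) between the two
#' endpoint years for: total harvested area (`d_area`), pollinator
#' dependence share (`d_dependence`), effective number of crops
#' (`d_diversity`), crop richness (`d_richness`) and Pielou evenness
#' (`d_evenness`). Rates with a non-positive or missing endpoint are `NA`
#' with a reason code column (`r_<name>`); evenness is undefined for
#' single-crop endpoints.
#'
#' @param panel A (harmonized, filtered) crop-area panel.
#' @param table A dependence table.
#' @param year_start,year_end Endpoint years (defaults 1961 and 2016).
#' @param regions Optional tibble `entity`, `region` joined onto the
#'   result; entities without an assignment get `NA` region.
#' @inheritParams dependence_share
#' @return Tibble of class `growth_rate_table`: `entity`, `region`, the
#'   five `d_*` rate columns and five `r_*` reason columns.
#' @export
country_growth_table <- function(panel, table = load_dependence_table(),
                                 year_start = 1961, year_end = 2016,
                                 regions = NULL,
                                 unclassified = c("exclude", "error")) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  unclassified <- match.arg(unclassified)
  for (y in c(year_start, year_end)) {
    if (!y %in% panel$year) {
      stop_cropdivr(sprintf("endpoint year %d absent from panel", y),
                    "cropdivr_validation_error")
    }
  }
  m0 <- endpoint_metrics(panel, table, year_start, unclassified)
  m1 <- endpoint_metrics(panel, table, year_end, unclassified)
  joined <- dplyr::full_join(m0, m1, by = "entity", suffix = c("_0", "_1"))
  span <- c(year_start, year_end)
  vars <- c(d_area = "total_area", d_dependence = "share", d_diversity = "eH",
            d_richness = "S", d_evenness = "J")
  out <- tibble(entity = joined$entity)
  for (nm in names(vars)) {
    gr <- annual_growth_rate(joined[[paste0(vars[[nm]], "_0")]],
                             joined[[paste0(vars[[nm]], "_1")]],
                             span[1], span[2])
    out[[nm]] <- gr$rate
    out[[sub("^d_", "r_", nm)]] <- gr$reason
  }
  if (!is.null(regions)) {
    out <- left_join(out, as_tibble(regions)[c("entity", "region")], by = "entity")
  } else {
    out$region <- NA_character_
  }
  out <- out %>%
    select("entity", "region", dplyr::starts_with("d_"), dplyr::starts_with("r_")) %>%
    arrange(.data$entity)
  attr(out, "year_start") <- as.integer(year_start)
  attr(out, "year_end") <- as.integer(year_end)
  class(out) <- c("growth_rate_table", class(out))
  out
}

#' Agricultural vulnerability indices
#'
#' Two per-entity differences of growth rates: `area_vulnerability =
#' d_area - d_diversity` and `dependence_vulnerability = d_dependence -
#' d_diversity` (%/yr). Positive values flag entities whose agricultural
#' expansion or growth in pollinator dependence outpaces crop
#' diversification — a pollination-shortfall risk signal. An index is `NA`
#' whenever either constituent rate is undefined.
#'
#' @param growth_table A [country_growth_table()] result.
#' @return Tibble `entity`, `region`, `area_vulnerability`,
#'   `dependence_vulnerability`.
#' @export
vulnerability_indices <- function(growth_table) {
  tibble(
    entity = growth_table$entity,
    region = growth_table$region,
    area_vulnerability = growth_table$d_area - growth_table$d_diversity,
    dependence_vulnerability = growth_table$d_dependence - growth_table$d_diversity
  )
}

#' Rank crops by global expansion rate
#'
#' Global per-crop areas are summed across entities at the two endpoint
#' years and ranked by compound annual growth rate, descending. Crops with
#' zero area at either endpoint cannot carry a rate and are reported
#' separately as novel (absent at start) or discontinued (absent at end).
#' Ties on rate are broken by larger absolute area change, then
#' alphabetically. The 2x2 cross of top-k / bottom-k membership against
#' pollinator dependence is returned for use with [g_test_2x2()].
#'
#' @param panel A crop-area panel.
#' @param table A dependence table.
#' @param k Size of the top and bottom sets (default 20).
#' @inheritParams country_growth_table
#' @return List with `ranking` (tibble `crop`, `category`, `dependent`,
#'   `area_start`, `area_end`, `rate`, `rank`), `excluded` (novel /
#'   discontinued crops), and `counts` (2x2 integer matrix, rows top/bottom,
#'   columns dependent/nondependent).
#' @export
rank_crop_expansion <- function(panel, table = load_dependence_table(), k = 20,
                                year_start = 1961, year_end = 2016,
                                unclassified = c("exclude", "error")) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  df <- classify_panel(panel, table, unclassified)
  glob <- df %>%
    filter(.data$year %in% c(year_start, year_end)) %>%
    group_by(.data$crop, .data$category, .data$dependent, .data$year) %>%
    summarise(area = sum(.data$area), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "year", values_from = "area", values_fill = 0) %>%
    rename(area_start = dplyr::all_of(as.character(year_start)),
           area_end = dplyr::all_of(as.character(year_end)))
  gr <- annual_growth_rate(glob$area_start, glob$area_end, year_start, year_end)
  glob$rate <- gr$rate
  excluded <- glob %>%
    filter(is.na(.data$rate)) %>%
    mutate(status = if_else(.data$area_start <= 0, "novel", "discontinued")) %>%
    select("crop", "category", "status", "area_start", "area_end")
  ranking <- glob %>%
    filter(!is.na(.data$rate)) %>%
    arrange(desc(.data$rate), desc(abs(.data$area_end - .data$area_start)), .data$crop) %>%
    mutate(rank = row_number()) %>%
    select("crop", "category", "dependent", "area_start", "area_end", "rate", "rank")
  if (k > nrow(ranking) / 2) {
    stop_cropdivr(sprintf("k = %d exceeds half the eligible crop count (%d)", k, nrow(ranking)),
                  "cropdivr_validation_error")
  }
  top <- head(ranking, k)
  bottom <- utils::tail(ranking, k)
  counts <- matrix(
    c(sum(top$dependent), sum(!top$dependent),
      sum(bottom$dependent), sum(!bottom$dependent)),
    nrow = 2, byrow = TRUE,
    dimnames = list(set = c("top", "bottom"),
                    dependence = c("dependent", "nondependent"))
  )
  list(ranking = ranking, excluded = excluded, counts = counts)
}

#' Likelihood-ratio (G) test of independence for a 2x2 table
#'
#' `G = 2 * sum(O * log(O / E))` with expectations from the margins,
#' compared to a chi-square on 1 df. Optional small-sample corrections:
#' Williams (divide G by `q = 1 + (N/r1 + N/r2 - 1)(N/c1 + N/c2 - 1) /
#' (6N)`) or Yates (shift each observed count 0.5 toward its expectation).
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correction One of `"none"` (default), `"williams"`, `"yates"`.
#' @return Tibble `G`, `df`, `p_value`, `correction` of class
#'   `g_test_result`, with the counts as attribute.
#' @examples
#' g_test_2x2(matrix(c(16, 6, 4, 14), 2)) # G = 10.60
#' @export
g_test_2x2 <- function(counts, correction = c("none", "williams", "yates")) {
  correction <- match.arg(correction)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != floor(counts)) || anyNA(counts)) {
    stop_cropdivr("counts must be a 2x2 matrix of non-negative integers",
                  "cropdivr_validation_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_cropdivr("zero margin in 2x2 table", "cropdivr_validation_error")
  }
  N <- sum(counts)
  E <- outer(rowSums(counts), colSums(counts)) / N
  O <- counts
  if (correction == "yates") {
    O <- O + pmin(0.5, abs(E - O)) * sign(E - O)
  }
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  if (correction == "williams") {
    q <- 1 + (N / rowSums(counts)[1] + N / rowSums(counts)[2] - 1) *
      (N / colSums(counts)[1] + N / colSums(counts)[2] - 1) / (6 * N)
    G <- G / q
  }
  G <- max(G, 0)
  out <- tibble(G = G, df = 1L, p_value = pchisq(G, df = 1, lower.tail = FALSE),
                correction = correction)
  attr(out, "counts") <- counts
  class(out) <- c("g_test_result", class(out))
  out
}

#' Pearson correlation with pairwise-complete input
#'
#' Product-moment correlation with a two-sided t-based p-value; rows where
#' either value is missing are dropped pairwise (undefined growth rates
#' propagate as `NA` and should not silently shrink to an error).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble `r`, `n`, `t`, `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop_cropdivr("x and y must have equal length", "cropdivr_validation_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop_cropdivr("need at least 3 complete pairs", "cropdivr_validation_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop_cropdivr("zero variance in x or y", "cropdivr_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = n, t = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
}

#' Global trend series for the five headline variables
#'
#' Convenience wrapper building the percent-change series (from
#' `base_year`) of global total area, dependence share, effective number
#' of crops, richness and evenness, as plotted in long-run global trend
#' figures.
#'
#' @param panel A crop-area panel.
#' @param table A dependence table.
#' @param base_year Base year (default the earliest year present).
#' @inheritParams dependence_share
#' @return Tibble `variable`, `year`, `value`, `pct_change` stacking the
#'   five series.
#' @export
global_trends <- function(panel, table = load_dependence_table(), base_year = NULL,
                          unclassified = c("exclude", "error")) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  base_year <- base_year %||% min(panel$year)
  glob <- as_tibble(panel) %>%
    group_by(.data$crop, .data$year) %>%
    summarise(area = sum(.data$area), .groups = "drop") %>%
    mutate(entity = "Global") %>%
    as_crop_area_panel(provenance = "global aggregate")
  dep <- suppressWarnings(dependence_share(glob, table, unclassified = unclassified))
  div <- diversity_profile(glob)
  metrics <- left_join(
    div, dep %>% select("entity", "year", "total_area", "share"),
    by = c("entity", "year")
  )
  series <- list(
    area = c("total_area"), dependence = c("share"), diversity = c("eH"),
    richness = c("S"), evenness = c("J")
  )
  out <- bind_rows(lapply(names(series), function(v) {
    percent_change_series(
      tibble(year = metrics$year, value = metrics[[series[[v]]]]),
      base_year = base_year, variable = v
    )
  }))
  attr(out, "base_year") <- as.integer(base_year)
  class(out) <- c("percent_change_series", class(out))
  out
}
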