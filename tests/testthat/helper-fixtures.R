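# Shared fixture builders: everything is generated in code at test time.

make_panel <- function(...) {
  as_crop_area_panel(tibble::tribble(...))
}

# minimal two-country, two-crop panel spanning the endpoint years
tiny_panel <- function() {
  make_panel(
    ~entity, ~crop, ~year, ~area,
    "A", "wheat", 1961, 60,
    "A", "soy",   1961, 40,
    "A", "wheat", 2016, 60,
    "A", "soy",   2016, 140,
    "B", "wheat", 1961, 1000,
    "B", "soy",   1961, 1000,
    "B", "wheat", 2016, 1100,
    "B", "soy",   2016, 1100
  )
}

tiny_dependence <- function() {
  as_dependence_table(tibble::tibble(
    crop = c("wheat", "soy"),
    category = c("none", "modest")
  ))
}

# FAOSTAT-dialect CSV text for read_crop_area_table
faostat_csv <- function(df,
                        element = "Area harvested") {
  header <- "Area,Item,Element,Year,Unit,Value"
  rows <- sprintf("%s,%s,%s,%d,ha,%s", df$entity, df$crop, element, df$year,
                  ifelse(is.na(df$area), "", format(df$area, scientific = FALSE)))
  paste(c(header, rows), collapse = "\n")
}

# random positive share vector of length S summing to 1
random_shares <- function(S) {
  x <- stats::rexp(S) + 1e-6
  x / sum(x)
}

# simulate a growth-rate-like table with known region effects and
# per-region residual sds
simulate_region_data <- function(n_per_group, means, sds, beta_x = 0,
                                 regions = c("Africa", "America", "Asia", "Europe", "Oceania")) {
  stopifnot(length(means) == length(regions), length(sds) == length(regions))
  region <- factor(rep(regions, each = n_per_group), levels = regions)
  x <- stats::rnorm(length(region))
  y <- means[as.integer(region)] + beta_x * x +
    stats::rnorm(length(region), 0, sds[as.integer(region)])
  tibble::tibble(y = y, region = as.character(region), x = x)
}
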