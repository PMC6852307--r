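#' Area shares of crops for an entity-year
#'
#' Proportions `p_i` of the total cultivated area accounted for by each
#' crop with positive area. Zero-area crops are excluded: presence means
#' positive harvested area.
#'
#' @param panel A crop-area panel.
#' @param entity,year Entity and year to evaluate.
#' @return A named numeric vector of shares summing to 1, names are crops.
#' @export
crop_shares <- function(panel, entity, year) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  df <- as_tibble(panel)
  df <- df[df$entity == entity & df$year == year & df$area > 0, ]
  total <- sum(df$area)
  if (nrow(df) == 0 || total <= 0) {
    stop_cropdivr(sprintf("zero total area for (%s, %s)", entity, year),
                  "cropdivr_validation_error")
  }
  setNames(df$area / total, df$crop)
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over positive shares summing to 1 (natural
#' log; a deviation up to 1e-9 from unit sum is renormalized).
#'
#' @param shares Numeric vector of positive shares.
#' @return `H'` (0 for a single share).
#' @export
shannon_H <- function(shares) {
  if (length(shares) == 0 || !is.numeric(shares) || any(!is.finite(shares)) ||
      any(shares <= 0)) {
    stop_cropdivr("shares must be positive and finite", "cropdivr_validation_error")
  }
  s <- sum(shares)
  if (abs(s - 1) > 1e-9) {
    stop_cropdivr(sprintf("shares sum to %.12g, not 1", s), "cropdivr_validation_error")
  }
  p <- shares / s
  -sum(p * log(p))
}

#' Effective number of crops
#'
#' `exp(H')`: the number of equally-abundant crops that would yield the
#' observed Shannon index. Always in `[1, S]`.
#'
#' @param H Shannon index, `>= 0`.
#' @return `exp(H)`.
#' @export
effective_crops <- function(H) {
  if (!is.numeric(H) || anyNA(H) || any(H < 0)) {
    stop_cropdivr("H must be non-negative", "cropdivr_validation_error")
  }
  exp(H)
}

#' Pielou evenness
#'
#' `J = H'/log(S)`, in `[0, 1]`, equal to 1 when all crops occupy the same
#' area. Undefined (returned as `NA`) for `S = 1`, where `log(S) = 0`; such
#' values are excluded from growth-rate computations downstream rather than
#' forced to a convention.
#'
#' @param H Shannon index.
#' @param S Crop richness (number of crops with positive area), `>= 1`.
#' @return `J`, or `NA_real_` when `S == 1`.
#' @export
evenness_J <- function(H, S) {
  if (!is.numeric(S) || anyNA(S) || any(S < 1) || any(S != floor(S))) {
    stop_cropdivr("S must be a positive integer", "cropdivr_validation_error")
  }
  if_else(S >= 2, H / log(S), NA_real_)
}

#' Diversity profile of a panel
#'
#' One row of diversity metrics per requested entity-year: richness `S`,
#' Shannon `H`, effective number of crops `eH` and Pielou evenness `J`.
#' Entity-years with zero total area are absent from the output.
#'
#' @param panel A crop-area panel.
#' @param entities,years Optional filters; default everything present.
#' @return Tibble `entity`, `year`, `S`, `H`, `eH`, `J`.
#' @examples
#' p <- as_crop_area_panel(data.frame(
#'   entity = "A", crop = c("wheat", "soy"), year = 2000, area = c(50, 50)
#' ))
#' diversity_profile(p) # eH = 2, J = 1
#' @export
diversity_profile <- function(panel, entities = NULL, years = NULL) {
  panel <- as_crop_area_panel(panel, provenance = attr(panel, "provenance", exact = TRUE) %||% "user")
  df <- as_tibble(panel)
  if (!is.null(entities)) df <- df[df$entity %in% entities, ]
  if (!is.null(years)) df <- df[df$year %in% years, ]
  df <- df[df$area > 0, ]
  if (nrow(df) == 0) {
    stop_cropdivr("no positive-area records for the requested entity-years",
                  "cropdivr_validation_error")
  }
  df %>%
    group_by(.data$entity, .data$year) %>%
    summarise(
      S = dplyr::n_distinct(.data$crop),
      H = {
        p <- .data$area / sum(.data$area)
        -sum(p * log(p))
      },
      .groups = "drop"
    ) %>%
    mutate(
      eH = effective_crops(.data$H),
      J = evenness_J(.data$H, .data$S)
    ) %>%
    arrange(.data$entity, .data$year)
}
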