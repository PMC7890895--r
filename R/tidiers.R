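# broom-style tidiers for fitted objects.

#' Tidy an evolutionary rate fit
#'
#' @param x A `regevo_rate_fit` from [fit_rate()].
#' @param ... Unused.
#' @return Tibble with one row per category: `intercept` (%), `slope`
#'   (percentage points per MY), `slope_se`, `r_squared`, `n_points`.
#' @exportS3Method generics::tidy
tidy.regevo_rate_fit <- function(x, ...) {
  x$fits
}

#' One-row summary of an evolutionary rate fit
#'
#' @param x A `regevo_rate_fit`.
#' @param ... Unused.
#' @return Tibble with `n_categories`, `n_points`, `min_interaction_p`.
#' @exportS3Method generics::glance
glance.regevo_rate_fit <- function(x, ...) {
  tibble(
    n_categories = nrow(x$fits),
    n_points = nrow(x$points),
    min_interaction_p = if (nrow(x$interactions)) min(x$interactions$interaction_p)
    else NA_real_
  )
}

#' Tidy a signature transition model
#'
#' @param x A `regevo_transition_model` from [estimate_transition_model()].
#' @param ... Unused.
#' @return Long tibble with `ancestral`, `derived`, `probability`, `count`.
#' @exportS3Method generics::tidy
tidy.regevo_transition_model <- function(x, ...) {
  tidyr::expand_grid(ancestral = SIGNATURES, derived = SIGNATURES) |>
    mutate(probability = purrr::map2_dbl(.data$ancestral, .data$derived,
                                         ~ x$prob[.x, .y]),
           count = purrr::map2_dbl(.data$ancestral, .data$derived,
                                   ~ x$counts[.x, .y]))
}

#' One-row summary of a transition model
#'
#' @param x A `regevo_transition_model`.
#' @param ... Unused.
#' @return Tibble with per-state totals and the diagonal (stay)
#'   probabilities.
#' @exportS3Method generics::glance
glance.regevo_transition_model <- function(x, ...) {
  tibble(
    n_AP = unname(x$totals["AP"]), n_AE = unname(x$totals["AE"]),
    n_PE = unname(x$totals["PE"]),
    stay_AP = x$prob["AP", "AP"], stay_AE = x$prob["AE", "AE"],
    stay_PE = x$prob["PE", "PE"]
  )
}
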