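#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted mixed-model result
#'
#' @param x An `rs_model`.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `se`, `statistic`, `df` (linear models only), `p_value`.
#' @export
tidy.rs_model <- function(x, ...) x$coefficients

#' One-row model summary
#'
#' @param x An `rs_model`.
#' @param ... Unused.
#' @export
glance.rs_model <- function(x, ...) {
  tibble(
    family = x$family, bic = x$bic, n_obs = x$n_obs,
    converged = x$converged, singular = x$singular,
    simplified = x$simplified %||% NA_character_,
    max_vif = if (is.null(x$vif)) NA_real_ else max(x$vif$gvif_scaled^2)
  )
}

#' Tidy a recovery experiment
#'
#' @param x An `rs_recovery`.
#' @param ... Unused.
#' @return The per-replicate estimate table.
#' @export
tidy.rs_recovery <- function(x, ...) x$replicates

#' @export
glance.rs_recovery <- function(x, ...) summary(x)
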