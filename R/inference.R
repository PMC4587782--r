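#' Filter gameplay traces for analysis
#'
#' Applies the trace-selection rules used before any risk-attitude analysis:
#' the first game of each participant is a practice game and is dropped,
#' games beyond the fifth are dropped, and games lasting a single step are
#' removed.
#'
#' @param traces A trace tibble (see [generate_game()]).
#' @return The filtered trace tibble (games 2-5 with at least 2 played days).
#' @examples
#' # a participant with games 1..6 of lengths 3, 5, 1, 8, 2, 9 keeps 2, 4, 5
#' @export
filter_games <- function(traces) {
  traces |>
    dplyr::filter(.data$game_index >= 2L, .data$game_index <= 5L) |>
    dplyr::group_by(.data$participant_id, .data$game_index) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::ungroup()
}

#' Effective risk attitudes from traces
#'
#' Applies the response-curve inversion to every played day and keeps the
#' days where it is defined (infection present and contact reduced:
#' `0 < I < 1`, `r < r0`). Undefined days are excluded, never imputed.
#'
#' @param traces A trace tibble.
#' @param r0 Maximum contact radius (default 4).
#' @return A tibble of per-day records: `participant_id`, `game_index`,
#'   `day`, `alpha`, `log_alpha`. `alpha` is always positive.
#' @export
extract_alphas <- function(traces, r0 = 4) {
  traces |>
    dplyr::mutate(alpha = infer_alpha(.data$radius, .data$infection_load, r0)) |>
    dplyr::filter(!is.na(.data$alpha)) |>
    dplyr::mutate(log_alpha = log(.data$alpha)) |>
    dplyr::select(dplyr::all_of(c("participant_id", "game_index", "day",
                                  "alpha", "log_alpha")))
}

#' Per-game model fit: geometric-mean risk attitude and MAPE
#'
#' For each game, summarises the effective risk attitude as the geometric
#' mean over the game's defined days, predicts the radius at every observed
#' load from the response curve with that single attitude, and scores the
#' prediction with the mean absolute percentage error
#'
#'   MAPE_k = 100 / n_k * sum_t |r_t - rhat_t| / r_t
#'
#' over the game's `n_k` defined days. A 95% confidence interval for the
#' game's attitude is a t-interval on the mean log attitude (a modelling
#' choice; with a single defined day the interval is undefined). Games with
#' no defined day are reported with `n_steps = 0` and `NA` estimates (the
#' "no-fit" marker).
#'
#' @param traces A trace tibble.
#' @param r0 Maximum contact radius (default 4).
#' @return A tibble with one row per game: `participant_id`, `game_index`,
#'   `alpha_hat`, `alpha_low`, `alpha_high`, `mape`, `n_steps`.
#' @export
game_fit <- function(traces, r0 = 4) {
  games <- dplyr::distinct(traces, .data$participant_id, .data$game_index)
  records <- traces |>
    dplyr::mutate(alpha = infer_alpha(.data$radius, .data$infection_load, r0)) |>
    dplyr::filter(!is.na(.data$alpha))
  if (nrow(records) > 0 && any(records$radius <= 0)) {
    # r = 0 implies I = 1, which the inversion domain excludes
    stop("internal error: zero radius on a defined step", call. = FALSE)
  }
  fits <- records |>
    dplyr::group_by(.data$participant_id, .data$game_index) |>
    dplyr::summarise(
      alpha_hat = exp(mean(log(.data$alpha))),
      alpha_low = exp(.t_ci(log(.data$alpha))[1]),
      alpha_high = exp(.t_ci(log(.data$alpha))[2]),
      mape = .game_mape(.data$radius, .data$infection_load,
                        alpha_hat[1], r0),
      n_steps = dplyr::n(),
      .groups = "drop"
    )
  games |>
    dplyr::left_join(fits, by = c("participant_id", "game_index")) |>
    dplyr::mutate(n_steps = dplyr::coalesce(.data$n_steps, 0L))
}

# robust to the empty slice dplyr evaluates when no game has defined days
.game_mape <- function(radius, load, a_hat, r0) {
  if (length(radius) == 0 || is.na(a_hat)) return(NA_real_)
  100 * mean(abs(radius - response_radius(load, a_hat, r0)) / radius)
}

.t_ci <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  se <- stats::sd(x) / sqrt(n)
  mean(x) + c(-1, 1) * stats::qt(1 - (1 - level) / 2, n - 1) * se
}

#' Cohort summary of effective risk attitudes
#'
#' Sample moments of the per-day effective risk attitudes on the natural and
#' log scales. Skewness is the adjusted Fisher-Pearson coefficient
#' (`G1 = m3 / m2^(3/2) * sqrt(n(n-1)) / (n-2)`); a constant sample has
#' skewness 0 by convention.
#'
#' @param records An [extract_alphas()] tibble.
#' @return A tibble with one row per scale (`alpha`, `log_alpha`): `n`,
#'   `mean`, `sd`, `skewness`.
#' @export
summarize_alphas <- function(records) {
  dplyr::bind_rows(
    tibble::tibble(scale = "alpha", n = length(records$alpha),
                   mean = mean(records$alpha), sd = stats::sd(records$alpha),
                   skewness = .skewness(records$alpha)),
    tibble::tibble(scale = "log_alpha", n = length(records$log_alpha),
                   mean = mean(records$log_alpha),
                   sd = stats::sd(records$log_alpha),
                   skewness = .skewness(records$log_alpha))
  )
}

# adjusted Fisher-Pearson skewness; 0 for degenerate samples
.skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Plot observed responses against the fitted response curve
#'
#' Scatter of a game's chosen radii against the infection loads that
#' prompted them, with the response curve at the game's geometric-mean risk
#' attitude (solid) and its 95% confidence band (dashed), the usual visual
#' check of per-game model fit.
#'
#' @param traces A trace tibble, typically one game.
#' @param r0 Maximum contact radius (default 4).
#' @return A ggplot object, faceted by game if several are present.
#' @export
plot_game_fit <- function(traces, r0 = 4) {
  fits <- game_fit(traces, r0)
  grid <- tidyr::expand_grid(
    fits[!is.na(fits$alpha_hat), ],
    infection_load = seq(0.001, 0.999, length.out = 200)
  )
  grid$fit <- response_radius(grid$infection_load, grid$alpha_hat, r0)
  grid$low <- ifelse(is.na(grid$alpha_low), NA,
                     response_radius(grid$infection_load,
                                     pmax(grid$alpha_low, 1e-12), r0))
  grid$high <- ifelse(is.na(grid$alpha_high), NA,
                      response_radius(grid$infection_load, grid$alpha_high, r0))
  ggplot2::ggplot(traces,
                  ggplot2::aes(.data$infection_load, .data$radius)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$low),
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$high),
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::facet_wrap(~ participant_id + game_index,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "infection load", y = "chosen radius")
}
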