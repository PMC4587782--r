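#' Nested population models of log risk attitude
#'
#' The population model decomposes an individual's log risk attitude at a
#' given step into a population baseline plus normal random effects:
#'
#'   log(alpha_{i,k,t}) = mu + lambda_i + eta_{i,k} + eps_{i,k,t}
#'
#' with `lambda_i ~ N(0, sigma_participant^2)` drawn once per participant,
#' `eta_{i,k} ~ N(0, sigma_game^2)` once per participant-game, and
#' `eps_{i,k,t} ~ N(0, sigma_time^2)` independently at every step. The four
#' nested variants keep or drop components:
#'
#' * **A** — participant + game + time (all three sigmas),
#' * **B** — participant + time (`sigma_game = 0`),
#' * **C** — game + time (`sigma_participant = 0`; the game effect is shared
#'   across participants and indexed by game number),
#' * **D** — time only (both grouping sigmas 0).
#'
#' @param model One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param mu Baseline log risk attitude.
#' @param sigma_participant,sigma_game,sigma_time Nonnegative standard
#'   deviations of the participant, game and time components. Components the
#'   chosen model excludes must be 0 (and are forced to 0 with a warning-free
#'   check in [risk_model_preset()]).
#'
#' @return An object of class `risk_model_params`.
#' @seealso [risk_model_preset()] for the fitted values shipped as presets.
#' @export
risk_model_params <- function(model = "A", mu, sigma_participant = 0,
                              sigma_game = 0, sigma_time = 0) {
  model <- match.arg(model, c("A", "B", "C", "D"))
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  sig <- c(participant = sigma_participant, game = sigma_game,
           time = sigma_time)
  if (anyNA(sig) || any(sig < 0)) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  if (model %in% c("B", "D") && sigma_game != 0) {
    stop("model ", model, " has no game component; `sigma_game` must be 0",
         call. = FALSE)
  }
  if (model %in% c("C", "D") && sigma_participant != 0) {
    stop("model ", model, " has no participant component; ",
         "`sigma_participant` must be 0", call. = FALSE)
  }
  structure(
    list(model = model, mu = mu,
         sigma_participant = sigma_participant,
         sigma_game = sigma_game,
         sigma_time = sigma_time),
    class = "risk_model_params"
  )
}

#' Fitted population-model presets
#'
#' Named presets carrying the maximum-likelihood estimates of the four nested
#' models of log risk attitude obtained from the participatory-game cohort
#' (230 participants, games 2-5). Model A, the preset used for the epidemic
#' simulations, has baseline `mu = -1.934` with participant, game and time
#' standard deviations 0.7354, 0.2730 and 0.5833.
#'
#' @param model One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A [risk_model_params()] object.
#' @examples
#' risk_model_preset("A")
#' @export
risk_model_preset <- function(model = "A") {
  model <- match.arg(model, c("A", "B", "C", "D"))
  switch(model,
    A = risk_model_params("A", mu = -1.934, sigma_participant = 0.7354,
                          sigma_game = 0.2730, sigma_time = 0.5833),
    B = risk_model_params("B", mu = -2.004, sigma_participant = 0.7935,
                          sigma_time = 0.6719),
    C = risk_model_params("C", mu = -2.382, sigma_game = 0.1697,
                          sigma_time = 0.9544),
    D = risk_model_params("D", mu = -2.325, sigma_time = 0.9628)
  )
}

#' @export
print.risk_model_params <- function(x, ...) {
  cat(sprintf(
    "<risk_model_params> model %s: mu = %g, sd(participant) = %g, sd(game) = %g, sd(time) = %g\n",
    x$model, x$mu, x$sigma_participant, x$sigma_game, x$sigma_time
  ))
  invisible(x)
}

#' Sample log risk attitudes from a nested population model
#'
#' Draws a full participant x game x step array of log risk attitudes from
#' the nested normal model, in tidy long form. The participant effect is
#' drawn once per participant, the game effect once per participant-game
#' pair, and the step effect independently at every step.
#'
#' @param params A [risk_model_params()] object.
#' @param n_participants,n_games,n_steps Design size. `n_steps` may be a
#'   single count (balanced design) or a vector of per-game lengths recycled
#'   across participants (unbalanced design).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble with columns `participant`, `game`, `step`, `log_alpha`.
#' @examples
#' sample_log_alpha(risk_model_preset("D"), 2, 2, 3, seed = 1)
#' @export
sample_log_alpha <- function(params, n_participants, n_games, n_steps,
                             seed = NULL) {
  stopifnot(inherits(params, "risk_model_params"))
  if (n_participants < 1 || n_games < 1 || any(n_steps < 1)) {
    stop("design counts must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_participants <- as.integer(n_participants)
  n_games <- as.integer(n_games)
  steps_per_game <- as.integer(rep_len(n_steps, n_games))

  lambda <- stats::rnorm(n_participants, 0, params$sigma_participant)
  eta <- stats::rnorm(n_participants * n_games, 0, params$sigma_game)

  design <- tidyr::expand_grid(
    participant = seq_len(n_participants),
    game = seq_len(n_games)
  )
  design <- tidyr::uncount(design, steps_per_game[design$game],
                           .id = "step")
  gidx <- (design$participant - 1L) * n_games + design$game
  eps <- stats::rnorm(nrow(design), 0, params$sigma_time)
  design$log_alpha <- params$mu + lambda[design$participant] +
    eta[gidx] + eps
  design
}
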