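#' Generate one synthetic participatory game
#'
#' Emulates a focal "player" embedded in the lattice simulation, producing a
#' gameplay trace with the mechanics of the participatory game: the focal
#' susceptible observes its local infection load each day and sets its radius
#' by the response curve using that day's true log risk attitude; the
#' computer-controlled susceptibles all adopt the focal player's effective
#' risk attitude for the day (the response-curve inversion of the focal
#' choice, which equals the generating attitude whenever the inversion is
#' defined; on undefined days they keep the previous value, starting from
#' "no response" before any information is available). The game ends when the
#' focal player is infected, when no infected individuals remain (survivor),
#' or after a 60-day timeout. Each completed day credits points equal to the
#' number of neighbours the focal player contacted; survivors earn a bonus of
#' full-contact day-equivalents from the epidemic's end through day 60; no
#' points are credited on the day of the focal infection.
#'
#' @param geometry A [build_geometry()] object.
#' @param params An [epidemic_params()] object; games default to a 60-step
#'   cap via `game_params()`.
#' @param true_log_alpha Vector of the focal player's true per-day log risk
#'   attitudes (recycled to the day cap), e.g. one participant-game slice of
#'   [sample_log_alpha()].
#' @param participant_id,game_index Identifiers recorded in the trace.
#' @param seed Optional integer seed; with `NULL` the current RNG stream is
#'   used (as when called from [generate_cohort()]).
#'
#' @return A `game_trace` tibble with one row per played day: columns
#'   `participant_id`, `game_index`, `day`, `infection_load` (shown to the
#'   player), `radius` (chosen for the next day), `contacts`, `points`,
#'   `end_condition` (one of `"infected"`, `"survivor"`, `"timeout"`).
#'   Attributes: `end_condition`, `total_points` (day points plus any
#'   survivor bonus), `survivor_bonus`, `focal_node`.
#' @export
generate_game <- function(geometry, params = game_params(), true_log_alpha,
                          participant_id = 1L, game_index = 1L, seed = NULL) {
  stopifnot(inherits(geometry, "lattice_geometry"),
            inherits(params, "epidemic_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- geometry$n
  r0 <- geometry$r0
  day_cap <- min(params$max_steps, 60L)
  true_log_alpha <- rep_len(true_log_alpha, day_cap)

  focal <- sample.int(n, 1L)
  focal_nb <- geometry$nb_count[focal]
  state <- integer(n)
  n0 <- floor(params$initial_infected * n)
  others <- setdiff(seq_len(n), focal)
  if (n0 > 0) state[sample(others, min(n0, length(others)))] <- 1L

  day <- 0L
  rows <- vector("list", day_cap)
  end_condition <- NA_character_
  alpha_shared <- Inf   # computer agents: full contact until first defined day
  bonus <- 0

  if (!any(state == 1L)) {
    end_condition <- "survivor"
    bonus <- 60 * focal_nb
  }

  while (is.na(end_condition)) {
    day <- day + 1L
    loads <- local_infection_load(geometry, state == 1L)
    focal_load <- loads[focal]
    r_focal <- response_radius(focal_load, exp(true_log_alpha[day]), r0)
    a_eff <- infer_alpha(r_focal, focal_load, r0)
    if (!is.na(a_eff)) alpha_shared <- a_eff

    radii2 <- rep(r0 * r0, n)
    sus <- which(state == 0L)
    if (is.finite(alpha_shared)) {
      radii2[sus] <- response_radius(loads[sus], alpha_shared, r0)^2
    }
    radii2[focal] <- r_focal * r_focal

    res <- .step_transition(geometry, state, radii2, params$p, params$q)
    state <- res$state

    d2f <- geometry$d2[geometry$ei == focal]
    contacts_focal <- sum(d2f <= r_focal * r_focal)

    infected_now <- state[focal] == 1L
    if (infected_now) {
      end_condition <- "infected"
    } else if (!any(state == 1L)) {
      end_condition <- "survivor"
      bonus <- (60 - day) * focal_nb
    } else if (day >= day_cap) {
      end_condition <- "timeout"
    }

    rows[[day]] <- tibble::tibble(
      participant_id = participant_id,
      game_index = as.integer(game_index),
      day = day,
      infection_load = focal_load,
      radius = r_focal,
      contacts = contacts_focal,
      points = if (infected_now) 0L else contacts_focal
    )
  }

  trace <- if (day > 0L) dplyr::bind_rows(rows[seq_len(day)]) else
    tibble::tibble(
      participant_id = integer(), game_index = integer(), day = integer(),
      infection_load = double(), radius = double(), contacts = integer(),
      points = integer()
    )
  trace$end_condition <- rep(end_condition, nrow(trace))
  structure(
    trace,
    end_condition = end_condition,
    total_points = sum(trace$points) + bonus,
    survivor_bonus = bonus,
    focal_node = focal,
    class = c("game_trace", class(trace))
  )
}

#' Game-length epidemic parameters
#'
#' The epidemic parameters used inside games: the experimental values
#' `p = 0.05`, `q = 0.2`, `I0 = 0.06`, with the 60-day game timeout as the
#' step cap.
#'
#' @inheritParams epidemic_params
#' @return An [epidemic_params()] object with `max_steps = 60`.
#' @export
game_params <- function(p = 0.05, q = 0.2, initial_infected = 0.06) {
  epidemic_params(p, q, initial_infected, max_steps = 60)
}

#' Generate a synthetic gameplay cohort
#'
#' Draws each participant's per-day log risk attitudes from the nested
#' population model (participant effect fixed across their games, game effect
#' per game, step effect per day) and plays one synthetic game per
#' participant-game pair.
#'
#' @param geometry A [build_geometry()] object.
#' @param n_participants,n_games Cohort design.
#' @param model A [risk_model_params()] object (default the Model A preset).
#' @param params An [epidemic_params()] object (default [game_params()]).
#' @param seed Integer seed for the whole cohort.
#'
#' @return A tibble of stacked day rows for every game (the trace format of
#'   [generate_game()]).
#' @export
generate_cohort <- function(geometry, n_participants, n_games,
                            model = risk_model_preset("A"),
                            params = game_params(), seed = NULL) {
  stopifnot(inherits(model, "risk_model_params"))
  if (!is.null(seed)) set.seed(seed)
  day_cap <- min(params$max_steps, 60L)
  out <- vector("list", n_participants * n_games)
  idx <- 0L
  for (i in seq_len(n_participants)) {
    lambda <- stats::rnorm(1, 0, model$sigma_participant)
    for (k in seq_len(n_games)) {
      eta <- stats::rnorm(1, 0, model$sigma_game)
      eps <- stats::rnorm(day_cap, 0, model$sigma_time)
      idx <- idx + 1L
      g <- generate_game(
        geometry, params,
        true_log_alpha = model$mu + lambda + eta + eps,
        participant_id = i, game_index = k
      )
      # drop the per-game attributes; the stacked cohort is a plain tibble
      out[[idx]] <- tibble::as_tibble(unclass(g)[names(g)])
    }
  }
  dplyr::bind_rows(out)
}

#' Write and read gameplay traces
#'
#' Traces are stored as plain CSV with one row per played day and columns
#' `participant_id`, `game_index`, `day`, `infection_load`, `radius`,
#' `contacts`, `points`, `end_condition`. Values round-trip exactly through
#' the pair of functions.
#'
#' @param traces A trace tibble (stacked [generate_game()] rows).
#' @param file Path to the CSV file.
#' @return `write_traces()` returns `file` invisibly; `read_traces()` returns
#'   the trace tibble. Malformed rows raise an error naming the row.
#' @export
write_traces <- function(traces, file) {
  cols <- c("participant_id", "game_index", "day", "infection_load",
            "radius", "contacts", "points", "end_condition")
  missing <- setdiff(cols, names(traces))
  if (length(missing)) {
    stop("traces lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(traces)[cols], file)
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  traces <- readr::read_csv(
    file,
    col_types = readr::cols(
      participant_id = readr::col_integer(),
      game_index = readr::col_integer(),
      day = readr::col_integer(),
      infection_load = readr::col_double(),
      radius = readr::col_double(),
      contacts = readr::col_integer(),
      points = readr::col_integer(),
      end_condition = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(traces)
  if (nrow(prob) > 0) {
    stop("malformed trace row ", prob$row[1], ": ", prob$expected[1],
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(traces))
  if (length(bad)) {
    stop("malformed trace row ", bad[1], ": missing value", call. = FALSE)
  }
  bad_end <- which(!traces$end_condition %in%
                     c("infected", "survivor", "timeout"))
  if (length(bad_end)) {
    stop("malformed trace row ", bad_end[1], ": unknown end_condition",
         call. = FALSE)
  }
  traces
}
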