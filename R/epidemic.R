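#' Epidemic parameters
#'
#' Parameters of the discrete-time stochastic SIR dynamics. The defaults are
#' the values used throughout the participatory-game experiments: per-contact
#' transmission probability `p = 0.05`, per-step recovery probability
#' `q = 0.2`, 6% of the population initially infected, and a cap of 1000
#' steps (games use a 60-day cap instead).
#'
#' @param p Per-contact transmission probability, in `[0, 1]`.
#' @param q Per-step recovery probability, in `[0, 1]`.
#' @param initial_infected Initially infected fraction `I0`, in `[0, 1]`.
#' @param max_steps Maximum number of steps before the run is cut off.
#' @return An object of class `epidemic_params`.
#' @export
epidemic_params <- function(p = 0.05, q = 0.2, initial_infected = 0.06,
                            max_steps = 1000) {
  vals <- c(p = p, q = q, initial_infected = initial_infected)
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    stop("`p`, `q` and `initial_infected` must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(max_steps) || max_steps < 1) {
    stop("`max_steps` must be >= 1", call. = FALSE)
  }
  structure(
    list(p = p, q = q, initial_infected = initial_infected,
         max_steps = as.integer(max_steps)),
    class = "epidemic_params"
  )
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat(sprintf(
    "<epidemic_params> p = %g, q = %g, I0 = %g, max_steps = %d\n",
    x$p, x$q, x$initial_infected, x$max_steps
  ))
  invisible(x)
}

#' Local infection load
#'
#' The infection load an individual observes: the number of infected cases
#' within its awareness neighbourhood (radius `r0`, regardless of the current
#' contact radius) divided by the total number of neighbours there. Boundary
#' individuals have smaller neighbourhoods, so the same number of infected
#' neighbours produces a higher load near an edge.
#'
#' @param geometry A [build_geometry()] object.
#' @param infected Logical vector of length `geometry$n` (or a vector of
#'   infected node ids) marking currently infected individuals.
#' @param agents Optional node ids to return loads for; default all nodes.
#' @return Infection loads in `[0, 1]`.
#' @export
local_infection_load <- function(geometry, infected, agents = NULL) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  if (!is.logical(infected)) {
    idx <- as.integer(infected)
    infected <- rep(FALSE, geometry$n)
    infected[idx] <- TRUE
  }
  if (length(infected) != geometry$n) {
    stop("`infected` must mark nodes of this geometry", call. = FALSE)
  }
  loads <- as.numeric(geometry$adj %*% infected) / geometry$nb_count
  if (is.null(agents)) loads else loads[agents]
}

# One synchronous transition given the radii already chosen this step:
# contacts form under the symmetric min rule; each susceptible with m
# infected contacts *within its own radius* is infected with probability
# 1 - (1-p)^m; agents infected before the step recover with probability q.
# Newly infected agents cannot recover within the same step.
.step_transition <- function(geom, state, rsq, p, q) {
  inf <- state == 1L
  sus <- state == 0L
  within_i <- geom$d2 <= rsq[geom$ei]
  contacts <- sum(within_i & geom$d2 <= rsq[geom$ej]) / 2
  tmask <- within_i & sus[geom$ei] & inf[geom$ej]
  m <- tabulate(geom$ei[tmask], nbins = geom$n)
  cand <- which(m > 0L)
  newly <- cand[stats::runif(length(cand)) < 1 - (1 - p)^m[cand]]
  prev_inf <- which(inf)
  rec <- prev_inf[stats::runif(length(prev_inf)) < q]
  state[newly] <- 1L
  state[rec] <- 2L
  list(state = state, contacts = contacts, newly = newly)
}

#' Simulate one epidemic with spontaneous social distancing
#'
#' Runs the individual-based SIR dynamics on the lattice. At every step each
#' susceptible observes its local infection load, draws its risk attitude for
#' the step from the population model (`exp(mu + lambda_i + eta_i + eps_it)`,
#' with the participant effect `lambda_i` and the per-run effect `eta_i`
#' fixed for the run and the step effect redrawn each step), and sets its
#' contact radius by the response curve. Infected and recovered individuals
#' keep the full radius `r0`. Contacts then form, transmission and recovery
#' occur synchronously, and the step's undirected contact-pair count is
#' recorded. The run stops when no infected individuals remain or at
#' `max_steps`; full contact is assumed to resume once the epidemic is over,
#' so the contact volume adds the full-contact pair count for each remaining
#' step up to `max_steps`.
#'
#' @param geometry A [build_geometry()] object.
#' @param params An [epidemic_params()] object.
#' @param risk_model A [risk_model_params()] object governing behaviour, or
#'   `NULL` (equivalently the string `"no-response"`) for the no-response
#'   baseline in which all radii stay at `r0` throughout.
#' @param seed Optional integer seed; the run is fully reproducible under it.
#' @param record_series Keep the per-step S/I/R/contact series (default TRUE).
#'
#' @return An object of class `epidemic_sim` with elements `attack_rate`
#'   (final fraction ever infected), `peak_attack_rate` (maximum fraction
#'   simultaneously infected — peak prevalence), `duration` (steps until no
#'   infected remained, or `max_steps`), `contact_volume` (total undirected
#'   pair contacts over the `max_steps` horizon), and a `series` tibble
#'   (`step`, `S`, `I`, `R`, `contacts`; step 0 is the initial state).
#'   [glance()] returns the outcomes as a one-row tibble, [tidy()] the
#'   series.
#'
#' @examples
#' geom <- build_geometry(12, 4)
#' sim <- simulate_epidemic(geom, epidemic_params(max_steps = 100),
#'                          risk_model_preset("A"), seed = 1)
#' glance(sim)
#' @export
simulate_epidemic <- function(geometry, params = epidemic_params(),
                              risk_model = risk_model_preset("A"),
                              seed = NULL, record_series = TRUE) {
  stopifnot(inherits(geometry, "lattice_geometry"),
            inherits(params, "epidemic_params"))
  respond <- !is.null(risk_model) &&
    !(is.character(risk_model) && risk_model == "no-response")
  if (respond) stopifnot(inherits(risk_model, "risk_model_params"))
  if (!is.null(seed)) set.seed(seed)

  n <- geometry$n
  r0 <- geometry$r0
  state <- integer(n)                      # 0 = S, 1 = I, 2 = R
  n0 <- floor(params$initial_infected * n)
  if (n0 > 0) state[sample.int(n, n0)] <- 1L

  if (respond) {
    lambda <- stats::rnorm(n, 0, risk_model$sigma_participant)
    eta <- stats::rnorm(n, 0, risk_model$sigma_game)
  }

  max_steps <- params$max_steps
  contacts <- numeric(0)
  s_cnt <- integer(0); i_cnt <- integer(0); r_cnt <- integer(0)
  step <- 0L
  peak <- n0 / n

  while (any(state == 1L) && step < max_steps) {
    step <- step + 1L
    radii2 <- rep(r0 * r0, n)
    if (respond) {
      sus <- which(state == 0L)
      loads <- local_infection_load(geometry, state == 1L, sus)
      eps <- stats::rnorm(n, 0, risk_model$sigma_time)
      alpha <- exp(risk_model$mu + lambda[sus] + eta[sus] + eps[sus])
      radii2[sus] <- response_radius(loads, alpha, r0)^2
    }
    res <- .step_transition(geometry, state, radii2, params$p, params$q)
    state <- res$state
    ni <- sum(state == 1L)
    peak <- max(peak, ni / n)
    contacts <- c(contacts, res$contacts)
    if (record_series) {
      s_cnt <- c(s_cnt, sum(state == 0L))
      i_cnt <- c(i_cnt, ni)
      r_cnt <- c(r_cnt, sum(state == 2L))
    }
  }

  over <- !any(state == 1L)
  duration <- if (over) step else max_steps
  contact_volume <- sum(contacts) +
    (max_steps - step) * geometry$full_pairs

  series <- NULL
  if (record_series) {
    series <- tibble::tibble(
      step = 0:step,
      S = c(n - n0, s_cnt),
      I = c(n0, i_cnt),
      R = c(0L, r_cnt),
      contacts = c(NA_real_, contacts)
    )
  }

  structure(
    list(
      attack_rate = 1 - sum(state == 0L) / n,
      peak_attack_rate = peak,
      duration = duration,
      contact_volume = contact_volume,
      steps_run = step,
      completed = over,
      series = series,
      params = params,
      risk_model = if (respond) risk_model else NULL,
      seed = seed,
      n = n
    ),
    class = "epidemic_sim"
  )
}

#' @export
print.epidemic_sim <- function(x, ...) {
  arm <- if (is.null(x$risk_model)) "no-response" else
    paste0("model ", x$risk_model$model)
  cat(sprintf(
    "<epidemic_sim> %s arm, n = %d\n  attack rate %.3f, peak %.3f, duration %d steps, %.4g contacts\n",
    arm, x$n, x$attack_rate, x$peak_attack_rate, x$duration, x$contact_volume
  ))
  invisible(x)
}

#' @rdname simulate_epidemic
#' @param x An `epidemic_sim` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.epidemic_sim <- function(x, ...) {
  tibble::tibble(
    attack_rate = x$attack_rate,
    peak_attack_rate = x$peak_attack_rate,
    duration = x$duration,
    contact_volume = x$contact_volume,
    completed = x$completed,
    n_agents = x$n
  )
}

#' @rdname simulate_epidemic
#' @exportS3Method generics::tidy
tidy.epidemic_sim <- function(x, ...) {
  if (is.null(x$series)) {
    stop("run with `record_series = TRUE` to keep the per-step series",
         call. = FALSE)
  }
  x$series
}

#' Plot the S/I/R time series of a simulated epidemic
#'
#' @param object An `epidemic_sim` object (run with `record_series = TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.epidemic_sim <- function(object, ...) {
  series <- tidy(object)
  long <- tidyr::pivot_longer(series, c("S", "I", "R"),
                              names_to = "compartment", values_to = "count")
  long$compartment <- factor(long$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$count,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "individuals", colour = NULL)
}
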