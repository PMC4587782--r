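#' Fit a nested variance-component model of log risk attitude
#'
#' Maximum-likelihood fits of the four nested normal models of
#' `log(alpha_{i,k,t})` (see [risk_model_params()] for the model family):
#' Model A has participant and participant-nested game random intercepts,
#' Model B participant only, Model C a game-number random intercept shared
#' across participants, and Model D an intercept only. Models A-C are fitted
#' by ML (`REML = FALSE`) with [lme4::lmer()]; Model D has the closed-form
#' normal MLE. AIC uses the free-parameter counts 4 (A), 3 (B), 3 (C) and
#' 2 (D).
#'
#' @param records A tibble of per-step records with columns
#'   `participant_id` (or `participant`), `game_index` (or `game`) and
#'   `log_alpha`, e.g. from [extract_alphas()] or [sample_log_alpha()].
#' @param model One of `"A"`, `"B"`, `"C"`, `"D"`.
#'
#' @return An object of class `risk_model_fit`: the model label, the
#'   estimates (`mu`, `sigma_participant`, `sigma_game`, `sigma_time`; sigmas
#'   absent from the model are 0), the maximized log-likelihood, the AIC, the
#'   number of observations, and (for A-C) the underlying lme4 fit.
#'   [tidy()] returns the estimates as a tibble, [glance()] the fit summary.
#' @export
fit_risk_model <- function(records, model = c("A", "B", "C", "D")) {
  model <- match.arg(model)
  d <- .normalize_records(records)
  if (nrow(d) < 2) stop("need at least 2 observations", call. = FALSE)

  if (model == "D") {
    mu <- mean(d$log_alpha)
    sigma <- sqrt(mean((d$log_alpha - mu)^2))   # ML, not n-1
    if (sigma == 0) stop("degenerate data: zero variance", call. = FALSE)
    ll <- sum(stats::dnorm(d$log_alpha, mu, sigma, log = TRUE))
    return(.new_fit(model, mu, 0, 0, sigma, ll, k = 2, n = nrow(d),
                    fit = NULL))
  }

  if (model == "A") {
    n_games_per_part <- tapply(d$game, d$participant,
                               function(g) length(unique(g)))
    if (all(n_games_per_part < 2)) {
      stop("model A needs at least one participant with 2 or more games",
           call. = FALSE)
    }
    fit <- lme4::lmer(
      log_alpha ~ 1 + (1 | participant) + (1 | participant:game),
      data = d, REML = FALSE
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    sp <- sqrt(vc$vcov[vc$grp == "participant"])
    sg <- sqrt(vc$vcov[vc$grp == "participant:game"])
    st <- sqrt(vc$vcov[vc$grp == "Residual"])
    return(.new_fit(model, lme4::fixef(fit)[[1]], sp, sg, st,
                    as.numeric(stats::logLik(fit)), k = 4, n = nrow(d),
                    fit = fit))
  }

  if (model == "B") {
    fit <- lme4::lmer(log_alpha ~ 1 + (1 | participant), data = d,
                      REML = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sp <- sqrt(vc$vcov[vc$grp == "participant"])
    st <- sqrt(vc$vcov[vc$grp == "Residual"])
    return(.new_fit(model, lme4::fixef(fit)[[1]], sp, 0, st,
                    as.numeric(stats::logLik(fit)), k = 3, n = nrow(d),
                    fit = fit))
  }

  # model C: game-number effect shared across participants
  fit <- lme4::lmer(log_alpha ~ 1 + (1 | game), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sg <- sqrt(vc$vcov[vc$grp == "game"])
  st <- sqrt(vc$vcov[vc$grp == "Residual"])
  .new_fit(model, lme4::fixef(fit)[[1]], 0, sg, st,
           as.numeric(stats::logLik(fit)), k = 3, n = nrow(d), fit = fit)
}

.normalize_records <- function(records) {
  nm <- names(records)
  part <- if ("participant_id" %in% nm) records$participant_id else
    if ("participant" %in% nm) records$participant else
      stop("records need a `participant` or `participant_id` column",
           call. = FALSE)
  game <- if ("game_index" %in% nm) records$game_index else
    if ("game" %in% nm) records$game else
      stop("records need a `game` or `game_index` column", call. = FALSE)
  if (!"log_alpha" %in% nm) {
    stop("records need a `log_alpha` column", call. = FALSE)
  }
  tibble::tibble(
    participant = factor(part),
    game = factor(game),
    log_alpha = records$log_alpha
  )
}

.new_fit <- function(model, mu, sp, sg, st, ll, k, n, fit) {
  structure(
    list(
      model = model,
      mu = unname(mu),
      sigma_participant = unname(sp),
      sigma_game = unname(sg),
      sigma_time = unname(st),
      logLik = ll,
      n_par = k,
      AIC = 2 * k - 2 * ll,
      n_obs = n,
      fit = fit
    ),
    class = "risk_model_fit"
  )
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat(sprintf(
    "<risk_model_fit> model %s (ML), n = %d\n  mu = %.4g, sd(participant) = %.4g, sd(game) = %.4g, sd(time) = %.4g\n  logLik = %.2f, AIC = %.1f\n",
    x$model, x$n_obs, x$mu, x$sigma_participant, x$sigma_game,
    x$sigma_time, x$logLik, x$AIC
  ))
  invisible(x)
}

#' @rdname fit_risk_model
#' @param x A `risk_model_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.risk_model_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma_participant", "sigma_game", "sigma_time"),
    estimate = c(x$mu, x$sigma_participant, x$sigma_game, x$sigma_time)
  )
}

#' @rdname fit_risk_model
#' @exportS3Method generics::glance
glance.risk_model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    mu = x$mu,
    sigma_participant = x$sigma_participant,
    sigma_game = x$sigma_game,
    sigma_time = x$sigma_time,
    logLik = x$logLik,
    n_par = x$n_par,
    AIC = x$AIC,
    n_obs = x$n_obs
  )
}

#' Fit and compare all four variance-component models
#'
#' Fits Models A-D by maximum likelihood on identical records and tabulates
#' them by AIC.
#'
#' @inheritParams fit_risk_model
#' @return A tibble with one row per model (columns of
#'   [glance.risk_model_fit()] plus `delta_AIC`), sorted by AIC.
#' @export
compare_risk_models <- function(records) {
  fits <- purrr::map(c("A", "B", "C", "D"),
                     function(m) glance(fit_risk_model(records, m)))
  out <- dplyr::arrange(dplyr::bind_rows(fits), .data$AIC)
  out$delta_AIC <- out$AIC - out$AIC[1]
  out
}
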