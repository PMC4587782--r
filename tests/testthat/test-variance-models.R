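records_from <- function(draws) {
  dplyr::rename(draws, participant_id = participant, game_index = game)
}

test_that("the intercept-only model has its closed-form normal MLE", {
  rec <- tibble::tibble(participant_id = 1:3, game_index = 2L,
                        log_alpha = c(-1, -2, -3))
  fit <- fit_risk_model(rec, "D")
  expect_equal(fit$mu, -2)
  expect_equal(fit$sigma_time, sqrt(2 / 3))
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$logLik)
  expect_equal(fit$n_par, 2)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mu"], -2)
})

test_that("fits refuse degenerate inputs", {
  expect_error(fit_risk_model(tibble::tibble(participant_id = 1,
                                             game_index = 2,
                                             log_alpha = -1), "D"),
               "at least 2")
  expect_error(fit_risk_model(tibble::tibble(participant_id = 1:4,
                                             game_index = 2,
                                             log_alpha = rep(-1, 4)), "D"),
               "degenerate")
  # model A needs repeated games within a participant
  one_game <- tibble::tibble(participant_id = rep(1:5, each = 3),
                             game_index = 2L,
                             log_alpha = rnorm(15))
  expect_error(fit_risk_model(one_game, "A"), "2 or more games")
})

test_that("the participant model agrees with direct likelihood optimization", {
  set.seed(21)
  # one grouping factor (participant), deliberately unbalanced sizes
  sizes <- sample(3:10, 12, replace = TRUE)
  b <- rnorm(12, 0, 0.8)
  rec <- tibble::tibble(
    participant_id = rep(seq_len(12), sizes),
    game_index = 2L,
    log_alpha = -2 + rep(b, sizes) + rnorm(sum(sizes), 0, 0.6)
  )
  fit <- fit_risk_model(rec, "B")
  nll <- function(par) {
    -oneway_loglik(rec$log_alpha, rec$participant_id, par[1],
                   exp(par[2]), exp(par[3]))
  }
  opt <- optim(c(-1, 0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-4)
  expect_equal(fit$mu, opt$par[1], tolerance = 1e-3)
  expect_equal(fit$sigma_participant, exp(opt$par[2]), tolerance = 1e-2)
  expect_equal(fit$sigma_time, exp(opt$par[3]), tolerance = 1e-2)
})

test_that("the full nested model recovers its generating parameters", {
  truth <- risk_model_preset("A")
  draws <- sample_log_alpha(truth, 230, 4, 14, seed = 101)
  fit <- fit_risk_model(records_from(draws), "A")
  expect_lt(abs(fit$mu - truth$mu), 0.15)
  expect_lt(abs(fit$sigma_participant - truth$sigma_participant) /
              truth$sigma_participant, 0.25)
  expect_lt(abs(fit$sigma_game - truth$sigma_game) / truth$sigma_game, 0.25)
  expect_lt(abs(fit$sigma_time - truth$sigma_time) / truth$sigma_time, 0.25)
})

test_that("log-likelihoods respect model nesting and AIC ranks the truth", {
  draws <- sample_log_alpha(risk_model_preset("A"), 120, 4, 10, seed = 5)
  rec <- records_from(draws)
  cmp <- compare_risk_models(rec)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$delta_AIC[1], 0)
  ll <- setNames(cmp$logLik, cmp$model)
  expect_gte(ll["A"], ll["B"])
  expect_gte(ll["B"], ll["D"])
  aic <- setNames(cmp$AIC, cmp$model)
  expect_lt(aic["A"], aic["B"])
  expect_lt(aic["B"], aic["D"])
  # identical records give identical tables
  expect_equal(compare_risk_models(rec), cmp)
})

test_that("no-signal data does not reward the complex model much", {
  draws <- sample_log_alpha(risk_model_params("D", mu = -2.3,
                                              sigma_time = 0.96),
                            100, 4, 10, seed = 6)
  cmp <- compare_risk_models(records_from(draws))
  aic <- setNames(cmp$AIC, cmp$model)
  expect_lt(aic["A"] - aic["D"], 10)
})

test_that("estimates are invariant to participant relabelling", {
  draws <- sample_log_alpha(risk_model_preset("A"), 30, 3, 6, seed = 13)
  rec <- records_from(draws)
  perm <- sample(30)
  rec2 <- dplyr::mutate(rec, participant_id = perm[participant_id])
  f1 <- fit_risk_model(rec, "A")
  f2 <- fit_risk_model(rec2, "A")
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
  expect_equal(f1$sigma_participant, f2$sigma_participant, tolerance = 1e-5)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("the game-number model reads the shared game effect", {
  set.seed(17)
  # explicit game-number shifts shared by all participants
  shifts <- c(`2` = 0.5, `3` = -0.5, `4` = 0.2, `5` = -0.2)
  rec <- tidyr::expand_grid(participant_id = 1:50, game_index = 2:5,
                            step = 1:8)
  rec$log_alpha <- -2 + shifts[as.character(rec$game_index)] +
    rnorm(nrow(rec), 0, 0.3)
  fit <- fit_risk_model(rec, "C")
  expect_equal(fit$mu, -2, tolerance = 0.15)
  expect_gt(fit$sigma_game, 0.2)
  expect_equal(fit$sigma_time, 0.3, tolerance = 0.05)
  expect_equal(fit$n_par, 3)
})
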