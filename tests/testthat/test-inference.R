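test_that("trace filtering drops practice, late and one-step games", {
  lens <- c(3, 5, 1, 8, 2, 9)
  traces <- dplyr::bind_rows(lapply(seq_along(lens), function(k) {
    make_trace(1, k, loads = rep(0.1, lens[k]), radii = rep(3, lens[k]))
  }))
  kept <- filter_games(traces)
  expect_setequal(unique(kept$game_index), c(2L, 4L, 5L))
  # all games one step long: nothing survives
  ones <- dplyr::bind_rows(lapply(1:4, function(k) {
    make_trace(1, k, loads = 0.1, radii = 3)
  }))
  expect_equal(nrow(filter_games(ones)), 0)
})

test_that("filtering matches an independent recount on a random cohort", {
  set.seed(55)
  raw <- list()
  for (i in 1:40) {
    n_games <- sample(1:7, 1)
    for (k in seq_len(n_games)) {
      len <- sample(c(1, 1, 2:20), 1)   # ~10% one-step games
      raw[[length(raw) + 1]] <- make_trace(i, k, runif(len, 0, 0.8),
                                           runif(len, 0, 4))
    }
  }
  traces <- dplyr::bind_rows(raw)
  kept <- filter_games(traces)
  # brute-force recount of which games the rules retain
  manual <- 0
  for (i in 1:40) {
    for (k in 2:5) {
      len <- sum(traces$participant_id == i & traces$game_index == k)
      if (len > 1) manual <- manual + 1
    }
  }
  expect_equal(nrow(dplyr::distinct(kept, participant_id, game_index)),
               manual)
})

test_that("alpha extraction applies the inversion on defined days only", {
  # every day at full radius (zero load): nothing extractable
  t0 <- make_trace(1, 2, loads = rep(0, 5), radii = rep(4, 5))
  expect_equal(nrow(extract_alphas(t0)), 0)
  t1 <- make_trace(1, 2, loads = c(0, 0.25, 1), radii = c(4, 2, 0))
  rec <- extract_alphas(t1)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$alpha, log(0.75) / log(0.25), tolerance = 1e-12)
  expect_equal(rec$log_alpha, log(rec$alpha))
  expect_true(all(extract_alphas(t1)$alpha > 0))
})

test_that("a noise-free response trace fits with zero error", {
  loads <- c(0.1, 0.3, 0.5, 0.7, 0.2)
  trace <- response_trace(3, 2, loads, alpha = 0.2)
  fit <- game_fit(trace)
  expect_equal(fit$alpha_hat, 0.2, tolerance = 1e-10)
  expect_equal(fit$mape, 0, tolerance = 1e-8)
  expect_equal(fit$n_steps, length(loads))
})

test_that("MAPE matches a hand computation on a noisy game", {
  loads <- c(0.2, 0.4, 0.6)
  radii <- c(3.1, 2.0, 1.4)
  trace <- make_trace(1, 3, loads, radii)
  fit <- game_fit(trace)
  alphas <- log(1 - (radii / 4)^2) / log(loads)
  a_hat <- exp(mean(log(alphas)))
  r_hat <- 4 * sqrt(1 - loads^a_hat)
  expect_equal(fit$alpha_hat, a_hat, tolerance = 1e-12)
  expect_equal(fit$mape, 100 * mean(abs(radii - r_hat) / radii),
               tolerance = 1e-12)
})

test_that("games with no defined day get the no-fit marker", {
  trace <- make_trace(1, 2, loads = rep(0, 4), radii = rep(4, 4))
  fit <- game_fit(trace)
  expect_equal(fit$n_steps, 0L)
  expect_true(is.na(fit$alpha_hat))
  expect_true(is.na(fit$mape))
})

test_that("per-step attitude noise spreads MAPE with a worst-fit tail", {
  set.seed(12)
  params <- risk_model_preset("A")
  games <- lapply(1:300, function(k) {
    len <- sample(5:20, 1)
    loads <- runif(len, 0.05, 0.8)
    log_a <- params$mu + rnorm(1, 0, params$sigma_participant) +
      rnorm(1, 0, params$sigma_game) + rnorm(len, 0, params$sigma_time)
    make_trace(k, 2, loads, response_radius(loads, exp(log_a), 4))
  })
  fits <- game_fit(dplyr::bind_rows(games))
  expect_true(all(fits$mape > 0))
  # a minority of games fits notably worse than the typical game
  expect_gt(max(fits$mape), 1.5 * median(fits$mape))
  expect_gt(epidistance:::.skewness(fits$mape), 0)
})

test_that("cohort moments behave on known distributions", {
  const <- tibble::tibble(alpha = rep(0.2, 10), log_alpha = log(rep(0.2, 10)))
  s <- summarize_alphas(const)
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$skewness, c(0, 0))
  set.seed(31)
  # lognormal attitudes near the cohort scale: strong skew on the natural
  # scale (moment formula gives ~6.2 at sigma = 1), none on the log scale
  la <- rnorm(20000, -2.2, 1)
  s2 <- summarize_alphas(tibble::tibble(alpha = exp(la), log_alpha = la))
  expect_gt(s2$skewness[s2$scale == "alpha"], 3)
  expect_lt(abs(s2$skewness[s2$scale == "log_alpha"]), 0.1)
})

test_that("extracted log attitudes from nested-model cohorts are near normal", {
  draws <- sample_log_alpha(risk_model_preset("A"), 500, 4, 10, seed = 77)
  expect_lt(abs(epidistance:::.skewness(draws$log_alpha)), 0.5)
})
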