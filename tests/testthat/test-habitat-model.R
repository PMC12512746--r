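# synthetic design with a planted generative predictor
planted_design <- function(n, seed, signal = "dist_channel_m", sd = 1,
                           beta = 3) {
  set.seed(seed)
  d <- tibble::tibble(
    dist_channel_m = runif(n, 0, 2000),
    dist_reef_m = runif(n, 0, 1500),
    depth_m = runif(n, 1, 60),
    prop_sand = runif(n),
    sex = sample(c("F", "M"), n, TRUE),
    tod = sample(c("dawn", "day", "dusk", "night"), n, TRUE)
  )
  d$degree <- pmax(0, beta * (2000 - d[[signal]]) / 2000 + rnorm(n, sd = sd))
  d
}

test_that("the design split is a seeded, exhaustive 75/25 partition", {
  d <- planted_design(100, 1)
  sp <- split_design(d, seed = 42)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  expect_equal(nrow(dplyr::bind_rows(sp$train, sp$test)), 100)

  sp2 <- split_design(d, seed = 42)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_design(d, seed = 43)
  expect_false(identical(sp$train, sp3$train))

  expect_error(split_design(d[1:7, ], seed = 1), "fewer than 8")
})

test_that("grid tuning returns the CV-RMSE argmin, deterministically", {
  d <- planted_design(200, 3)
  one <- settings_grid(3L, 0.1, 0.75, 150L)
  best <- tune_boosted_model(d, grid = one, seed = 9)
  expect_equal(best$interaction_depth, 3L)
  expect_equal(best$shrinkage, 0.1)

  grid <- settings_grid(c(1L, 4L), c(0.1, 0.3), 0.75, 150L)
  b1 <- tune_boosted_model(d, grid = grid, seed = 9)
  cv <- attr(b1, "cv_results")
  expect_equal(min(cv$cv_rmse), b1$cv_rmse)
  b2 <- tune_boosted_model(d, grid = grid, seed = 9)
  expect_equal(b1$cv_rmse, b2$cv_rmse)
  expect_equal(b1$interaction_depth, b2$interaction_depth)

  flat <- dplyr::mutate(d, degree = 1)
  expect_error(tune_boosted_model(flat, grid = one, seed = 1), "zero variance")
})

test_that("relative influence finds a planted predictor and sums to 100", {
  s <- settings_grid(3L, 0.1, 0.75, 200L)
  hits <- 0
  for (seed in 1:5) {
    d <- planted_design(500, seed, signal = "dist_channel_m", sd = 0.6)
    fit <- fit_boosted_model(d, s, seed = seed)
    expect_equal(sum(fit$importance$relative_influence), 100, tolerance = 1e-6)
    hits <- hits + (fit$importance$predictor[1] == "dist_channel_m")
  }
  expect_gte(hits, 4)  # dominant generative predictor tops the ranking

  # pure-noise response: no predictor towers over the rest consistently
  top_share <- vapply(1:5, function(seed) {
    set.seed(seed)
    d <- planted_design(300, seed)
    d$degree <- rnorm(300)
    f <- fit_boosted_model(d, s, seed = seed)
    f$importance$relative_influence[1]
  }, numeric(1))
  expect_lt(median(top_share), 50)
})

test_that("hold-out evaluation is a Spearman correlation with clear edge cases", {
  s <- settings_grid(3L, 0.1, 0.75, 200L)
  d <- planted_design(400, 11, sd = 0.4)
  sp <- split_design(d, seed = 11)
  fit <- fit_boosted_model(sp$train, s, seed = 11)
  rho <- evaluate_holdout(fit, sp$test)
  expect_gt(rho, 0.5)  # strong planted signal survives the hold-out

  # shuffling the response destroys the correlation
  rhos <- vapply(1:5, function(seed) {
    set.seed(seed)
    d2 <- d
    d2$degree <- sample(d2$degree)
    sp2 <- split_design(d2, seed = seed)
    f2 <- fit_boosted_model(sp2$train, s, seed = seed)
    evaluate_holdout(f2, sp2$test)
  }, numeric(1))
  expect_gte(sum(abs(rhos) < 0.3), 4)

  # constant predictions: undefined correlation is signalled, not silent
  d3 <- planted_design(100, 2)
  const_fit <- fit_boosted_model(d3, settings_grid(1L, 1e-10, 1, 1L), seed = 1)
  expect_warning(r <- evaluate_holdout(const_fit, d3), "undefined")
  expect_true(is.na(r))
})

test_that("the full protocol composes and records the split seed", {
  d <- planted_design(300, 21, sd = 0.5)
  fit <- fit_habitat_model(d, grid = settings_grid(c(1L, 3L), 0.1, 0.75, 150L),
                           seed = 21)
  expect_s3_class(fit, "habitat_gbm")
  expect_equal(fit$split_seed, 21)
  expect_gt(fit$rho_test, 0.5)
  g <- glance(fit)
  expect_named(g, c("interaction_depth", "shrinkage", "bag_fraction",
                    "n_trees", "r2_train", "rho_test"))
  expect_equal(tidy(fit), fit$importance)
})

test_that("design assembly stacks periods and honours the 3-node rule", {
  sim <- small_sim()
  cov <- assemble_node_covariates(sim$sim$scene, sim$sim$stations)
  des <- assemble_design(sim$annotated, sim$sim$tags, cov,
                         species = "grey_reef_shark")
  expect_true(all(c("degree", "tod", "sex", "dist_channel_m",
                    "dist_reef_m", "depth_m") %in% names(des)))
  expect_true(all(des$tod %in% PERIOD_LEVELS_TEST))
  expect_true(all(des$degree >= 0))
  # every contributing individual spans >= 3 receivers overall
  n_nodes <- sim$annotated %>%
    dplyr::filter(tag_id %in% des$tag_id) %>%
    dplyr::group_by(tag_id) %>%
    dplyr::summarise(n = dplyr::n_distinct(station_id))
  expect_true(all(n_nodes$n >= 3))

  flat <- assemble_design(sim$annotated, sim$sim$tags, cov,
                          species = "grey_reef_shark",
                          stack_by_period = FALSE)
  expect_false("tod" %in% names(flat))
  expect_equal(anyDuplicated(paste(flat$tag_id, flat$station_id)), 0)
})
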