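flat_data <- function(n = 200, seed = 1, f = function(x) 2 * x, noise = 0.1,
                      n_animals = 4, n_studies = 2) {
  set.seed(seed)
  x <- runif(n, -1, 1)
  data.frame(
    mxd_km = f(x) + rnorm(n, sd = noise),
    x = x,
    centroid_lat = 29, centroid_lon = -82,
    weight = 1,
    animal_id = sample(paste0("a", seq_len(n_animals)), n, TRUE),
    study_id = sample(paste0("s", seq_len(n_studies)), n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("design building reduces bases and drops degenerate terms", {
  d <- flat_data()
  # 3 distinct values: basis size drops to 3 with a warning
  d$few <- rep(c(0, 1, 2), length.out = nrow(d))
  spec <- gamm_spec("mxd", "overall", "meteorological", smooth_vars = c("x", "few"))
  expect_warning(des <- build_design(spec, d), "reduced to 3")
  expect_true(any(grepl("s\\(few", des$terms$smooth)))

  # 2 distinct values: demoted to a linear term
  d$bin <- rep(c(0, 1), length.out = nrow(d))
  spec1 <- gamm_spec("mxd", "overall", "meteorological", smooth_vars = "bin")
  expect_warning(des1 <- build_design(spec1, d), "demoted to linear")
  expect_true("bin" %in% des1$terms$linear)

  d$one <- factor("only")
  spec2 <- gamm_spec("mxd", "overall", "geographic", factor_vars = "one")
  expect_warning(des2 <- build_design(spec2, d), "one level")
  expect_false("one" %in% des2$terms$factor)

  # a covariate with 5 distinct values gets its basis reduced
  d$coarse <- rep(1:5, length.out = nrow(d))
  spec3 <- gamm_spec("mxd", "overall", "meteorological", smooth_vars = "coarse")
  expect_warning(des3 <- build_design(spec3, d), "reduced to 5")
})

test_that("penalized WLS solution matches the closed form at fixed smoothing", {
  d <- flat_data(n = 80, f = function(x) sin(2 * pi * x), noise = 0.3,
                 n_animals = 1, n_studies = 1)
  set.seed(2)
  d$weight <- runif(80, 0.5, 2)
  spec <- gamm_spec("mxd", "overall", "meteorological", smooth_vars = "x")
  des <- suppressWarnings(build_design(spec, d))
  dd <- des$data
  dd$.w <- des$weights
  fit <- mgcv::gam(des$formula, data = dd, weights = .w,
                   knots = des$knots, sp = c(0.7, 0.05), select = TRUE)
  X <- stats::predict(fit, type = "lpmatrix")
  S <- matrix(0, ncol(X), ncol(X))
  sm <- fit$smooth[[1]]
  idx <- sm$first.para:sm$last.para
  for (j in seq_along(sm$S)) {
    S[idx, idx] <- S[idx, idx] + fit$full.sp[j] * sm$S[[j]]
  }
  w <- des$weights
  y <- des$data$mxd_km
  beta <- solve(t(X) %*% (w * X) + S, t(X) %*% (w * y))
  expect_equal(unname(stats::coef(fit)), as.numeric(beta), tolerance = 1e-8)
})

test_that("smooths recover a line, shrink pure noise, and ignore weight scale", {
  d <- flat_data(n = 600, seed = 4, noise = 0.1)
  d$junk <- rnorm(600)
  spec <- gamm_spec("mxd", "overall", "meteorological",
                    smooth_vars = c("x", "junk"))
  fit <- fit_gamm(spec, d)
  rn <- reaction_norm(fit, "x")
  # fitted effect within 0.05 of the centred line over the central 80 percent
  g <- rn$curve
  mid <- g$covariate > quantile(d$x, 0.1) & g$covariate < quantile(d$x, 0.9)
  expect_lt(max(abs(g$effect[mid] - 2 * (g$covariate[mid] - mean(g$covariate)))),
            0.06)
  edf <- fit$smooth_table[, "edf"]
  expect_lt(edf[["s(x)"]], 2.5)               # ~ linear
  expect_gt(edf[["s(x)"]], 0.8)
  # pure-noise covariate: shrinkage collapses the smooth
  expect_lt(edf[["s(junk)"]], 1.5)
  rn_j <- reaction_norm(fit, "junk")
  expect_lt(max(abs(rn_j$curve$effect)), 0.1)
  # effect curves are centred
  expect_lt(abs(mean(rn$curve$effect)), 1e-8)

  d10 <- d; d10$weight <- d$weight * 10
  fit10 <- fit_gamm(spec, d10)
  expect_equal(stats::coef(fit10$fit), stats::coef(fit$fit), tolerance = 1e-6)
})

test_that("an unpenalized full basis interpolates noise-free data", {
  d <- flat_data(n = 8, noise = 0, n_animals = 1, n_studies = 1)
  spec <- gamm_spec("mxd", "overall", "meteorological", smooth_vars = "x", k = 8)
  des <- suppressWarnings(build_design(spec, d))
  fit <- mgcv::gam(des$formula, data = des$data, knots = des$knots, sp = 0)
  expect_lt(sum(stats::resid(fit)^2), 1e-10)
})

test_that("reaction-norm concavity diagnostics classify known shapes", {
  flags <- vapply(1:10, function(seed) {
    d <- flat_data(n = 400, seed = seed, noise = 0.3)
    fit <- fit_gamm(gamm_spec("mxd", "overall", "meteorological",
                              smooth_vars = "x"), d)
    reaction_norm(fit, "x")$concavity
  }, character(1))
  expect_gte(sum(flags == "none"), 9) # linear truth is not called curved

  d <- flat_data(n = 600, seed = 2, f = function(x) -2 * x^2, noise = 0.2)
  fit <- fit_gamm(gamm_spec("mxd", "overall", "meteorological",
                            smooth_vars = "x"), d)
  rn <- reaction_norm(fit, "x")
  expect_equal(rn$concavity, "concave")
  expect_lt(abs(rn$argmax - 0), 0.25)
})

test_that("single-day runs contribute no lag pairs to the AR estimate", {
  res <- c(1.0, -2.0, 3.0)
  an <- c("a", "b", "c")
  day <- as.Date("2010-01-01") + c(0, 5, 9)
  expect_equal(movecap:::pooled_lag1(res, an, day), 0)
})

test_that("random intercepts and variance components are reported", {
  set.seed(10)
  n_an <- 30; per <- 25
  b <- rnorm(n_an, 0, 0.5)
  d <- data.frame(
    animal_id = rep(paste0("a", 1:n_an), each = per),
    study_id = rep(c("s1", "s2"), length.out = n_an * per),
    x = runif(n_an * per, -1, 1))
  d$mxd_km <- 1 + 0.5 * d$x + b[as.integer(sub("a", "", d$animal_id))] +
    rnorm(nrow(d), sd = 0.3)
  d$centroid_lat <- 29; d$centroid_lon <- -82; d$weight <- 1
  fit <- fit_gamm(gamm_spec("mxd", "monthly", "meteorological",
                            smooth_vars = "x"), d)
  vc <- fit$variance_components
  expect_true("s(animal_id)" %in% names(vc))
  expect_equal(unname(vc[["s(animal_id)"]]), 0.5, tolerance = 0.35)
  expect_true(is.finite(fit$adj_r2))
})
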