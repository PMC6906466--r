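test_that("cyclic basis is exactly periodic", {
  spec <- sm("x", bs = "cyclic", k = 10, period = 24)
  b <- build_basis(spec, seq(0, 23.5, by = 0.5))
  expect_equal(eval_basis(b, 0), eval_basis(b, 24), tolerance = 1e-12)
  expect_equal(eval_basis(b, 3.7), eval_basis(b, 27.7), tolerance = 1e-12)
})

test_that("the basis reproduces a sine to 1e-3 with 10 basis functions", {
  x <- seq(0, 23.9, by = 0.05)
  y <- sin(2 * pi * x / 24)
  for (spec in list(sm("x", bs = "cyclic", k = 10, period = 24),
                    sm("x", bs = "cubic", k = 12))) {
    b <- build_basis(spec, x)
    co <- qr.solve(cbind(1, b$X), y)
    expect_lt(max(abs(cbind(1, b$X) %*% co - y)), 1e-3)
  }
})

test_that("basis construction validates its inputs", {
  expect_error(sm("x", bs = "cyclic", k = 10), "period")
  expect_error(sm("x", k = 3), "k >= 4")
  expect_error(build_basis(sm("x", k = 10), rep(1:5, 4)), "distinct")
})

test_that("unpenalized fits agree with the stats::glm oracle", {
  set.seed(21)
  n <- 400
  x1 <- runif(n); x2 <- rnorm(n)
  eta <- 0.3 + 0.8 * x1 - 0.5 * x2
  # binomial
  d <- data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2)
  f <- fit_gam(d, "y", "binomial", linear = c("x1", "x2"))
  g <- glm(y ~ x1 + x2, binomial, d)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  # gamma, log link
  dg <- data.frame(y = rgamma(n, shape = 3, rate = 3 / exp(eta)),
                   x1 = x1, x2 = x2)
  fg <- fit_gam(dg, "y", "gamma", linear = c("x1", "x2"))
  gg <- glm(y ~ x1 + x2, Gamma(link = "log"), dg)
  expect_equal(unname(fg$coefficients), unname(coef(gg)), tolerance = 1e-5)
})

test_that("a strongly penalized cubic smooth collapses to the GLM on its
           null space", {
  set.seed(3)
  n <- 300; x <- runif(n)
  d <- data.frame(y = rbinom(n, 1, plogis(-0.3 + 1.2 * x)), x = x)
  f <- fit_gam(d, "y", "binomial", smooths = list(sm("x", k = 8)),
               fixed_lambda = c(x = 1e10))
  g <- glm(y ~ x, binomial, d)
  expect_lt(max(abs(f$fitted - fitted(g))), 1e-6)
})

test_that("cyclic smooth predictions match at the period endpoints", {
  set.seed(31)
  n <- 500
  h <- runif(n, 0, 24)
  d <- data.frame(y = rbinom(n, 1, plogis(sin(2 * pi * h / 24))), h = h)
  f <- fit_gam(d, "y", "binomial",
               smooths = list(sm("h", bs = "cyclic", k = 10, period = 24)))
  p <- predict(f, data.frame(h = c(0, 24)), type = "link")
  expect_lt(abs(p[1] - p[2]), 1e-10)
  pe <- partial_effect(f, "h", n = 49)
  expect_lt(abs(pe$fit[1] - pe$fit[49]), 1e-10)
})

test_that("binomial fits recover a known logistic slope within 2 SE", {
  set.seed(17)
  n <- 500; x <- runif(n)
  d <- data.frame(y = rbinom(n, 1, plogis(-0.5 + 1.5 * x)), x = x)
  f <- fit_gam(d, "y", "binomial", linear = "x")
  se <- sqrt(f$vcov[2, 2])
  expect_lt(abs(f$coefficients[["x"]] - 1.5), 2 * se)
})

test_that("gamma fits recover the intercept under a supplied offset", {
  set.seed(23)
  n <- 400
  off <- runif(n, 0, 2)
  y <- rgamma(n, shape = 5, rate = 5 / exp(1 + off))
  d <- data.frame(y = y)
  f <- fit_gam(d, "y", "gamma", offset = off)
  se <- sqrt(f$vcov[1, 1])
  expect_lt(abs(f$coefficients[[1]] - 1), 2 * se + 0.05)
  # rate predictions divide the offset back out
  r <- predict(f, data.frame(row = 1:3), type = "rate",
               offset = c(0, log(2), log(4)))
  expect_equal(r[1], r[2], tolerance = 1e-8)
  expect_equal(r[1], r[3], tolerance = 1e-8)
})

test_that("beta fits shrink to a flat profile on null uniform data", {
  set.seed(29)
  h <- rep(0:23, 12)
  n <- length(h)
  y <- (1 / 24 * (n - 1) + 0.5) / n + rnorm(n, 0, 0.003)
  d <- data.frame(y = pmin(pmax(y, 1e-4), 1 - 1e-4), h = h)
  f <- fit_gam(d, "y", "beta",
               smooths = list(sm("h", bs = "cyclic", k = 8, period = 24)))
  squeezed_flat <- (1 / 24 * (n - 1) + 0.5) / n
  expect_lt(abs(mean(f$fitted) - squeezed_flat), 0.003)
  expect_lt(f$edf_total, 1.5)  # smooth shrinks away, intercept remains
  expect_true(f$deviance_explained >= 0 && f$deviance_explained <= 1)
})

test_that("responses outside the family support are rejected", {
  d <- data.frame(y = c(0.2, 0.5, 1.2), x = 1:3)
  expect_error(fit_gam(d, "y", "beta", linear = "x"), "support")
  d2 <- data.frame(y = c(1, 0, -1), x = 1:3)
  expect_error(fit_gam(d2, "y", "gamma", linear = "x"), "support")
})

test_that("AICc follows the closed formula and rejects degenerate input", {
  expect_equal(aicc_value(-10, 2, 20), 24 + 12 / 17)
  expect_error(aicc_value(-10, 0, 20), "positive")
  expect_error(aicc_value(-10, 10, 11), "n - k - 1")
})

test_that("AICc prefers the simpler nested model on null data", {
  # fixed-complexity nested comparison: the extra smooth fits only noise
  wins <- 0
  for (s in 1:40) {
    set.seed(600 + s)
    n <- 200
    x <- runif(n, 0, 24)
    d <- data.frame(y = rbinom(n, 1, 0.5), x = x)
    f0 <- fit_gam(d, "y", "binomial")
    f1 <- fit_gam(d, "y", "binomial", smooths = list(sm("x", k = 8)),
                  fixed_lambda = c(x = 1e-4))
    wins <- wins + (f0$aicc <= f1$aicc)
  }
  expect_gte(wins / 40, 0.9)
})

test_that("deviance explained is monotone over nested smooth sets", {
  set.seed(37)
  n <- 300
  d <- data.frame(
    y = rbinom(n, 1, 0.5), x1 = runif(n), x2 = runif(n)
  )
  lam <- c(x1 = 1, x2 = 1)
  f1 <- fit_gam(d, "y", "binomial", smooths = list(sm("x1", k = 6)),
                fixed_lambda = lam)
  f2 <- fit_gam(d, "y", "binomial",
                smooths = list(sm("x1", k = 6), sm("x2", k = 6)),
                fixed_lambda = lam)
  expect_gte(f2$deviance_explained, f1$deviance_explained - 1e-10)
})

test_that("select_model applies the AICc rule with the significance
           tie-break", {
  set.seed(41)
  n <- 300; x <- runif(n)
  d <- data.frame(y = rbinom(n, 1, plogis(-1 + 2.5 * x)), x = x)
  f0 <- fit_gam(d, "y", "binomial")
  f1 <- fit_gam(d, "y", "binomial", linear = "x")
  # single candidate returns itself
  expect_identical(select_model(list(f1))$best_label, "model1")
  # a clear (>1 AICc) winner is chosen
  expect_gt(f0$aicc - f1$aicc, 1)
  sel <- select_model(list(f0, f1), labels = c("null", "x"))
  expect_equal(sel$best_label, "x")
  expect_error(select_model(list()), "no candidate")
  # near-tie with a non-significant extra term -> reduced model wins
  found <- FALSE
  for (s in 1:60) {
    set.seed(700 + s)
    xx <- runif(n)
    dd <- data.frame(y = rbinom(n, 1, 0.5), x = xx)
    g0 <- fit_gam(dd, "y", "binomial")
    g1 <- fit_gam(dd, "y", "binomial", linear = "x")
    if (abs(g1$aicc - g0$aicc) < 1 && g1$terms$p_value[1] > 0.05) {
      sel <- select_model(list(g1, g0), labels = c("full", "reduced"))
      expect_equal(sel$best_label, "reduced")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("random intercepts absorb group-level variation", {
  set.seed(43)
  G <- 12; per <- 30
  g <- rep(sprintf("g%02d", 1:G), each = per)
  u <- rnorm(G, 0, 1)[rep(1:G, each = per)]
  x <- runif(G * per)
  d <- data.frame(y = rbinom(G * per, 1, plogis(0.8 * x + u)),
                  x = x, g = g)
  f <- fit_gam(d, "y", "binomial", linear = "x", group = "g")
  expect_gt(f$edf[["(group)"]], 2)       # groups get real df
  expect_lt(f$edf[["(group)"]], G)       # but are shrunk
  se <- sqrt(f$vcov[2, 2])
  expect_lt(abs(f$coefficients[["x"]] - 0.8), 3 * se)
  # population-level predictions ignore the random intercept
  p1 <- predict(f, data.frame(x = 0.5, g = "g01"), type = "link")
  p2 <- predict(f, data.frame(x = 0.5, g = "g07"), type = "link")
  expect_equal(p1, p2)
  p3 <- predict(f, data.frame(x = 0.5, g = "g01"), type = "link",
                exclude_group = FALSE)
  p4 <- predict(f, data.frame(x = 0.5, g = "g07"), type = "link",
                exclude_group = FALSE)
  expect_false(isTRUE(all.equal(p3, p4)))
})

test_that("smooth fits track the independent mgcv oracle", {
  skip_if_not_installed("mgcv")
  set.seed(47)
  n <- 600
  x <- runif(n, 0, 24)
  p <- plogis(-0.4 + 1.1 * sin(2 * pi * x / 24))
  d <- data.frame(y = rbinom(n, 1, p), x = x)
  f <- fit_gam(d, "y", "binomial",
               smooths = list(sm("x", bs = "cyclic", k = 10, period = 24)))
  m <- mgcv::gam(y ~ s(x, bs = "cc", k = 10), family = binomial,
                 data = d, knots = list(x = c(0, 24)))
  grid <- data.frame(x = seq(0, 24, length.out = 101))
  pf <- predict(f, grid, type = "response")
  pm <- as.numeric(predict(m, grid, type = "response"))
  expect_lt(sqrt(mean((pf - pm)^2)), 0.05)
})

test_that("the two-stage hurdle separates presence from abundance", {
  set.seed(53)
  n <- 200
  d <- data.frame(
    present = rbinom(n, 1, 0.6),
    n_receivers_deployed = 15,
    n_tagged_to_date = 8,
    x = runif(n)
  )
  d$n_sharks_present <- d$present * rpois(n, 3)
  d$present <- as.integer(d$n_sharks_present > 0)
  h <- fit_hurdle(d, linear = "x")
  expect_s3_class(h$stage1, "et_gam")
  expect_s3_class(h$stage2, "et_gam")
  expect_true(h$stage2_stable)
  expect_equal(h$stage2$n, sum(d$n_sharks_present > 0))
  # all-zero abundance: stage 2 absent, stage 1 valid
  d0 <- d
  d0$n_sharks_present <- 0L
  d0$present <- 0L
  d0$present[1:40] <- 1L  # presence indicator can still be modelled
  h0 <- fit_hurdle(d0, linear = "x")
  expect_null(h0$stage2)
  expect_s3_class(h0$stage1, "et_gam")
  # few positive days flags the abundance stage unstable
  d1 <- d
  d1$n_sharks_present[11:n] <- 0L
  d1$present <- as.integer(d1$n_sharks_present > 0)
  expect_warning(h1 <- fit_hurdle(d1, linear = "x"), "unstable")
  expect_false(h1$stage2_stable)
})
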