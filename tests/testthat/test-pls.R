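test_that("full-rank PLS equals the closed-form least-squares oracle", {
  for (seed in 1:20) {
    prob <- dense_problem(seed)
    fit <- fit_pls(prob$X, prob$y, n_components = ncol(prob$X))
    ols <- lm.fit(cbind(1, prob$X), prob$y)
    expect_lt(max(abs(fit$fitted - ols$fitted.values)), 1e-8)
    expect_equal(unname(fit$coefficients), unname(ols$coefficients[-1]),
                 tolerance = 1e-6)
  }
})

test_that("single-column line is fitted exactly with one component", {
  X <- matrix(1:6, ncol = 1)
  y <- 2 * X[, 1] + 1
  fit <- fit_pls(X, y, 1L)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$coefficients), 2)
  expect_lt(fit$see, 1e-10)
})

test_that("degenerate responses and rank deficiency are handled by convention", {
  X <- matrix(rnorm(20), 10, 2)
  fit <- fit_pls(X, rep(3, 10), 2L)
  expect_equal(fit$r2, 0)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$fitted, rep(3, 10))

  # duplicated column: rank 1, requesting 2 components truncates with warning
  X1 <- cbind(1:10, 1:10)
  expect_warning(fit2 <- fit_pls(X1, rnorm(10), 2L), "rank limited")
  expect_equal(fit2$n_components, 1L)
  expect_error(fit_pls(matrix(1:4, 2), 1:2, 5L), class = "duotox_config_error")
})

test_that("LOO q2: perfect line gives 1; permuted response gives <= 0 on average", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  cv <- loo_q2(X, c(1, 2, 3), 1L)
  expect_equal(cv$q2, 1)
  expect_equal(cv$csdep, 0)

  prob <- dense_problem(101, n = 20, p = 4, noise = 0.05)
  set.seed(202)
  q2s <- replicate(50, loo_q2(prob$X, sample(prob$y), 2L)$q2)
  expect_lt(mean(q2s), 0.05)
})

test_that("q2 <= R2 across datasets and the component scan picks sensibly", {
  for (seed in c(3, 14, 27)) {
    prob <- dense_problem(seed, n = 18, p = 6, noise = 0.3)
    for (k in c(1L, 3L, 6L)) {
      fit <- fit_pls(prob$X, prob$y, k)
      expect_lte(loo_q2(prob$X, prob$y, k)$q2, fit$r2 + 1e-12)
    }
  }
  w <- small_world()
  sc <- scan_components(w$desc$X, w$pa$z, max_components = 10L)
  expect_equal(sc$n_components, sc$scan$n_components[which.max(sc$scan$q2)])
  sc2 <- scan_components(w$desc$X, w$pa$z, max_components = 10L,
                         criterion = "sep_min")
  expect_equal(sc2$n_components, sc2$scan$n_components[which.min(sc2$scan$csdep)])
})

test_that("external validation follows its defining arithmetic", {
  # toy 4-row case checked against hand summation
  model <- structure(list(coefficients = c(1), intercept = 0, y_mean = 2),
                     class = "pls_model")
  X_test <- matrix(c(1, 2, 3, 4), ncol = 1)
  y_test <- c(1.2, 1.8, 3.3, 3.9)
  ext <- external_validation(model, X_test, y_test, training_mean = 2)
  press <- (1.2 - 1)^2 + (1.8 - 2)^2 + (3.3 - 3)^2 + (3.9 - 4)^2
  sd_ <- (1.2 - 2)^2 + (1.8 - 2)^2 + (3.3 - 2)^2 + (3.9 - 2)^2
  expect_equal(ext$r2_pred, (sd_ - press) / sd_)
  expect_equal(ext$sep, sqrt(press / 4))

  # perfect predictions
  ext2 <- external_validation(model, X_test, c(1, 2, 3, 4), training_mean = 2)
  expect_equal(ext2$r2_pred, 1)
  expect_equal(ext2$sep, 0)
  # predicting the training mean for every row -> r2_pred = 0
  model0 <- structure(list(coefficients = c(0), intercept = 2, y_mean = 2),
                      class = "pls_model")
  expect_equal(external_validation(model0, X_test, y_test,
                                   training_mean = 2)$r2_pred, 0,
               tolerance = 1e-12)
  # undefined SD flagged
  expect_warning(
    ext3 <- external_validation(model0, X_test, c(2, 2, 2, 2), training_mean = 2),
    "undefined")
  expect_false(ext3$defined)
})

test_that("field contributions: normalization, concentration, renormalization", {
  w <- small_world()
  sc <- scan_components(w$desc$X, w$pa$z, 6L)
  fit <- fit_pls(w$desc$X, w$pa$z, sc$n_components)
  contrib <- field_contributions(fit, w$desc)
  expect_equal(sum(contrib), 100, tolerance = 0.01)
  expect_named(contrib, c("S", "E", "H", "D", "A"))

  # all coefficient mass in one field -> 100 / 0 split
  fields <- c("S", "S", "E", "E")
  X <- matrix(rnorm(40), 10, 4)
  m1 <- structure(list(coefficients = c(1, 2, 0, 0)), class = "pls_model")
  c1 <- field_contributions(m1, fields, X)
  expect_equal(unname(c1["S"]), 100)
  expect_equal(unname(c1["E"]), 0)

  # equal |coef|*sd mass -> 50/50
  Xe <- cbind(scale(rnorm(10)), scale(rnorm(10)))
  m2 <- structure(list(coefficients = c(1, -1)), class = "pls_model")
  c2 <- field_contributions(m2, c("S", "E"), Xe)
  expect_equal(unname(c2["S"]), 50, tolerance = 1e-9)

  # removing a field's columns sends it to 0 and renormalizes the rest
  keepE <- fields == "E"
  m3 <- structure(list(coefficients = c(1, 2, 0.5, 0.25)), class = "pls_model")
  full <- field_contributions(m3, fields, X)
  mE <- structure(list(coefficients = m3$coefficients[keepE]), class = "pls_model")
  partE <- field_contributions(mE, fields[keepE], X[, keepE, drop = FALSE])
  expect_equal(unname(partE["E"]), 100)
})

test_that("contribution recovery: planted 3:1 field signal is found", {
  # plant S and E signal at 3:1 within ONE endpoint (planting across the two
  # endpoints would be renormalized away by the composite's standards) and
  # give that endpoint all the weight
  w <- small_world(seed = 17L)
  sp <- w$spec
  sp$weight_algae <- 1; sp$weight_geno <- 0
  lay <- synthetic_layout(sp)
  s1 <- lay$sites[1, ]; s2 <- lay$sites[2, ]
  sp$planted_coefficients <- list(
    algae = data.frame(field = c("S", "E"), x = c(s1[1], s2[1]),
                       y = c(s1[2], s2[2]), z = c(s1[3], s2[3]),
                       coef = c(3, 1)),
    geno = data.frame(field = "H", x = s1[1], y = s1[2], z = s1[3], coef = 1))
  pa <- plant_activities(w$mols, sp)
  desc <- assemble_descriptors(w$mols, grid = pa$grid)
  sc <- scan_components(desc$X, pa$z, 8L)
  fit <- fit_pls(desc$X, pa$z, sc$n_components)
  contrib <- field_contributions(fit, desc)
  expect_gt(contrib[["S"]] + contrib[["E"]], 60)
  expect_gt(contrib[["S"]], contrib[["E"]])
})
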