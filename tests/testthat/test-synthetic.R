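test_that("the generator is seed-deterministic end to end", {
  spec <- synthetic_spec(nrow = 40, ncol = 40, seed = 7)
  d1 <- make_drivers(spec)
  d2 <- make_drivers(spec)
  expect_identical(d1, d2)
  e1 <- evolve_landscape(spec, steps = 2)
  e2 <- evolve_landscape(spec, steps = 2)
  expect_identical(lapply(e1$maps, `[[`, "codes"),
                   lapply(e2$maps, `[[`, "codes"))
  expect_identical(e1$truth, e2$truth)
})

test_that("driver fields are standardized and their autocorrelation tracks the correlation length", {
  spec <- synthetic_spec(nrow = 80, ncol = 80, seed = 3)
  d <- make_drivers(spec)
  for (nm in names(d)) {
    expect_lt(abs(mean(d[[nm]])), 1e-8)
    expect_equal(sd(d[[nm]]), 1, tolerance = 1e-8)
  }
  # zero correlation length: neighboring cells are near-independent
  spec0 <- synthetic_spec(nrow = 80, ncol = 80, correlation_length = 0,
                          seed = 3)
  f0 <- make_drivers(spec0)$terrain
  r0 <- cor(as.vector(f0[-1, ]), as.vector(f0[-80, ]))
  expect_lt(abs(r0), 0.05)
  # smoothed field: strong neighbor correlation
  f8 <- d$terrain
  r8 <- cor(as.vector(f8[-1, ]), as.vector(f8[-80, ]))
  expect_gt(r8, 0.8)
})

test_that("evolution honors demand exactly and is inert with zero demand", {
  quiet <- synthetic_spec(nrow = 30, ncol = 30, seed = 5,
                          transitions = lapply(default_transitions(),
                                               function(tr) { tr$demand <- 0; tr }))
  e <- evolve_landscape(quiet, steps = 3)
  for (s in 2:4)
    expect_identical(e$maps[[s]]$codes, e$maps[[1]]$codes)

  spec <- synthetic_spec(nrow = 60, ncol = 60, seed = 5,
                         transitions = list(list(
                           from = 1L, to = 6L, intercept = -1,
                           coefs = c(terrain = 1, moisture = 0, access = 0,
                                     dist_city = -2),
                           demand = 50L)))
  e2 <- evolve_landscape(spec, steps = 1)
  gained <- sum(e2$maps[[2]]$codes == 6) - sum(e2$maps[[1]]$codes == 6)
  expect_equal(gained, 50)
})

test_that("empirical transition frequency increases with the true probability", {
  spec <- synthetic_spec(nrow = 100, ncol = 100, seed = 11,
                         transitions = list(list(
                           from = 1L, to = 6L, intercept = -1,
                           coefs = c(terrain = 1.5, moisture = 0, access = 1,
                                     dist_city = -2),
                           demand = 600L)))
  e <- evolve_landscape(spec, steps = 1)
  tr <- e$truth[[1]][[1]]
  idx <- which(!is.na(tr$p))
  converted <- e$maps[[2]]$codes[idx] == 6L
  bins <- cut(tr$p[idx], quantile(tr$p[idx], c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  freq <- tapply(converted, bins, mean)
  expect_true(all(diff(freq) > 0))
})

test_that("geometric fixture series behave as constructed", {
  expect_equal(make_series(1, 2, 5), c(1, 2, 4, 8, 16))
  expect_equal(make_series(3, 1, 4), rep(3, 4))
  expect_length(make_series(2, 1.5, 9), 9)
  expect_error(make_series(-1, 2, 4), "positive")
  expect_error(make_series(1, 0, 4), "positive")
})
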