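test_that("neighborhood effect matches window enumeration", {
  # uniform class map: every interior cell sees the full window
  g <- tiny_grid(rep(2, 100), 10, 10, cell_size = 30)
  ne <- neighborhood_effect(g, 2L, cars_params())
  expect_equal(ne[5, 5], 1)
  expect_equal(ne[1, 1], 3 / 8)   # corner: 3 of 8 window positions in-grid

  codes <- matrix(1L, 9, 9); codes[5, 5] <- 6L
  g2 <- landuse_grid(codes, 30)
  ne2 <- neighborhood_effect(g2, 6L, cars_params())
  expect_equal(ne2[4:6, 4:6], matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1) / 8, 3))
  expect_equal(sum(ne2 > 0), 8)

  p0 <- cars_params(neighborhood_weights = rep(0, 7))
  expect_true(all(neighborhood_effect(g2, 6L, p0) == 0))

  # window-count oracle on a random map and radius 2
  g3 <- rand_grid(61, 12, 12)
  p2 <- cars_params(neighborhood_radius = 2)
  ne3 <- neighborhood_effect(g3, 4L, p2)
  for (cell in c(1, 40, 77, 144)) {
    rc <- arrayInd(cell, dim(g3$codes))
    rr <- max(1, rc[1] - 2):min(12, rc[1] + 2)
    cc <- max(1, rc[2] - 2):min(12, rc[2] + 2)
    cnt <- sum(g3$codes[rr, cc] == 4L) - (g3$codes[rc] == 4L)
    expect_equal(ne3[rc], cnt / 24)
  }
})

test_that("allocation is inert without net demand and under full prohibition", {
  w <- shared_world()
  g <- w$evo$maps[[2]]
  dem <- structure(class_areas(g)$cells, names = lu_classes())
  res <- allocate(g, w$probs, dem, cells = TRUE,
                  params = cars_params(seed = 1))
  expect_identical(res$map$codes, g$codes)

  dem2 <- dem; dem2[6] <- dem2[6] + 200; dem2[1] <- dem2[1] - 200
  frozen <- transition_rules(allowed = matrix(FALSE, 7, 7))
  expect_warning(
    res2 <- allocate(g, w$probs, dem2, tmatrix = frozen, cells = TRUE,
                     params = cars_params(seed = 1, max_iter = 40)),
    "did not meet demand")
  expect_identical(res2$map$codes, g$codes)
  expect_false(res2$converged)
  expect_equal(unname(res2$unmet["construction"]), 200)
})

test_that("allocation meets demand under constraints and passes a brute-force audit", {
  w <- shared_world()
  g <- w$evo$maps[[2]]
  counts <- class_areas(g)$cells
  dem <- structure(counts, names = lu_classes())
  dem[6] <- dem[6] + 350; dem[2] <- dem[2] + 150
  dem[1] <- dem[1] - 350; dem[3] <- dem[3] - 150
  tmx <- transition_rules(forbid = cbind(2L, 6L))   # forests never urbanize
  restricted <- matrix(FALSE, 100, 100); restricted[1:20, 1:20] <- TRUE
  res <- allocate(g, w$probs, dem, tmatrix = tmx, restricted = restricted,
                  cells = TRUE, params = cars_params(seed = 3))
  out <- res$map

  # conservation of the mapped cell multiset size
  expect_equal(sum(!is.na(out$codes)), sum(!is.na(g$codes)))
  # demand met within tolerance
  tol <- pmax(1, 0.001 * dem)
  expect_true(all(abs(class_areas(out)$cells - dem) <= tol))
  # constraint soundness via crosstab audit
  ct <- crosstab(g, out)
  expect_equal(ct["forests", "construction"], 0)
  # restricted cells immutable
  expect_identical(out$codes[restricted], g$codes[restricted])
  # determinism
  res_b <- allocate(g, w$probs, dem, tmatrix = tmx, restricted = restricted,
                    cells = TRUE, params = cars_params(seed = 3))
  expect_identical(res_b$map$codes, out$codes)
  # different seed explores a different allocation
  res_c <- allocate(g, w$probs, dem, tmatrix = tmx, restricted = restricted,
                    cells = TRUE, params = cars_params(seed = 4))
  expect_false(identical(res_c$map$codes, out$codes))
})

test_that("the per-class demand gap is non-increasing across sweeps", {
  w <- shared_world()
  g <- w$evo$maps[[2]]
  dem <- structure(class_areas(g)$cells, names = lu_classes())
  dem[6] <- dem[6] + 400; dem[1] <- dem[1] - 400
  res <- allocate(g, w$probs, dem, cells = TRUE,
                  params = cars_params(seed = 5))
  log <- res$log
  for (cl in lu_classes()) {
    gaps <- abs(log$gap[log$class == cl])
    expect_true(all(diff(gaps) <= 0))
  }
})
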