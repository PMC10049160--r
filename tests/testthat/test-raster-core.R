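test_that("a uniform map yields the forced class areas", {
  g <- tiny_grid(rep(2, 9), 3, 3, cell_size = 100)
  a <- class_areas(g)
  expect_equal(a$cells[a$class == "forests"], 9)
  expect_equal(sum(a$area_ha), 9)   # 100 m cell = 1 ha
})

test_that("ASCII round-trip preserves cells and geotransform; out-of-legend values go to nodata", {
  g <- rand_grid(3, 12, 9, cell_size = 30)
  g$origin <- c(500, 1200)
  path <- withr::local_tempfile(fileext = ".asc")
  write_landuse(g, path)
  g2 <- read_landuse(path)
  expect_identical(g2$codes, g$codes)
  expect_equal(g2$cell_size, g$cell_size)
  expect_equal(g2$origin, g$origin)

  m <- matrix(2L, 3, 3); m[2, 2] <- 9L
  write_asc(m, path, cell_size = 100)
  expect_warning(g3 <- read_landuse(path), "outside the legend")
  expect_true(is.na(g3$codes[2, 2]))
  expect_equal(sum(!is.na(g3$codes)), 8)
})

test_that("class areas follow count x cell area and exclude nodata", {
  codes <- rep(2L, 100); codes[1:40] <- 1L
  g <- tiny_grid(codes, 10, 10, cell_size = 30)
  a <- class_areas(g)
  expect_equal(a$area_ha[a$class == "farmland"], 40 * 0.09)

  m <- matrix(c(2L, NA, NA, 2L), 2, 2)
  g2 <- landuse_grid(m, cell_size = 100)
  a2 <- class_areas(g2)
  expect_equal(a2$cells[a2$class == "forests"], 2)
  expect_equal(sum(a2$cells), 2)

  g3 <- rand_grid(11, 100, 100, p_nodata = 0.1)
  expect_equal(class_areas(g3)$cells, bf_class_counts(g3))
})

test_that("crosstab enumerates cell pairs with conserved marginals", {
  g <- rand_grid(5, 15, 15)
  expect_equal(sum(abs(crosstab(g, g) - diag(class_areas(g)$area_ha))), 0)

  a <- tiny_grid(c(1, 2, 1, 2), 2, 2)          # column-major: (1,1;2,2) rows
  b <- tiny_grid(c(1, 2, 6, 6), 2, 2)
  ct <- crosstab(a, b)                          # 100 m cells = 1 ha
  expect_equal(ct["farmland", "farmland"], 1)
  expect_equal(ct["farmland", "construction"], 1)
  expect_equal(ct["forests", "forests"], 1)
  expect_equal(ct["forests", "construction"], 1)
  expect_equal(sum(ct), 4)

  g2 <- rand_grid(6, 15, 15)
  expect_equal(unname(rowSums(crosstab(g, g2))),
               class_areas(g)$area_ha)
  expect_equal(crosstab(g, g2), t(crosstab(g2, g)), ignore_attr = TRUE)
  expect_error(crosstab(g, rand_grid(6, 10, 10)), "dimensions")
})

test_that("buffer masks are exact Euclidean discs and monotone in radius", {
  codes <- matrix(1L, 9, 9); codes[5, 5] <- 6L
  g <- landuse_grid(codes, cell_size = 30)
  expect_equal(buffer_mask(g, 6, 0), codes == 6L)

  m <- buffer_mask(g, 6, 2 * 30)
  # brute-force disc oracle
  d <- sqrt(outer((1:9 - 5)^2, (1:9 - 5)^2, "+"))
  expect_equal(m, d <= 2)
  expect_equal(sum(m), 13)

  m_small <- buffer_mask(g, 6, 45)
  expect_true(all(m_small <= m))   # mask(r1) subset of mask(r2)

  expect_warning(m0 <- buffer_mask(g, 7, 100), "absent")
  expect_false(any(m0))
})

test_that("block aggregation conserves sums and matches forced layouts", {
  v <- matrix(runif(36), 6, 6)
  id <- block_aggregate(v, cell_size = 30, block = 30)
  expect_equal(id$values, v)

  ones <- matrix(1, 6, 6)
  agg <- block_aggregate(ones, cell_size = 30, block = 90)
  expect_equal(agg$values, matrix(9, 2, 2))

  v2 <- matrix(rnorm(35 * 22), 35, 22)
  agg2 <- block_aggregate(v2, cell_size = 30, block = 100)
  expect_equal(sum(agg2$values, na.rm = TRUE), sum(v2))
  expect_error(block_aggregate(v2, 30, 10), "at least the cell size")
})
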