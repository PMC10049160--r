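test_that("land-use intensity is the level-weighted area sum", {
  expect_equal(lui(c(construction = 10)), 40)
  expect_equal(lui(c(construction = 4, forests = 5)), 4 * 4 + 2 * 5)
  a <- c(farmland = 3, forests = 1, grassland = 2, wetland = 0,
         waters = 1, construction = 5, unused = 4)
  expect_equal(lui(a), lui(rev(a)))   # order-invariant
  expect_equal(lui(c(construction = 4, forests = 4), normalize = TRUE), 3)
  expect_error(lui(c(farmland = -1)), "non-negative")
})

test_that("annual growth is simple annualized relative change with zero-base handling", {
  expect_equal(annual_growth(100, 100, 10), 0)
  expect_equal(annual_growth(100, 110, 10), 0.01)
  expect_equal(annual_growth(200, 220, 10), annual_growth(100, 110, 10))
  expect_equal(annual_growth(0, 0, 10), 0)
  expect_true(is.na(annual_growth(0, 5, 10)))
  expect_equal(annual_growth(100, 121, 2, compound = TRUE), 0.1)
  expect_error(annual_growth(100, 110, 0), "positive")
})

test_that("the coordination index hits its landmark values and is scale-invariant", {
  g <- 0.037
  expect_equal(coordination_index(g, g), sqrt(2) / 2)
  expect_equal(coordination_index(g, -g), 0)
  expect_equal(coordination_index(g, 0), 0.5)
  expect_true(is.na(coordination_index(0, 0)))

  rates <- expand.grid(a = seq(-0.1, 0.1, length.out = 21),
                       b = seq(-0.1, 0.1, length.out = 21))
  rates <- rates[rates$a != 0 | rates$b != 0, ]
  o1 <- coordination_index(rates$a, rates$b)
  o3 <- coordination_index(3 * rates$a, 3 * rates$b)
  expect_equal(o1, o3, tolerance = 1e-12)
  expect_true(all(o1 >= 0 & o1 <= 1 + 1e-12))
  # the maximum 1 is attained only on the balanced diagonal
  at_max <- abs(o1 - 1) < 1e-9
  expect_true(all(abs(rates$a[at_max] - rates$b[at_max]) < 1e-12))
})

test_that("classification follows the published thresholds and sub-labels", {
  expect_equal(classify_coordination(sqrt(2) / 2, 0.01, 0.02), "adapted/ahead")
  expect_equal(classify_coordination(0.2, 0.02, 0.01), "uncoordinated/lagging")
  expect_equal(classify_coordination(0.5, 0.02, 0.01), "adapted/lagging")
  expect_equal(classify_coordination(0.8, 0.01, 0.02), "coordinated/ahead")
  expect_equal(classify_coordination(0.9, 0.01, 0.01), "coordinated/ahead")
  expect_equal(classify_coordination(NA, 0, 0), "no-change")
})

test_that("block coordination agrees with a directly computed block", {
  w <- shared_world()
  g0 <- w$evo$maps[[1]]; g1 <- w$evo$maps[[3]]
  d20 <- dlb_carbon_density(2020); d30 <- dlb_carbon_density(2030)
  cg <- coordination_grid(g0, g1, d20, d30, years = 10, block = 900)
  expect_true(all(cg$o >= 0 & cg$o <= 1, na.rm = TRUE))
  expect_true(all(cg$label[is.na(cg$o)] == "no-change"))

  # recompute block (1,1) by hand: 30 m cells, 900 m block = 30x30 cells
  sub <- g0$codes[1:30, 1:30]
  counts <- tabulate(sub[!is.na(sub)], nbins = 7)
  a_ha <- counts * cell_area_ha(g0)
  lui_direct <- lui(structure(a_ha, names = lu_classes()))
  row1 <- cg[cg$block_row == 1 & cg$block_col == 1, ]
  expect_equal(row1$lui_t0, lui_direct)
  dens <- structure(d20$total, names = d20$class)[lu_classes()]
  expect_equal(row1$cs_t0, sum(a_ha * dens))

  # block enumeration order does not change the class tally
  tab <- table(cg$label)
  cg_rev <- coordination_grid(g0, g1, d20, d30, years = 10, block = 900)
  expect_identical(table(cg_rev$label), tab)
})
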