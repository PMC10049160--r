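test_that("the natural-evolution scenario compiles to identity pressure", {
  g <- rand_grid(71, 15, 15)
  c_nes <- compile_scenario(scenario_nes(), g)
  expect_true(all(c_nes$multipliers == 1))
  expect_false(any(c_nes$restricted))
  expect_true(all(is.infinite(c_nes$max_loss)))
})

test_that("ecological-protection multipliers encode the published factors", {
  m <- scenario_eps()$multipliers
  expect_equal(unname(m["farmland", "construction"]), 0.2)
  expect_equal(unname(m["unused", "construction"]), 0.2)
  expect_equal(unname(m["farmland", "forests"]), 1.6)
  expect_equal(unname(m["farmland", "wetland"]), 1.6)
  expect_equal(unname(m["unused", "waters"]), 1.6)
  expect_equal(unname(m["grassland", "forests"]), 1.6)
  expect_equal(unname(m["forests", "farmland"]), 1)

  m_eds <- scenario_eds()$multipliers
  expect_equal(unname(m_eds["grassland", "construction"]), 1.5)
  expect_equal(unname(m_eds["forests", "farmland"]), 1.5)
  expect_equal(unname(m_eds["waters", "construction"]), 1)
})

test_that("scenario compilation resolves masks, buffers and errors", {
  g <- rand_grid(72, 30, 30, classes = 1:5)   # no construction yet
  barrier <- matrix(FALSE, 30, 30); barrier[1:15, ] <- TRUE
  comp <- suppressWarnings(
    compile_scenario(scenario_eps(), g,
                     masks = list(ecological_barrier = barrier)))
  # only ecological classes inside the barrier are frozen
  eco <- matrix(g$codes %in% c(2L, 3L, 4L, 5L), 30, 30)
  expect_identical(comp$restricted, barrier & eco)

  # with construction present, its 10-km periphery is exempted
  g2 <- rand_grid(73, 30, 30, cell_size = 5000)
  comp2 <- compile_scenario(scenario_eps(), g2,
                            masks = list(ecological_barrier = barrier))
  exempt <- buffer_mask(g2, 6L, 10000)
  expect_false(any(comp2$restricted & exempt))

  expect_error(suppressWarnings(compile_scenario(scenario_eps(), g)),
               "missing mask")

  c_eds <- compile_scenario(scenario_eds(), g)
  expect_equal(sum(c_eds$restricted), sum(g$codes == 5L))
})

test_that("the planned-development cap limits conversions away from each class", {
  w <- shared_world()
  g <- w$evo$maps[[2]]
  barrier <- matrix(FALSE, 100, 100); barrier[1:10, ] <- TRUE
  farm <- matrix(FALSE, 100, 100); farm[90:100, ] <- TRUE
  comp <- compile_scenario(scenario_pds(), g,
                           masks = list(ecological_barrier = barrier,
                                        basic_farmland = farm))
  counts <- class_areas(g)$cells
  expect_equal(comp$max_loss, floor(0.069 * counts))

  dem <- structure(counts, names = lu_classes())
  dem[6] <- dem[6] + 600; dem[1] <- dem[1] - 450; dem[3] <- dem[3] - 150
  res <- suppressWarnings(
    allocate(g, w$probs, dem, restricted = comp$restricted,
             multipliers = comp$multipliers, max_loss = comp$max_loss,
             cells = TRUE, params = cars_params(seed = 6)))
  ct <- crosstab(g, res$map) / cell_area_ha(g)   # cells
  moved <- rowSums(ct) - diag(ct)
  expect_true(all(moved <= comp$max_loss + 1e-9))
  # restriction soundness on the output map
  expect_identical(res$map$codes[comp$restricted], g$codes[comp$restricted])
})

test_that("ecological protection curbs construction growth relative to natural evolution", {
  w <- shared_world()
  g0 <- w$evo$maps[[1]]; g1 <- w$evo$maps[[2]]
  markov <- fit_markov(crosstab(g0, g1))
  barrier <- matrix(FALSE, 100, 100); barrier[1:40, ] <- TRUE
  gain <- function(scen, masks) {
    comp <- compile_scenario(scen, g1, masks)
    dem <- project_markov(adjust_markov(markov, scen), class_areas(g1))
    res <- suppressWarnings(
      allocate(g1, w$probs, dem, restricted = comp$restricted,
               multipliers = comp$multipliers, max_loss = comp$max_loss,
               params = cars_params(seed = 8)))
    sum(res$map$codes == 6L, na.rm = TRUE) - sum(g1$codes == 6L, na.rm = TRUE)
  }
  g_nes <- gain(scenario_nes(), list())
  g_eps <- gain(scenario_eps(), list(ecological_barrier = barrier))
  expect_lte(g_eps, g_nes)
})
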