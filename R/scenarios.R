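#' Declarative scenario configuration
#'
#' Encodes one named policy scenario as the pieces the allocation stage
#' consumes: a 7 x 7 score-multiplier matrix, restriction recipes
#' (which classes are frozen inside which mask layers), an exemption
#' buffer around existing construction, and an optional per-class
#' development-intensity cap.
#'
#' @param name Scenario name.
#' @param multipliers 7 x 7 non-negative matrix (default all ones).
#' @param restrict List of recipes `list(mask = "layer", classes = codes)`
#'   freezing those classes where the named mask layer is `TRUE`.
#' @param restrict_classes_everywhere Codes frozen wherever they occur.
#' @param urban_buffer_km Radius of a construction-land buffer exempted
#'   from restriction (0 = none).
#' @param intensity_cap Fraction in `[0, 1]`: max share of each class's
#'   cells allowed to convert away outside restrictions (`NA` = uncapped).
#' @param cap_total If `TRUE` the cap is applied to the total mapped
#'   area rather than per class.
#' @param demand Demand source: `"markov"` (adjusted by the multipliers)
#'   or `"explicit"`.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(name,
                            multipliers = matrix(1, 7, 7),
                            restrict = list(),
                            restrict_classes_everywhere = integer(0),
                            urban_buffer_km = 0,
                            intensity_cap = NA_real_,
                            cap_total = FALSE,
                            demand = c("markov", "explicit")) {
  stopifnot(all(multipliers >= 0),
            is.na(intensity_cap) || (intensity_cap >= 0 && intensity_cap <= 1))
  dimnames(multipliers) <- list(from = lu_classes(), to = lu_classes())
  structure(list(name = name, multipliers = multipliers,
                 restrict = restrict,
                 restrict_classes_everywhere = restrict_classes_everywhere,
                 urban_buffer_km = urban_buffer_km,
                 intensity_cap = intensity_cap, cap_total = cap_total,
                 demand = match.arg(demand)),
            class = "scenario_config")
}

code <- function(...) unname(lu_legend()[c(...)])

#' Natural evolution scenario: historical trend, no constraints
#' @return A [scenario_config()] with identity multipliers and no masks.
#' @export
scenario_nes <- function() scenario_config("nes")

#' Ecological protection scenario
#'
#' Transition scores of farmland and unused land to forests, wetland and
#' waters, and of grassland to forests, are raised by 60% (x1.6);
#' farmland and unused land to construction are cut by 80% (x0.2).
#' Forests, grassland, wetland and waters are frozen inside the
#' ecological-barrier mask, except within a 10-km buffer around existing
#' urban areas kept open for minimum urbanisation demand.
#'
#' @return A [scenario_config()].
#' @export
scenario_eps <- function() {
  m <- matrix(1, 7, 7)
  src <- code("farmland", "unused")
  m[src, code("forests", "wetland", "waters")] <- 1.6
  m[code("grassland"), code("forests")] <- 1.6
  m[src, code("construction")] <- 0.2
  scenario_config("eps", multipliers = m,
                  restrict = list(list(mask = "ecological_barrier",
                                       classes = code("forests", "grassland",
                                                      "wetland", "waters"))),
                  urban_buffer_km = 10)
}

#' Economic development scenario
#'
#' Transition scores of every class except waters to farmland and
#' construction are raised by 50% (x1.5); waters cells are frozen to
#' secure production and domestic water supply.
#'
#' @return A [scenario_config()].
#' @export
scenario_eds <- function() {
  m <- matrix(1, 7, 7)
  src <- setdiff(seq_len(7), code("waters"))
  m[src, code("farmland", "construction")] <- 1.5
  scenario_config("eds", multipliers = m,
                  restrict_classes_everywhere = code("waters"))
}

#' Planned development scenario
#'
#' Forests, wetland and waters are frozen inside the ecological-barrier
#' mask; farmland is frozen inside the basic-farmland (main agricultural
#' producing area) mask; outside restrictions, the development intensity
#' of each class is capped at 6.9% of its area.
#'
#' @return A [scenario_config()].
#' @export
scenario_pds <- function() {
  scenario_config("pds",
                  restrict = list(
                    list(mask = "ecological_barrier",
                         classes = code("forests", "wetland", "waters")),
                    list(mask = "basic_farmland",
                         classes = code("farmland"))),
                  intensity_cap = 0.069)
}

#' Look up a shipped scenario by name
#' @param name One of `"nes"`, `"eps"`, `"eds"`, `"pds"`.
#' @return A [scenario_config()].
#' @export
get_scenario <- function(name) {
  switch(tolower(name),
         nes = scenario_nes(), eps = scenario_eps(),
         eds = scenario_eds(), pds = scenario_pds(),
         stop("unknown scenario: ", name))
}

#' Compile a scenario into allocation inputs
#'
#' Resolves the declarative recipes against a base map and mask layers:
#' builds the restricted-cell mask (class-conditional masks, minus any
#' urban exemption buffer), passes the multipliers through, and converts
#' the intensity cap to per-class `max_loss` cell counts.
#'
#' @param config A [scenario_config()].
#' @param base The base-year [landuse_grid()].
#' @param masks Named list of logical matrices referenced by the
#'   config's recipes.
#' @return List with `multipliers`, `restricted` (logical matrix),
#'   `max_loss` (per-class cap in cells) and `name`.
#' @export
compile_scenario <- function(config, base, masks = list()) {
  nr <- nrow(base$codes); nc <- ncol(base$codes)
  restricted <- matrix(FALSE, nr, nc)
  exempt <- if (config$urban_buffer_km > 0)
    buffer_mask(base, code("construction"), config$urban_buffer_km * 1000)
  else matrix(FALSE, nr, nc)
  for (r in config$restrict) {
    if (is.null(masks[[r$mask]]))
      stop("scenario '", config$name, "' references missing mask layer '",
           r$mask, "'")
    hit <- masks[[r$mask]] & !is.na(base$codes) &
      matrix(base$codes %in% r$classes, nr, nc)
    restricted <- restricted | (hit & !exempt)
  }
  if (length(config$restrict_classes_everywhere)) {
    hit <- !is.na(base$codes) &
      matrix(base$codes %in% config$restrict_classes_everywhere, nr, nc)
    restricted <- restricted | hit
  }
  counts <- tabulate(base$codes[!is.na(base$codes)], nbins = 7)
  max_loss <- if (is.na(config$intensity_cap)) rep(Inf, 7)
  else if (config$cap_total) rep(floor(config$intensity_cap * sum(counts)), 7)
  else floor(config$intensity_cap * counts)
  list(name = config$name, multipliers = config$multipliers,
       restricted = restricted, max_loss = max_loss)
}

#' Scenario-adjusted Markov demand
#'
#' Applies the scenario's multiplier matrix to the Markov row
#' probabilities and renormalizes rows before projecting, so policy
#' pressure feeds the demand path as well as the allocation scores.
#'
#' @param model A [fit_markov()] model.
#' @param config A [scenario_config()].
#' @return An adjusted `markov_model`.
#' @export
adjust_markov <- function(model, config) {
  P <- model$P * config$multipliers
  P <- P / rowSums(P)
  structure(list(P = P, interval = model$interval), class = "markov_model")
}
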