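# Shared fixtures, built in code and memoized for the test run. The default
# bundle (300 x 300, seed 1) is the study-condition testbed; the small
# bundle keeps engine-heavy tests fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_bundle <- function() memo("bundle", function() synth_bundle(synth_spec(seed = 1)))

default_calibration <- function() memo("calibration", function() {
  b <- default_bundle()
  eca_calibrate(b$map_t0, b$map_t1, b$drivers, fraction = 1, seed = 1,
                exclude = b$masks$core_area)
})

default_targets <- function() memo("targets", function() {
  b <- default_bundle()
  scenario_targets(area_table(b$map_t1), default_calibration()$transition,
                   steps = 3)
})

default_report <- function() memo("report", function() {
  b <- default_bundle()
  run_all_scenarios(b$map_t1, b$drivers, b$masks, default_calibration(),
                    default_targets(), seed = 1)
})

small_bundle <- function() memo("small_bundle", function()
  synth_bundle(synth_spec(shape = c(80, 80), seed = 42)))

small_models <- function() memo("small_models", function() {
  b <- small_bundle()
  cal <- eca_calibrate(b$map_t0, b$map_t1, b$drivers, fraction = 1, seed = 2,
                       exclude = b$masks$core_area)
  cal
})
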