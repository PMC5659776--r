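# Shared fixtures: parametric contours and a compact phantom spec used
# by the unit tests (smaller than the defaults to keep tests quick).

make_circle <- function(r = 50, center = c(100, 80), n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

make_ellipse <- function(a = 60, b = 30, center = c(100, 80), n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

small_spec <- function(...) {
  phantom_spec(width = 160L, height = 130L, center = c(80, 62),
               semi_axes = c(34, 20), sheath_width = 10, ...)
}

# Small trained model shared by localization/pipeline tests; built once
# per test file.
small_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- generate_training_set(6, small_spec(), seed = 101)
      cache <<- list(
        train = train,
        model = train_atasm(lapply(train, `[[`, "image"),
                            lapply(train, `[[`, "tendon"),
                            lapply(train, `[[`, "sheath"))
      )
    }
    cache
  }
})
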