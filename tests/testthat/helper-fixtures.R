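# Shared fixtures. Everything is generated in code; heavier objects are
# memoised per session so multiple test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small phantom: fast to generate, still has all three regions
small_phantom_params <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(40L, 40L, 30L), spacing = c(1, 1, 2),
                   root_radius_mm = 9, bend_mm = 3,
                   target_calc_volume_mm3 = 300)
  do.call(phantom_params, utils::modifyList(defaults, args))
}

small_phantom <- function(seed = 1L, ...) {
  p <- small_phantom_params(seed = seed, ...)
  generate_phantom(p, sprintf("FX%03d", seed))
}

# desk-scale preprocessed fixture volumes
tiny_preprocess_cfg <- function() preprocess_config(shape = c(32L, 32L, 32L))

pvl_ns <- asNamespace("pvlnet")
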