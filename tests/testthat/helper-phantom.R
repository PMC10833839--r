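# Phantom fixtures are expensive (volume inversion, meshing); cache them per
# session, keyed by the spec fields that matter.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(spec = phantom_spec(seed = 11)) {
  key <- paste(deparse(unclass(spec)), collapse = "")
  key <- substr(digest_chars(key), 1, 32)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom_pair(spec)
  .phantom_cache[[key]]
}

# tiny string hash (no external deps)
digest_chars <- function(s) {
  x <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(x)) h <- (h * 31 + x[i]) %% 2147483647
  paste0("k", h)
}

# small, fast phantom for unit-scale registration tests
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(32L, 32L, 32L), spacing = c(4, 4, 4),
         deform_spacing = 32, max_displacement = 6, noise_sd = 5,
         n_surface_points = 100L, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

# the acceptance-scale phantom: 64^3, 8 mm maximum displacement
acceptance_phantom_spec <- function(...) {
  phantom_spec(seed = 11L, ...)
}

# registration configuration used for phantom studies: sizes chosen so a
# full 3-level run takes about a minute on one core
phantom_reg_config <- function(lambda1 = 16, lambda2 = 100, alpha = 1,
                               iterations = c(150L, 150L, 150L),
                               samples = 4000L, seed = 42L) {
  registration_config(lambda1 = lambda1,
                      weights = cost_weights(alpha = alpha,
                                             lambda2 = lambda2),
                      samples_per_iter = samples, iterations = iterations,
                      seed = seed)
}

.reg_cache <- new.env(parent = emptyenv())

# cache full registration runs shared between acceptance properties
cached_registration <- function(tag, fun) {
  if (is.null(.reg_cache[[tag]])) .reg_cache[[tag]] <- fun()
  .reg_cache[[tag]]
}
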