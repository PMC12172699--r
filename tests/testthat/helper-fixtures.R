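# Shared, lazily-built phantom fixtures. Everything is generated in code at
# a fixed seed; the cache avoids re-rendering across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# amyloid-negative / positive template pair from small rendered cohorts
fixture_pair <- function() fixture("pair", function() {
  neg <- make_cohort(6, 0, seed = 101)
  pos <- make_cohort(0, 6, seed = 102)
  template_pair(build_template(lapply(neg, `[[`, "volume"), "negative"),
                build_template(lapply(pos, `[[`, "volume"), "positive"))
})

# a clean amyloid-negative-ish subject used as registration target
fixture_fixed <- function() fixture("fixed", function() {
  render_pet(phantom_spec(burden = 0.2, seed = 1, noise_sd = 0.05))$volume
})

fixture_vois <- function() fixture("vois", function() make_voi_set())

expect_exit_ok <- function(status) expect_identical(status, 0L)
expect_exit_usage <- function(status) expect_identical(status, 2L)
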