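# Small fixtures shared across test files. Everything is generated in code;
# memoised so repeated use within a test run costs one generation.

local_fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = local_fixture_env)) {
    assign(key, force(expr), envir = local_fixture_env)
  }
  get(key, envir = local_fixture_env)
}

quick_profile <- function(...) subject_profile(beat_period_s = 0.8, ...)

# one-subject paired study, 3 reps per state: 12 pairs, 108 windows
tiny_study <- function() {
  memo("tiny_study",
       generate_study(quick_profile(), reps_per_state = 3, seed = 42))
}

tiny_pairs <- function() memo("tiny_pairs", pair_study(tiny_study()))

tiny_features <- function() memo("tiny_features", featurize_study(tiny_study()))
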