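#' Arm muscle-activity states
#'
#' The measurement protocol defines four held arm states: `normal` (arm
#' hanging down, code 1), `bend` (arm bent, code 2), `strength` (arm bent with
#' strain, code 3) and `dumbbell` (arm bent holding a 5 kg dumbbell, code 4).
#' For the headline 3-class recognition task, `strength` and `dumbbell` are
#' merged into a single `strain` label (code 3'), because their pulse-wave
#' signatures are nearly indistinguishable.
#'
#' @return A tibble with columns `code` (integer 1--4), `state` (factor) and
#'   `merged` (factor with levels `normal`, `bend`, `strain`).
#' @export
#' @examples
#' activity_states()
activity_states <- function() {
  tibble::tibble(
    code = 1:4,
    state = factor(state_levels(), levels = state_levels()),
    merged = merge_states(state_levels())
  )
}

state_levels <- function() c("normal", "bend", "strength", "dumbbell")

merged_levels <- function() c("normal", "bend", "strain")

#' Coerce to a canonical activity-state factor
#'
#' Accepts state names (`"normal"`, ...), integer codes 1--4, or an existing
#' factor, and returns a factor with the canonical four levels. Unknown values
#' are an error, never silently dropped.
#'
#' @param x Character, integer or factor vector of states.
#' @return Factor with levels `normal < bend < strength < dumbbell`.
#' @export
#' @examples
#' as_activity_state(c(1, 4, 2))
#' as_activity_state(c("bend", "normal"))
as_activity_state <- function(x) {
  lv <- state_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% 1:4)) {
      stop("activity-state codes must be integers in 1..4", call. = FALSE)
    }
    return(factor(lv[x], levels = lv))
  }
  x <- tolower(as.character(x))
  if (!all(x %in% lv)) {
    bad <- setdiff(unique(x), lv)
    stop("unknown activity state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = lv)
}

#' Merge the four states into the 3-class label set
#'
#' `strength` and `dumbbell` both map to `strain`; `normal` and `bend` map to
#' themselves. The merge is surjective onto the three merged levels.
#'
#' @param state Vector coercible by [as_activity_state()].
#' @return Factor with levels `normal`, `bend`, `strain`.
#' @export
#' @examples
#' merge_states(c("normal", "strength", "dumbbell"))
merge_states <- function(state) {
  s <- as_activity_state(state)
  out <- c(normal = "normal", bend = "bend",
           strength = "strain", dumbbell = "strain")[as.character(s)]
  factor(unname(out), levels = merged_levels())
}
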