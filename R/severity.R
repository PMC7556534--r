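#' PTSD severity states
#'
#' The Markov state space comprises five living severity categories plus an
#' absorbing dead state. Living states are ordered from least to most severe.
#'
#' @param include_dead logical; append the absorbing `"dead"` state.
#' @return Character vector of state names.
#' @export
#' @examples
#' severity_states()
severity_states <- function(include_dead = FALSE) {
  s <- c("asymptomatic", "mild", "moderate", "severe", "extreme")
  if (include_dead) c(s, "dead") else s
}

#' CAPS-IV severity bands
#'
#' Standard banding of total CAPS-IV scores into the five severity categories:
#' 0-19 asymptomatic/few symptoms, 20-39 mild (subthreshold), 40-59 moderate
#' (threshold), 60-79 severe, and 80+ extreme symptomatology. Bands are
#' contiguous integer intervals covering `[0, Inf)`.
#'
#' @return A data.frame with columns `lower`, `upper` (inclusive integer CAPS
#'   bounds; `upper = Inf` for the open-ended extreme band) and `state`.
#' @export
#' @examples
#' severity_bands()
severity_bands <- function() {
  structure(
    data.frame(
      lower = c(0, 20, 40, 60, 80),
      upper = c(19, 39, 59, 79, Inf),
      state = severity_states(),
      stringsAsFactors = FALSE
    ),
    class = c("severity_bands", "data.frame")
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), nrow(bands) == 5L,
            all(c("lower", "upper", "state") %in% names(bands)))
  if (bands$lower[1] != 0 || !is.infinite(bands$upper[nrow(bands)]))
    stop("severity bands must cover [0, Inf)")
  if (any(bands$lower[-1] != bands$upper[-nrow(bands)] + 1))
    stop("severity bands must be contiguous integer intervals")
  invisible(bands)
}

#' Classify a CAPS-IV score into a severity state
#'
#' Scores are integer-valued on the CAPS-IV; non-integer inputs are floored
#' before banding so that the bands are exhaustive.
#'
#' @param score Numeric vector of CAPS-IV total scores (>= 0).
#' @param bands Severity bands, as from [severity_bands()].
#' @return Character vector of state names, one per score.
#' @export
#' @examples
#' classify_caps(c(0, 39, 40, 59, 60, 85))
classify_caps <- function(score, bands = severity_bands()) {
  if (any(!is.finite(score)) || any(score < 0))
    stop("CAPS scores must be finite and non-negative")
  validate_bands(bands)
  s <- floor(score)
  idx <- findInterval(s, bands$lower)
  bands$state[idx]
}
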