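#' Metadata for the eight cognitive tests of the battery
#'
#' Each test is described by its scoring direction, the transform applied
#' before modelling, the admissible raw-score range and the administration
#' time limit. The two trail-making tests are timed in seconds, so lower
#' raw scores mean better performance; they are log-transformed before
#' modelling and their z-scores are sign-flipped so that higher z always
#' means better performance. All other tests count correct responses
#' within a time limit and are modelled on the identity scale.
#'
#' @param test_id One of \code{"SDMT"}, \code{"CFT"}, \code{"SCNT"},
#'   \code{"SWRT"}, \code{"SIT"}, \code{"TMTA"}, \code{"TMTB"},
#'   \code{"LFT"}.
#' @return A list of class \code{"test_spec"} with elements
#'   \code{test_id}, \code{label}, \code{direction}
#'   (\code{"higher_better"} or \code{"lower_better"}), \code{transform}
#'   (\code{"identity"} or \code{"log"}), \code{range} (length-2 numeric)
#'   and \code{time_limit} (seconds).
#' @examples
#' test_spec("TMTA")$direction  # "lower_better"
#' @export
test_spec <- function(test_id) {
  test_id <- match.arg(toupper(test_id), battery_tests())
  spec <- .battery_specs[[test_id]]
  structure(spec, class = "test_spec")
}

#' @rdname test_spec
#' @export
battery_tests <- function() names(.battery_specs)

# Admissible ranges follow the observed score ranges of the normative
# sample; TMT administrations are capped at 240 s.
.battery_specs <- list(
  SDMT = list(test_id = "SDMT", label = "Symbol Digit Modalities Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 110), time_limit = 90),
  CFT  = list(test_id = "CFT", label = "Category Fluency Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 60), time_limit = 60),
  SCNT = list(test_id = "SCNT", label = "Stroop Color Naming Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 150), time_limit = 45),
  SWRT = list(test_id = "SWRT", label = "Stroop Word Reading Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 180), time_limit = 45),
  SIT  = list(test_id = "SIT", label = "Stroop Interference Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 125), time_limit = 45),
  TMTA = list(test_id = "TMTA", label = "Trail Making Test A",
              direction = "lower_better", transform = "log",
              range = c(5, 240), time_limit = 240),
  TMTB = list(test_id = "TMTB", label = "Trail Making Test B",
              direction = "lower_better", transform = "log",
              range = c(10, 240), time_limit = 240),
  LFT  = list(test_id = "LFT", label = "Letter Fluency Test",
              direction = "higher_better", transform = "identity",
              range = c(0, 100), time_limit = 180)
)

#' Language codes of the normative sample
#'
#' Ten administration languages, ordered as in the normative cohort
#' description. English is the reference category throughout.
#' @return Character vector of language codes.
#' @export
norm_languages <- function() {
  c("EN", "DE", "ES", "IT", "PL", "FRCA", "FR", "NL", "ESLA", "DA")
}

#' Apply a test's modelling transform to raw scores
#'
#' @param spec A \code{test_spec}.
#' @param raw Numeric raw scores.
#' @return Scores on the model scale (natural log for timed trail-making
#'   tests, identity otherwise).
#' @export
transform_raw <- function(spec, raw) {
  if (spec$transform == "log") {
    if (any(raw <= 0, na.rm = TRUE))
      stop("non-positive raw score for log-transformed test ", spec$test_id)
    log(raw)
  } else {
    raw
  }
}

#' @rdname transform_raw
#' @param y Scores on the model scale.
#' @export
back_transform <- function(spec, y) {
  if (spec$transform == "log") exp(y) else y
}
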