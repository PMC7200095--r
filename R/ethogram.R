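#' Define an ethogram
#'
#' An ethogram is the closed catalogue of mutually exclusive behaviour
#' classes that observations and classifier outputs are allowed to use.
#' A separate rejection class (by default `"other"`) absorbs windows whose
#' maximum class probability does not exceed the acceptance threshold and
#' bursts without an absolute vote majority; it is never a trainable class.
#'
#' @param classes Character vector of behaviour class names. The default is
#'   the six-class red-fox ethogram: feeding, grooming, resting, caching,
#'   trotting, walking.
#' @param reject_class Name of the rejection category. Must not collide with
#'   `classes`.
#' @param descriptions Optional named character vector of free-text class
#'   descriptions (names must match `classes`).
#'
#' @return An object of class `"ethogram"`: a list with elements `classes`,
#'   `reject_class` and `descriptions`.
#' @examples
#' eth <- ethogram()
#' eth$classes
#' @export
ethogram <- function(classes = c("feeding", "grooming", "resting",
                                 "caching", "trotting", "walking"),
                     reject_class = "other",
                     descriptions = NULL) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("ethogram classes must be unique")
  if (reject_class %in% classes)
    stop("reject_class must not be one of the behaviour classes")
  if (!is.null(descriptions)) {
    if (is.null(names(descriptions)) || !all(names(descriptions) %in% classes))
      stop("descriptions must be named by ethogram classes")
  }
  structure(list(classes = classes,
                 reject_class = reject_class,
                 descriptions = descriptions),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat("Ethogram with", length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("Rejection class:", x$reject_class, "\n")
  invisible(x)
}

is_ethogram <- function(x) inherits(x, "ethogram")
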