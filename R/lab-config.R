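#' Laboratory panel configuration
#'
#' The twelve laboratory measurements used throughout the package, with their
#' plausibility limits and clinical normal ranges, and a tag separating the
#' five regularly collected labs (white blood cell count, platelets, sodium,
#' potassium, blood urea nitrogen) from the seven informatively collected ones
#' (arterial/venous pH, PaO2, arterial/venous PaCO2, lactate, troponin).
#' The default panel is read from a JSON file shipped with the package
#' (\code{system.file("extdata", "lab_config.json", package = "informiss")}),
#' so users can supply their own panel in the same format.
#'
#' @param path Path to a JSON lab configuration. Defaults to the shipped panel.
#' @return A data frame of class \code{lab_config} with one row per lab and
#'   columns \code{name}, \code{label}, \code{regular} (logical),
#'   \code{lower_limit}, \code{lower_normal}, \code{upper_normal},
#'   \code{upper_limit}, \code{severity_direction} (+1 if the lab rises with
#'   illness severity in the simulator, -1 if it falls), and \code{normal_value}
#'   (the midpoint of the normal range, used by normal-value imputation).
#' @examples
#' labs <- lab_config()
#' labs[labs$name == "bun", "normal_value"]  # 13.5
#' @export
lab_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lab_config.json", package = "informiss")
  }
  raw <- jsonlite::fromJSON(path)$labs
  labs <- as.data.frame(raw, stringsAsFactors = FALSE)
  validate_lab_config(labs)
  labs$normal_value <- (labs$lower_normal + labs$upper_normal) / 2
  class(labs) <- c("lab_config", "data.frame")
  labs
}

validate_lab_config <- function(labs) {
  required <- c("name", "regular", "lower_limit", "lower_normal",
                "upper_normal", "upper_limit")
  missing_cols <- setdiff(required, names(labs))
  if (length(missing_cols) > 0) {
    stop("lab config missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ok <- labs$lower_limit <= labs$lower_normal &
    labs$lower_normal < labs$upper_normal &
    labs$upper_normal <= labs$upper_limit
  if (!all(ok)) {
    stop("lab config violates lower_limit <= lower_normal < upper_normal <= upper_limit for: ",
         paste(labs$name[!ok], collapse = ", "))
  }
  if (anyDuplicated(labs$name)) stop("duplicate lab names in config")
  invisible(labs)
}

#' @rdname lab_config
#' @param labs A \code{lab_config} data frame.
#' @return \code{lab_names}: character vector of lab column names, regular labs
#'   first.
#' @export
lab_names <- function(labs = lab_config()) {
  c(labs$name[labs$regular], labs$name[!labs$regular])
}
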