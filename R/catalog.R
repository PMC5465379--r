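#' Feature catalogue for the 270-feature activity-recognition set
#'
#' Enumerates, in a fixed order, every feature computed from a 10-second
#' multi-sensor clip: 131 per inertial sensor (accelerometer, gyroscope) and 8
#' from the barometer, 270 in total. Per inertial axis (x, y, z) there are 38
#' definitions: mean, range, interquartile range; SD, skew, kurtosis; 4
#' z-score histogram fractions on [-2, 2]; 4 moments of the first derivative;
#' 4 moments of the one-sided power spectrum; and 20 mean band powers in
#' 0.5 Hz bins spanning 0-10 Hz. Cross-axis features add 3 Pearson
#' correlations, raw and normalized mean cross products for the three axis
#' pairs, their absolute variants, the mean squared norm and the sum of axial
#' SDs. Barometer features are the 4 derivative moments, SD, range, IQR and
#' the least-squares pressure slope.
#'
#' @return A data.frame with one row per feature: \code{name}, \code{sensor}
#'   (\code{"acc"}, \code{"gyro"}, \code{"baro"}), \code{channel} (axis, axis
#'   pair or \code{"all"}) and \code{definition} (definition id, shared across
#'   sensors/axes).
#' @examples
#' cat270 <- feature_catalog()
#' table(cat270$sensor)   # acc 131, gyro 131, baro 8
#' @export
feature_catalog <- function() {
  if (!is.null(.catalog_cache$df)) return(.catalog_cache$df)
  axis_defs <- c(
    "mean", "range", "iqr",
    "sd", "skew", "kurt",
    paste0("zhist", 1:4),
    "deriv_mean", "deriv_sd", "deriv_skew", "deriv_kurt",
    "spec_mean", "spec_sd", "spec_skew", "spec_kurt",
    sprintf("bp%02d", 1:20)
  )
  pairs <- c("xy", "xz", "yz")
  rows <- list()
  for (sensor in c("acc", "gyro")) {
    for (ax in c("x", "y", "z")) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(sensor, ax, axis_defs, sep = "_"),
        sensor = sensor, channel = ax, definition = axis_defs,
        stringsAsFactors = FALSE
      )
    }
    cross <- data.frame(
      name = c(
        paste(sensor, "corr", pairs, sep = "_"),
        paste(sensor, "xprod", rep(pairs, each = 2), c("raw", "norm"), sep = "_"),
        paste(sensor, "absxprod", rep(pairs, each = 2), c("raw", "norm"), sep = "_"),
        paste(sensor, c("msn", "sumsd"), sep = "_")
      ),
      sensor = sensor,
      channel = c(pairs, rep(pairs, each = 2), rep(pairs, each = 2), "all", "all"),
      definition = c(
        rep("corr", 3),
        paste0("xprod_", rep(c("raw", "norm"), 3)),
        paste0("absxprod_", rep(c("raw", "norm"), 3)),
        "msn", "sumsd"
      ),
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- cross
  }
  baro_defs <- c("deriv_mean", "deriv_sd", "deriv_skew", "deriv_kurt",
                 "sd", "range", "iqr", "slope")
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste("baro", baro_defs, sep = "_"),
    sensor = "baro", channel = "p", definition = baro_defs,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .catalog_cache$df <- out
  out
}

.catalog_cache <- new.env(parent = emptyenv())

#' Names of the eight barometer features
#' @return Character vector of length 8.
#' @export
barometer_feature_names <- function() {
  cat270 <- feature_catalog()
  cat270$name[cat270$sensor == "baro"]
}
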