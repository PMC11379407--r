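#' Region-of-interest statistics of a property map channel
#'
#' Computes the mean and the lower/upper quartiles (linear interpolation
#' between order statistics) of a property-map channel over a rectangular
#' region of interest, together with the fraction of undetermined pixels.
#' Regions with more than 2% undetermined pixels are flagged `omitted`, the
#' rule used to exclude unreliable acquisitions from averaged error tables.
#'
#' @param map a `property_map` (or a bare matrix, in which case `mask` may
#'   supply the undetermined pixels).
#' @param channel `"mua"` or `"mus_prime"` when `map` is a `property_map`.
#' @param roi `c(row1, row2, col1, col2)` in pixels; defaults to a centred
#'   square covering at most 300 pixels per side.
#' @param mask optional logical matrix of undetermined pixels for bare
#'   matrices.
#' @param omit_threshold undetermined fraction beyond which the ROI is
#'   omitted.
#' @return An object of class `roi_result`: `mean`, `q25`, `q75`,
#'   `undetermined_fraction`, `omitted`, `n_pixels`.
#' @export
roi_stats <- function(map, channel = c("mus_prime", "mua"), roi = NULL,
                      mask = NULL, omit_threshold = 0.02) {
  channel <- match.arg(channel)
  if (inherits(map, "property_map")) {
    values <- if (channel == "mua") map$mua_map else map$mus_prime_map
    mask <- map$undetermined_mask
  } else {
    values <- map
    if (is.null(mask)) mask <- !is.finite(values)
  }
  if (is.null(roi)) {
    side <- min(300, nrow(values), ncol(values))
    r0 <- floor((nrow(values) - side) / 2)
    c0 <- floor((ncol(values) - side) / 2)
    roi <- c(r0 + 1, r0 + side, c0 + 1, c0 + side)
  }
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(values) ||
      roi[4] > ncol(values) || roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("ROI must be a non-empty rectangle inside the image")
  }
  v <- values[roi[1]:roi[2], roi[3]:roi[4]]
  m <- mask[roi[1]:roi[2], roi[3]:roi[4]]
  frac <- mean(m)
  good <- v[!m]
  if (length(good) == 0) {
    return(structure(list(mean = NA_real_, q25 = NA_real_, q75 = NA_real_,
                          undetermined_fraction = frac, omitted = TRUE,
                          n_pixels = length(v)),
                     class = "roi_result"))
  }
  q <- quantile(good, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(mean = mean(good), q25 = q[1], q75 = q[2],
                 undetermined_fraction = frac,
                 omitted = frac > omit_threshold, n_pixels = length(v)),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("ROI: mean %.4g [q25 %.4g, q75 %.4g], %.2f%% undetermined%s\n",
              x$mean, x$q25, x$q75, 100 * x$undetermined_fraction,
              if (x$omitted) " (omitted)" else ""))
  invisible(x)
}

#' Mean absolute percent error
#'
#' `mean(|measured - truth| / truth) * 100`, elementwise over aligned
#' vectors. Zero truth values are an error (the relative error is
#' undefined there).
#'
#' @param measured,truth aligned numeric vectors.
#' @param na.rm drop pairs with missing measurements.
#' @return MAPE in percent.
#' @export
mape <- function(measured, truth, na.rm = FALSE) {
  if (length(measured) != length(truth)) stop("inputs must align")
  if (any(truth == 0)) stop("truth contains zeros; MAPE undefined")
  e <- abs(measured - truth) / abs(truth) * 100
  mean(e, na.rm = na.rm)
}

#' Spectrally weighted average
#'
#' Collapses a spectral measurement onto an imaging channel using the
#' channel's normalized illumination spectrum as the weighting function:
#' `sum(w * s) / sum(w)`.
#'
#' @param spectrum measurement per wavelength.
#' @param led_profile non-negative weight per wavelength, aligned with
#'   `spectrum`, not all zero.
#' @return weighted average (scalar).
#' @export
spectral_weighted_average <- function(spectrum, led_profile) {
  if (length(spectrum) != length(led_profile)) {
    stop("spectrum and LED profile grids must align")
  }
  if (any(led_profile < 0) || sum(led_profile) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  sum(led_profile * spectrum) / sum(led_profile)
}

#' Wavelength-averaged error table over phase-function and polarization
#'
#' Aggregates per-acquisition errors into the summary layout used to
#' compare phase-function and polarization pairings: rows are assumed phase
#' functions, columns are quantity-by-polarization cells, and each cell is
#' the mean of the per-channel errors with omitted channels (undetermined
#' fraction above the 2% rule) excluded from the average.
#'
#' @param results data frame with columns `spf`, `polarization`, `channel`,
#'   `quantity`, `error` (percent) and optionally `omitted` (logical).
#' @return data frame, one row per `spf`, one column per
#'   `quantity`/`polarization` combination (named `quantity.polarization`),
#'   containing wavelength-averaged errors (NaN where every channel was
#'   omitted).
#' @export
error_table <- function(results) {
  need <- c("spf", "polarization", "channel", "quantity", "error")
  if (!all(need %in% names(results))) {
    stop("results must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(results$omitted)) results$omitted <- FALSE
  kept <- results[!results$omitted, , drop = FALSE]
  agg <- stats::aggregate(error ~ spf + polarization + quantity, data = kept,
                          FUN = mean)
  agg$quantity_pol <- paste(agg$quantity, agg$polarization, sep = ".")
  spfs <- unique(results$spf)
  cols <- unique(agg$quantity_pol)
  out <- data.frame(spf = spfs)
  for (cl in cols) {
    out[[cl]] <- vapply(spfs, function(s) {
      v <- agg$error[agg$spf == s & agg$quantity_pol == cl]
      if (length(v) == 0) NaN else v
    }, numeric(1))
  }
  out
}

#' Write an error table as CSV or Markdown
#'
#' @param table an [error_table()] result.
#' @param path file path.
#' @param format `"csv"` or `"markdown"`.
#' @export
write_error_table <- function(table, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    hdr <- paste0("| ", paste(names(table), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|")
    rows <- apply(table, 1, function(r) {
      paste0("| ", paste(format(r, digits = 4), collapse = " | "), " |")
    })
    writeLines(c(hdr, sep, rows), path)
  }
  invisible(path)
}
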