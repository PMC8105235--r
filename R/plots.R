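#' Plot an aortic time-density curve
#'
#' Enhancement versus time with the trigger threshold, trigger time and peak
#' marked when a [trigger_config()] is supplied.
#'
#' @param object An `fpa_tdc`.
#' @param cfg Optional [trigger_config()] to annotate trigger and peak.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpa_tdc
#' @export
autoplot.fpa_tdc <- function(object, cfg = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hu)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "aortic HU") +
    ggplot2::theme_minimal()
  if (!is.null(cfg)) {
    p <- p +
      ggplot2::geom_hline(yintercept = object$baseline_hu + cfg$threshold_hu,
                          linetype = "dashed") +
      ggplot2::geom_vline(xintercept = detect_trigger(object, cfg),
                          colour = "red") +
      ggplot2::geom_vline(xintercept = find_peak(object), colour = "blue")
  }
  p
}

#' Plot agreement between test and reference values
#'
#' @param object An `fpa_agreement`.
#' @param type `"scatter"` (identity and regression lines) or
#'   `"bland_altman"` (bias and limits of agreement).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpa_agreement
#' @export
autoplot.fpa_agreement <- function(object, type = c("scatter", "bland_altman"),
                                   ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    df <- tibble(x = object$x, y = object$y)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "red") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "reference", y = "test",
                    subtitle = sprintf("y = %.2fx %+.2f, r = %.2f, CCC = %.2f",
                                       object$slope, object$intercept,
                                       object$r, object$ccc)) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble(m = (object$x + object$y) / 2, d = object$y - object$x)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
      ggplot2::geom_hline(yintercept = object$bias, colour = "red") +
      ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "mean of methods", y = "difference (test - reference)") +
      ggplot2::theme_minimal()
  }
}

slice_df <- function(map, slice) {
  d <- dim(map)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  s <- map[, , slice]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(s)
  df
}

#' Plot an axial slice of a perfusion or CFR map
#'
#' @param object An `fpa_perfusion` or `fpa_cfr`.
#' @param slice Axial slice index (defaults to the mid-slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @method autoplot fpa_perfusion
#' @export
autoplot.fpa_perfusion <- function(object, slice = NULL, ...) {
  df <- slice_df(object$map, slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey95",
                                  name = "P (mL/min/g)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.fpa_perfusion
#' @method autoplot fpa_cfr
#' @export
autoplot.fpa_cfr <- function(object, slice = NULL, ...) {
  df <- slice_df(object$map, slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey95", option = "magma",
                                  name = "CFR") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

# Conventional flow-capacity colours, normal (red) to scar (black).
CAPACITY_PALETTE <- c("scar" = "black", "definite ischemia" = "#2166AC",
                      "moderately reduced" = "#4DAF4A",
                      "mildly reduced" = "#FFFF33",
                      "minimally reduced" = "#FF7F00", "normal" = "#E41A1C")

#' Plot an axial slice of a flow-capacity map
#'
#' @param object An `fpa_capacity`.
#' @param slice Axial slice index (defaults to the mid-slice).
#' @param ... Unused.
#' @return A ggplot raster with the conventional severity palette.
#' @method autoplot fpa_capacity
#' @export
autoplot.fpa_capacity <- function(object, slice = NULL, ...) {
  map <- object$class_index
  df <- slice_df(map, slice)
  df$class <- factor(object$legend[df$value], levels = object$legend)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = CAPACITY_PALETTE, na.value = "grey95",
                               name = "flow capacity", drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
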