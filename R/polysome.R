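#' Construct a polysome-gradient absorbance trace
#'
#' @param position uniformly spaced, strictly increasing gradient coordinates
#'   (e.g. elution position or time).
#' @param absorbance A254 values (AU), same length as \code{position}.
#' @param regions named list of two-element numeric vectors giving half-open
#'   position ranges \code{c(from, to)}; must include \code{monosome_80S} and
#'   \code{polysome} for [pm_ratio()], and the two must not overlap.
#' @param baseline constant AU offset subtracted before integration
#'   (default 0). See [estimate_baseline()].
#' @return object of class \code{absorbance_trace}.
#' @export
absorbance_trace <- function(position, absorbance, regions = list(),
                             baseline = 0) {
  stopifnot(length(position) == length(absorbance), length(position) >= 2)
  d <- diff(position)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  h <- d[1]
  if (any(abs(d - h) > 1e-9 * max(abs(position))))
    stop("positions must be uniformly spaced")
  span <- range(position)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2 || r[1] >= r[2])
      stop("region '", nm, "' must be c(from, to) with from < to")
    if (r[1] < span[1] - h / 2 || r[2] > span[2] + h / 2)
      stop("region '", nm, "' lies outside the trace span")
  }
  if (all(c("monosome_80S", "polysome") %in% names(regions))) {
    m <- regions$monosome_80S; p <- regions$polysome
    if (max(m[1], p[1]) < min(m[2], p[2]))
      stop("monosome_80S and polysome regions must be disjoint")
  }
  structure(list(position = position, absorbance = absorbance,
                 regions = regions, baseline = baseline, step = h),
            class = "absorbance_trace")
}

#' @export
print.absorbance_trace <- function(x, ...) {
  cat("absorbance_trace:", length(x$position), "points, step", x$step,
      "- regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate a constant baseline from a blank region
#'
#' The baseline is the minimum absorbance within the named region; assign the
#' result to the trace's \code{baseline} field to integrate
#' baseline-subtracted areas.
#' @param trace an \code{absorbance_trace}.
#' @param region name of a region in the trace covering signal-free gradient.
#' @return baseline value (AU).
#' @export
estimate_baseline <- function(trace, region) {
  idx <- region_indices(trace, region)
  min(trace$absorbance[idx[1]:idx[2]])
}

## region bounds snapped to the nearest sample points; returns c(i0, i1)
region_indices <- function(trace, region) {
  if (!region %in% names(trace$regions))
    stop("trace has no region named '", region, "'")
  r <- trace$regions[[region]]
  i0 <- which.min(abs(trace$position - r[1]))
  i1 <- which.min(abs(trace$position - r[2]))
  if (i1 - i0 + 1 < 3)
    stop("region '", region, "' contains fewer than 3 sample points")
  c(i0, i1)
}

#' Area under the curve by composite Simpson's rule
#'
#' Integrates the baseline-subtracted absorbance over a named region.
#' Region boundaries are snapped to the nearest sample points. Values that
#' become negative after baseline subtraction are clipped to 0. With an odd
#' number of sample intervals, Simpson's rule covers the first even count and
#' the final interval is added by the trapezoid rule.
#'
#' @param trace an \code{absorbance_trace}.
#' @param region region name.
#' @param clip_negative clip post-baseline negatives to zero (default TRUE).
#' @return area in AU x position units.
#' @export
simpson_auc <- function(trace, region, clip_negative = TRUE) {
  idx <- region_indices(trace, region)
  y <- trace$absorbance[idx[1]:idx[2]] - trace$baseline
  if (clip_negative) y <- pmax(y, 0)
  simpson_integrate(y, trace$step)
}

## composite Simpson on a uniform grid; odd interval count handled by a
## trailing trapezoid
simpson_integrate <- function(y, h) {
  n <- length(y) - 1  # number of intervals
  stopifnot(n >= 2)
  area <- 0
  m <- if (n %% 2 == 0) n else n - 1
  i <- seq(1, m - 1, by = 2)  # left index (1-based) of each Simpson pair
  area <- sum(h / 3 * (y[i] + 4 * y[i + 1] + y[i + 2]))
  if (n %% 2 == 1)
    area <- area + h / 2 * (y[n] + y[n + 1])
  area
}

#' Polysome to monosome area ratio
#'
#' Ratio of the Simpson's-rule areas of the \code{polysome} and
#' \code{monosome_80S} regions; the standard summary of global translational
#' activity from a sucrose-gradient trace.
#'
#' @param trace an \code{absorbance_trace} with both regions defined.
#' @param clip_negative passed to [simpson_auc()].
#' @return dimensionless P/M ratio.
#' @export
pm_ratio <- function(trace, clip_negative = TRUE) {
  mono <- simpson_auc(trace, "monosome_80S", clip_negative = clip_negative)
  poly <- simpson_auc(trace, "polysome", clip_negative = clip_negative)
  if (mono <= 0) stop("monosome area is not positive; P/M ratio undefined")
  poly / mono
}

#' Read a two-column trace file (position, absorbance)
#'
#' @param path TSV/CSV path; separator guessed from the extension.
#' @param regions,baseline passed to [absorbance_trace()].
#' @return an \code{absorbance_trace}.
#' @export
read_trace <- function(path, regions = list(), baseline = 0) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  absorbance_trace(df[[1]], df[[2]], regions = regions, baseline = baseline)
}

#' Write per-region areas and the P/M ratio as TSV
#' @param trace an \code{absorbance_trace}.
#' @param path output path.
#' @export
write_auc_table <- function(trace, path) {
  areas <- vapply(names(trace$regions), function(r) simpson_auc(trace, r),
                  numeric(1))
  out <- data.frame(region = names(trace$regions), area = unname(areas))
  if (all(c("monosome_80S", "polysome") %in% names(trace$regions)))
    out <- rbind(out, data.frame(region = "P/M_ratio",
                                 area = pm_ratio(trace)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
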