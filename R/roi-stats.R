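# Mask-restricted directional displacement statistics and the
# three-row (Mean / Min-Max / SD) per-direction report format, plus a
# two-condition comparison without inferential statistics.

.axisInfo <- function() {
  data.frame(
    axis = c("X", "Y", "Z"),
    direction = c("lateromedial", "anteroposterior", "axial"),
    col = c("ux_mm", "uy_mm", "uz_mm"),
    stringsAsFactors = FALSE
  )
}

#' Directional displacement statistics within a mask
#'
#' Per-axis mean, min, max and sample SD (n-1 denominator) of the mm
#' displacement over the valid field records whose node lies inside the
#' mask. The sign of the lateromedial (X) component depends on knee
#' laterality; reporting flips X for left knees onto the common
#' convention while stored fields remain unflipped.
#'
#' @param field a [DisplacementField] (or a records data.frame with the
#'   same columns).
#' @param mask a [LabelMask] on the parent volume grid.
#' @param laterality `"right"` or `"left"`.
#' @return data.frame with one row per axis: axis, direction, mean_mm,
#'   min_mm, max_mm, sd_mm, n_nodes.
#' @examples
#' # three valid nodes with X displacements 1, 2, 3 mm give
#' # mean 2, sd 1, min 1, max 3
#' @seealso [compareConditions()], [formatStatsTable()]
#' @export
roiStatistics <- function(field, mask, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  r <- if (is(field, "DisplacementField")) field@records else field
  m <- mask@data
  inMask <- m[cbind(r$i + 1L, r$j + 1L, r$k + 1L)]
  r <- r[r$valid & inMask, , drop = FALSE]
  if (nrow(r) == 0L) {
    stop("no valid displacement records inside the mask")
  }
  info <- .axisInfo()
  out <- do.call(rbind, lapply(seq_len(3), function(a) {
    u <- r[[info$col[a]]]
    if (a == 1L && laterality == "left") {
      u <- -u
    }
    data.frame(
      axis = info$axis[a], direction = info$direction[a],
      mean_mm = mean(u), min_mm = min(u), max_mm = max(u),
      sd_mm = if (length(u) > 1L) sd(u) else 0,
      n_nodes = length(u), stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Compare directional statistics between two conditions
#'
#' Per-axis mean difference (`b - a`) and ratio (`b / a`) between two
#' statistics tables, e.g. native versus lesioned states at one load. No
#' inferential statistics are attached.
#'
#' @param statsA,statsB data.frames from [roiStatistics()] covering the
#'   same axes.
#' @param names character(2) condition labels.
#' @return data.frame with axis, per-condition means, difference and
#'   ratio.
#' @export
compareConditions <- function(statsA, statsB, names = c("a", "b")) {
  if (!identical(statsA$axis, statsB$axis)) {
    stop("axis mismatch between the two statistics tables")
  }
  out <- data.frame(
    axis = statsA$axis, direction = statsA$direction,
    mean_a = statsA$mean_mm, mean_b = statsB$mean_mm,
    difference_mm = statsB$mean_mm - statsA$mean_mm,
    ratio = statsB$mean_mm / statsA$mean_mm,
    stringsAsFactors = FALSE
  )
  names(out)[3:4] <- paste0("mean_", names)
  attr(out, "conditions") <- names
  out
}

#' Render statistics in the three-row report layout
#'
#' Formats a [roiStatistics()] table in the conventional displacement
#' report layout: per direction, rows `Mean`, `Min-Max` and `SD`, values
#' printed to `digits` decimals (e.g. a mean of -0.983 mm with SD
#' 0.272 mm renders as "-0.983" and "0.272").
#'
#' @param stats data.frame from [roiStatistics()].
#' @param digits decimals to print.
#' @return data.frame with columns direction, statistic, value
#'   (character).
#' @export
formatStatsTable <- function(stats, digits = 3) {
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  do.call(rbind, lapply(seq_len(nrow(stats)), function(q) {
    s <- stats[q, ]
    data.frame(
      direction = rep(sprintf(
        "%s direction (Dp%s)",
        paste0(toupper(substring(s$direction, 1, 1)), substring(s$direction, 2)),
        s$axis
      ), 3),
      statistic = c("Mean", "Min-Max", "SD"),
      value = c(
        fmt(s$mean_mm),
        paste0(fmt(s$min_mm), "–", fmt(s$max_mm)),
        fmt(s$sd_mm)
      ),
      stringsAsFactors = FALSE
    )
  }))
}
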