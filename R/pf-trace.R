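#' Protofilament trace
#'
#' An ordered sequence of 3D points (nm) traced along one protofilament (PF)
#' at a microtubule end, together with the index of the flare origin: the
#' last traced point that still lies within the MT cylinder. Points from the
#' origin onward form the "flare", the part of the PF bending away from the
#' lattice. In manually built contour models the first point sits on the MT
#' wall and the second marks the last in-cylinder segment, so `origin_index`
#' is 2 for such models.
#'
#' @param points numeric matrix with 3 columns (x, y, z in nm), one row per
#'   point, ordered from the MT wall outward.
#' @param origin_index 1-based index of the flare origin within `points`.
#' @param grid_id,mt_id,pf_id identifiers (coerced to character).
#' @return An object of class `pf_trace`.
#' @examples
#' tr <- pf_trace(rbind(c(0, 0, -8), c(0, 0, 0), c(1, 0, 4), c(3, 0, 7)),
#'                origin_index = 2)
#' pf_flare_length(tr)
#' @export
pf_trace <- function(points, origin_index = 2L,
                     grid_id = "g1", mt_id = "mt1", pf_id = "pf1") {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have 3 columns (x, y, z in nm)", call. = FALSE)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L)
    stop("a pf_trace needs at least 2 points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("all coordinates must be finite", call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0))
    stop("consecutive points must be distinct (separation > 0 nm)",
         call. = FALSE)
  origin_index <- as.integer(origin_index)
  if (origin_index < 1L || origin_index > nrow(points))
    stop("`origin_index` out of range", call. = FALSE)
  structure(
    list(grid_id = as.character(grid_id), mt_id = as.character(mt_id),
         pf_id = as.character(pf_id), points = points,
         origin_index = origin_index),
    class = "pf_trace")
}

#' @export
print.pf_trace <- function(x, ...) {
  cat(sprintf("<pf_trace %s/%s/%s: %d points, flare origin at %d, flare %.2f nm>\n",
              x$grid_id, x$mt_id, x$pf_id, nrow(x$points), x$origin_index,
              pf_flare_length(x)))
  invisible(x)
}

#' Microtubule end record
#'
#' One MT end: its polarity, the state of any luminal capping density seen at
#' the end, the protofilament count of the lattice, and the traced PF
#' contours. Ends whose PFs are all blunt may carry no traces but still count
#' toward capping statistics.
#'
#' @param traces list of [pf_trace()] objects (possibly empty).
#' @param polarity `"plus"` or `"minus"`.
#' @param cap_state one of `"none"`, `"partial"`, `"full"`, `"attached"`
#'   (`"attached"`: end-on attachment to a larger assembly, counted as
#'   capped).
#' @param n_pf protofilament number of the lattice (13 or 14 for typical
#'   GMPCPP-nucleated MTs).
#' @param grid_id,mt_id identifiers.
#' @return An object of class `mt_end_record`.
#' @export
mt_end_record <- function(traces = list(), polarity = c("plus", "minus"),
                          cap_state = c("none", "partial", "full", "attached"),
                          n_pf = 14L, grid_id = "g1", mt_id = "mt1") {
  polarity <- match.arg(polarity)
  cap_state <- match.arg(cap_state)
  if (!is.list(traces) || !all(vapply(traces, inherits, TRUE, "pf_trace")))
    stop("`traces` must be a list of pf_trace objects", call. = FALSE)
  n_pf <- as.integer(n_pf)
  if (n_pf < 1L) stop("`n_pf` must be positive", call. = FALSE)
  if (length(traces) > n_pf)
    stop("more traces than lattice protofilaments", call. = FALSE)
  structure(
    list(grid_id = as.character(grid_id), mt_id = as.character(mt_id),
         polarity = polarity, cap_state = cap_state, n_pf = n_pf,
         traces = traces),
    class = "mt_end_record")
}

#' @export
print.mt_end_record <- function(x, ...) {
  cat(sprintf("<mt_end_record %s/%s: %s end, cap %s, %d/%d PFs traced>\n",
              x$grid_id, x$mt_id, x$polarity, x$cap_state,
              length(x$traces), x$n_pf))
  invisible(x)
}

# polyline arc length of a point matrix
polyline_length <- function(points) {
  if (is.null(points) || nrow(points) < 2L) return(0)
  sum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2)))
}

# cumulative arc-length coordinate along a polyline (first point at 0)
arc_coordinate <- function(points) {
  if (nrow(points) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                              points[-nrow(points), , drop = FALSE])^2))))
}
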