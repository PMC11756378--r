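.CONTOUR_COLUMNS <- c("grid_id", "mt_id", "polarity", "cap_state", "n_pf",
                      "pf_id", "point_index", "x_nm", "y_nm", "z_nm",
                      "origin_index")

#' Read a protofilament contour table
#'
#' Reads the contour CSV schema: one row per traced point with columns
#' `grid_id, mt_id, polarity, cap_state, n_pf, pf_id, point_index` (0-based,
#' ordered within each PF), `x_nm, y_nm, z_nm, origin_index` (0-based index
#' of the flare origin within the PF). Rows may appear in any order;
#' validation failures report the offending rows.
#'
#' @param path CSV file (UTF-8, header required).
#' @return list of [mt_end_record()] objects, one per `(grid_id, mt_id)`.
#' @export
read_contour_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CONTOUR_COLUMNS, names(tab))
  if (length(miss))
    stop("contour table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_pol <- which(!tab$polarity %in% c("plus", "minus"))
  if (length(bad_pol))
    stop("unknown polarity at rows ",
         paste(head(bad_pol, 5L), collapse = ", "), call. = FALSE)
  bad_cap <- which(!tab$cap_state %in% c("none", "partial", "full", "attached"))
  if (length(bad_cap))
    stop("unknown cap_state at rows ",
         paste(head(bad_cap, 5L), collapse = ", "), call. = FALSE)
  coords <- c("x_nm", "y_nm", "z_nm")
  if (any(!is.finite(as.matrix(tab[coords]))))
    stop("non-finite coordinates at rows ",
         paste(head(which(rowSums(!is.finite(as.matrix(tab[coords]))) > 0), 5L),
               collapse = ", "), call. = FALSE)
  tab$row <- seq_len(nrow(tab))
  ends <- list()
  for (piece in split(tab, list(tab$grid_id, tab$mt_id), drop = TRUE)) {
    traces <- list()
    for (pf in split(piece, piece$pf_id, drop = TRUE)) {
      pf <- pf[order(pf$point_index), , drop = FALSE]
      if (!identical(as.integer(pf$point_index),
                     seq_len(nrow(pf)) - 1L))
        stop("non-contiguous point_index for pf ", pf$pf_id[1L],
             " (rows ", paste(head(pf$row, 5L), collapse = ", "), ")",
             call. = FALSE)
      oi <- unique(pf$origin_index)
      if (length(oi) != 1L)
        stop("inconsistent origin_index for pf ", pf$pf_id[1L],
             call. = FALSE)
      traces[[length(traces) + 1L]] <- pf_trace(
        as.matrix(pf[coords]), origin_index = oi + 1L,
        grid_id = pf$grid_id[1L], mt_id = pf$mt_id[1L], pf_id = pf$pf_id[1L])
    }
    traces <- traces[order(vapply(traces, function(t) t$pf_id, ""))]
    ends[[length(ends) + 1L]] <- mt_end_record(
      traces, polarity = piece$polarity[1L], cap_state = piece$cap_state[1L],
      n_pf = piece$n_pf[1L], grid_id = piece$grid_id[1L],
      mt_id = piece$mt_id[1L])
  }
  ends[order(vapply(ends, function(e) paste(e$grid_id, e$mt_id), ""))]
}

#' Write MT end records to a contour table
#'
#' Inverse of [read_contour_table()] (0-based `point_index` and
#' `origin_index` in the file).
#'
#' @param ends list of [mt_end_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_table <- function(ends, path) {
  stopifnot(all(vapply(ends, inherits, TRUE, "mt_end_record")))
  rows <- list()
  for (e in ends) for (tr in e$traces) {
    n <- nrow(tr$points)
    rows[[length(rows) + 1L]] <- data.frame(
      grid_id = e$grid_id, mt_id = e$mt_id, polarity = e$polarity,
      cap_state = e$cap_state, n_pf = e$n_pf, pf_id = tr$pf_id,
      point_index = seq_len(n) - 1L,
      x_nm = tr$points[, 1L], y_nm = tr$points[, 2L], z_nm = tr$points[, 3L],
      origin_index = tr$origin_index - 1L, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    setNames(as.data.frame(matrix(nrow = 0, ncol = length(.CONTOUR_COLUMNS))),
             .CONTOUR_COLUMNS)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a kymograph trace table into event histories
#'
#' Schema: `mt_id, segment_index, dx_px, dt_frames, tip_marker` (0/1).
#' Segments are ordered by `segment_index` within each MT and converted with
#' [segments_to_events()].
#'
#' @param path CSV file.
#' @param calib a [kymo_calibration()].
#' @param ... passed to [segments_to_events()].
#' @return data.frame of classified events (zero rows, with a warning, for
#'   an empty table).
#' @export
read_kymo_table <- function(path, calib = kymo_calibration(), ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("mt_id", "segment_index", "dx_px", "dt_frames")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("kymo table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty kymograph table: ", path, call. = FALSE)
    return(data.frame(mt_id = character(0), class = character(0),
                      rate_um_min = numeric(0), duration_min = numeric(0),
                      tip_marker = integer(0)))
  }
  bad <- which(tab$dt_frames <= 0)
  if (length(bad))
    stop("non-positive dt_frames at rows ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  tab <- tab[order(tab$mt_id, tab$segment_index), , drop = FALSE]
  segments_to_events(tab, calib = calib, ...)
}

#' Write classified events to CSV
#'
#' @param events events data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
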