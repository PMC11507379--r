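#' Double a circular mitochondrial reference
#'
#' Concatenating the mitochondrial sequence with itself makes alignments
#' that cross the origin of the circle appear contiguous on the doubled
#' sequence; coordinates are mapped back to the circle with
#' [wrap_interval()].
#'
#' @param mito One-row sequence record table (see [seq_record()]).
#' @return One-row record of length `2L`, name suffixed `_x2`.
#' @export
double_reference <- function(mito) {
  stopifnot(nrow(mito) == 1L)
  if (endsWith(mito$name, "_x2")) {
    stop("reference '", mito$name, "' appears to be doubled already")
  }
  seq_record(paste0(mito$name, "_x2"), strrep(mito$seq, 2L), role = "unplaced")
}

#' Map a doubled-reference interval back onto the circle
#'
#' Coordinates are 0-based half-open on the doubled reference
#' (`0 <= start < end <= 2L`). The interval is reduced modulo the circle
#' length `L`; if the reduced interval crosses the origin it is rendered as
#' two segments, the first ending at `L`.
#'
#' @param start,end Integer coordinates on the doubled reference.
#' @param L Circle length.
#' @return A `circular_interval`: list with `L`, `start` (in `[0, L)`),
#'   `length`, and a two-column `segments` matrix (half-open) with one row,
#'   or two rows for an origin-spanning interval.
#' @examples
#' wrap_interval(16000, 17000, 16727)  # origin-spanning comma pair
#' @export
wrap_interval <- function(start, end, L) {
  stopifnot(length(start) == 1L, length(end) == 1L, length(L) == 1L)
  if (start < 0 || end <= start || end > 2L * L) {
    stop("require 0 <= start < end <= 2L; got [", start, ", ", end, ") with L = ", L)
  }
  len <- end - start
  if (len > L) {
    stop("interval of length ", len, " is longer than the circle (L = ", L, ")")
  }
  s <- start %% L
  structure(
    list(L = L, start = s, length = len, segments = circ_segments(s, len, L)),
    class = "circular_interval"
  )
}

# segments matrix (half-open) for a circular interval given start in [0, L)
circ_segments <- function(start, len, L) {
  if (start + len <= L) {
    matrix(c(start, start + len), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
  } else {
    matrix(c(start, 0, L, len - (L - start)), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
  }
}

#' Render a circular interval as a coordinate string
#'
#' Origin-spanning intervals are rendered as a pair of coordinate ranges
#' separated by a comma (e.g. `"16000-16727,0-273"`); all coordinates are
#' 0-based half-open.
#'
#' @param start Start position in `[0, L)` (vectorised).
#' @param len Interval length (vectorised).
#' @param L Circle length.
#' @return Character vector.
#' @export
mito_interval_string <- function(start, len, L) {
  mapply(function(s, l) {
    seg <- circ_segments(s, l, L)
    paste(paste0(seg[, "start"], "-", seg[, "end"]), collapse = ",")
  }, start, len, USE.NAMES = FALSE)
}

#' @export
format.circular_interval <- function(x, ...) {
  mito_interval_string(x$start, x$length, x$L)
}

#' @export
print.circular_interval <- function(x, ...) {
  cat("<circular_interval L=", x$L, "> ", format(x), "\n", sep = "")
  invisible(x)
}

# Gap and relative orientation of two arcs on a circle of length L.
# Arcs given as (start in [0, L), length). Returns list(gap, dir):
# gap = 0 if the arcs overlap; otherwise the minimal circular distance.
# dir = +1 if b follows a in the forward (clockwise) direction, -1 if b
# precedes a, 0 on overlap or exact tie.
circ_gap <- function(s1, l1, s2, l2, L) {
  overlap <- ((s2 - s1) %% L) < l1 || ((s1 - s2) %% L) < l2
  if (overlap) return(list(gap = 0L, dir = 0L))
  d_fwd <- (s2 - (s1 + l1)) %% L
  d_bwd <- (s1 - (s2 + l2)) %% L
  if (d_fwd < d_bwd) list(gap = d_fwd, dir = 1L)
  else if (d_bwd < d_fwd) list(gap = d_bwd, dir = -1L)
  else list(gap = d_fwd, dir = 0L)
}
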