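# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported proportions and
#' display-unit populations follow the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Even-odd ray casting; `poly` is an n x 2 vertex matrix (open or closed
# ring). Vectorised over points, loops over the (few) polygon edges.
# Points exactly on a horizontal edge follow the half-open convention of
# the crossing rule; fixture polygons are built so centers never sit on
# shared borders ambiguously (grid cell centers fall strictly inside).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) stopf("polygon needs at least 3 distinct vertices")
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Validate and normalise a rectangular extent c(xmin, ymin, xmax, ymax).
as_extent <- function(extent) {
  if (length(extent) != 4 || !is.numeric(extent)) {
    stopf("extent must be numeric c(xmin, ymin, xmax, ymax)")
  }
  extent <- as.numeric(extent)
  names(extent) <- c("xmin", "ymin", "xmax", "ymax")
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"]) {
    stopf("degenerate extent: zero or negative area")
  }
  extent
}

extent_area <- function(extent) {
  unname((extent["xmax"] - extent["xmin"]) * (extent["ymax"] - extent["ymin"]))
}
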