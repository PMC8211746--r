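# Small planar geometry engine for protected-area processing.
#
# All coordinates live in the grid's projected equal-area km frame, so areas
# computed here equal areas on the globe. Polygons are simple rings: numeric
# matrices with two columns (x, y), implicitly closed, no holes.
#
# Area of a union of rings is computed exactly by an event-driven vertical
# scanline: between two consecutive event abscissae (ring vertices, pairwise
# edge crossings, window edges) the union's vertical extent varies linearly
# with x, so evaluating the merged interval length at the interval midpoint
# and multiplying by the width integrates the union area exactly.

.as_ring <- function(p, id = "<ring>") {
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p)) {
    abort(sprintf("polygon %s must be a numeric matrix with columns x, y", id))
  }
  if (any(!is.finite(p))) abort(sprintf("polygon %s has non-finite vertices", id))
  # repair: drop repeated consecutive vertices and an explicit closing vertex
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) >= 2) {
    dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
    p <- p[!dup, , drop = FALSE]
  }
  if (nrow(p) < 3) abort(sprintf("polygon %s is degenerate (fewer than 3 distinct vertices)", id))
  p
}

#' Area of a simple polygon ring
#'
#' Shoelace formula; vertex order does not matter (absolute value).
#'
#' @param ring Numeric matrix with columns x, y (km), implicitly closed.
#' @return Area in km^2.
#' @export
polygon_area <- function(ring) {
  p <- .as_ring(ring)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# all edges of a list of rings: matrix x1,y1,x2,y2,ring
.ring_segments <- function(rings) {
  segs <- lapply(seq_along(rings), function(k) {
    p <- rings[[k]]
    nx <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    cbind(p, nx, k)
  })
  do.call(rbind, segs)
}

# x-coordinates of proper crossings between non-vertical segment pairs,
# restricted to the open window (x0, x1)
.crossing_events <- function(segs, x0, x1) {
  nv <- segs[, 1] != segs[, 3]
  s <- segs[nv, , drop = FALSE]
  n <- nrow(s)
  if (n < 2) return(numeric(0))
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    j <- seq.int(i + 1, n)
    p1x <- s[i, 1]; p1y <- s[i, 2]; rx <- s[i, 3] - p1x; ry <- s[i, 4] - p1y
    q1x <- s[j, 1]; q1y <- s[j, 2]
    sx <- s[j, 3] - q1x; sy <- s[j, 4] - q1y
    denom <- rx * sy - ry * sx
    ok <- denom != 0
    t <- ((q1x - p1x) * sy - (q1y - p1y) * sx) / denom
    u <- ((q1x - p1x) * ry - (q1y - p1y) * rx) / denom
    hit <- ok & t > 0 & t < 1 & u > 0 & u < 1
    xs <- p1x + t[hit] * rx
    out[[i]] <- xs[xs > x0 & xs < x1]
  }
  unlist(out, use.names = FALSE)
}

# merged length of the union of [lo, hi] intervals
.interval_union_length <- function(lo, hi) {
  if (length(lo) == 0) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > cur_hi) {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else if (hi[i] > cur_hi) cur_hi <- hi[i]
  }
  total + (cur_hi - cur_lo)
}

# vertical extent of the union of rings at abscissa x, clipped to [y0, y1]
.union_length_at <- function(segs, x, y0, y1) {
  lo <- numeric(0); hi <- numeric(0)
  for (k in unique(segs[, 5])) {
    s <- segs[segs[, 5] == k, , drop = FALSE]
    cross <- (s[, 1] - x) * (s[, 3] - x) < 0
    if (!any(cross)) next
    s <- s[cross, , drop = FALSE]
    ys <- s[, 2] + (x - s[, 1]) * (s[, 4] - s[, 2]) / (s[, 3] - s[, 1])
    ys <- sort(ys)
    if (length(ys) %% 2 != 0) next  # x grazes a vertex; measure-zero event
    a <- ys[seq(1, length(ys), by = 2)]
    b <- ys[seq(2, length(ys), by = 2)]
    a <- pmax(a, y0); b <- pmin(b, y1)
    keep <- b > a
    lo <- c(lo, a[keep]); hi <- c(hi, b[keep])
  }
  .interval_union_length(lo, hi)
}

# exact area of (union of rings) within the window [x0,x1] x [y0,y1]
.union_area_window <- function(rings, x0 = -Inf, x1 = Inf,
                               y0 = -Inf, y1 = Inf) {
  if (length(rings) == 0) return(0)
  segs <- .ring_segments(rings)
  xs <- c(segs[, 1], segs[, 3])
  if (!is.finite(x0)) x0 <- min(xs)
  if (!is.finite(x1)) x1 <- max(xs)
  if (x1 <= x0) return(0)
  ev <- sort(unique(c(x0, x1, xs[xs > x0 & xs < x1],
                      .crossing_events(segs, x0, x1))))
  mids <- (ev[-1] + ev[-length(ev)]) / 2
  widths <- diff(ev)
  sum(widths * vapply(mids, function(x) .union_length_at(segs, x, y0, y1),
                      numeric(1)))
}
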