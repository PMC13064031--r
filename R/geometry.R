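#' Point-in-polygon membership, boundary inclusive
#'
#' Even-odd ray casting with an explicit on-boundary test. Points lying
#' exactly on a polygon edge or vertex count as inside; ties are thereby
#' broken deterministically toward "inside", which matters for geofence
#' membership of tags standing on a zone border.
#'
#' @param x,y point coordinates (metres), equal length.
#' @param polygon numeric matrix with columns x,y, one row per vertex, in
#'   order (closing edge implied).
#' @return logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) >= 2, nrow(polygon) >= 3)
  px <- polygon[, 1]; py <- polygon[, 2]
  nv <- length(px)
  jx <- px[c(nv, seq_len(nv - 1))]  # previous vertex
  jy <- py[c(nv, seq_len(nv - 1))]
  n <- length(x)
  inside <- logical(n)
  eps <- 1e-9
  for (k in seq_len(n)) {
    xk <- x[k]; yk <- y[k]
    if (!is.finite(xk) || !is.finite(yk)) { inside[k] <- NA; next }
    # boundary test: point on segment (jx,jy)-(px,py)?
    cross <- (px - jx) * (yk - jy) - (py - jy) * (xk - jx)
    on_line <- abs(cross) <= eps
    within <- (xk >= pmin(jx, px) - eps) & (xk <= pmax(jx, px) + eps) &
              (yk >= pmin(jy, py) - eps) & (yk <= pmax(jy, py) + eps)
    if (any(on_line & within)) { inside[k] <- TRUE; next }
    # even-odd ray cast toward +x
    crosses <- ((py > yk) != (jy > yk)) &
               (xk < (jx - px) * (yk - py) / (jy - py) + px)
    inside[k] <- (sum(crosses) %% 2L) == 1L
  }
  inside
}

#' @keywords internal
#' @noRd
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test that a polygon is simple (no self-intersection)
#'
#' Checks all non-adjacent edge pairs for proper crossings; O(n^2), fine for
#' geofence-sized polygons.
#'
#' @param polygon numeric matrix, columns x,y.
#' @return `TRUE` if simple.
#' @export
polygon_is_simple <- function(polygon) {
  polygon <- as.matrix(polygon)
  nv <- nrow(polygon)
  if (nv < 3) return(FALSE)
  edges <- cbind(seq_len(nv), c(seq_len(nv)[-1], 1L))
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      # skip adjacent edges (share a vertex)
      shared <- length(intersect(edges[i, ], edges[j, ])) > 0
      if (shared) next
      if (segments_intersect(polygon[edges[i, 1], ], polygon[edges[i, 2], ],
                             polygon[edges[j, 1], ], polygon[edges[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
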