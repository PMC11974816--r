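# Internal numerical helpers shared across modules.

#' @importFrom stats approx coef lm median quantile sd smooth.spline splinefun
#'   kmeans rnorm runif setNames predict
NULL

# Otsu threshold of a numeric vector/matrix (wraps EBImage::otsu on a
# unit-scaled copy; returns the threshold on the original intensity scale).
.otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) {
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  }
  u <- (x - r[1]) / diff(r)
  thr <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1L)), range = c(0, 1),
                       levels = levels)
  r[1] + thr * diff(r)
}

# 1-D Gaussian smoothing with reflection padding; sigma in samples.
# sigma = 0 returns the input unchanged.
.gauss_smooth1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- c(rev(x[seq_len(min(radius, n))]), x,
           rev(x[seq.int(max(1L, n - radius + 1L), n)]))
  # if n < radius the reflected pads are short; extend by repetition
  while (length(pad) < n + 2L * radius) pad <- c(pad[1L], pad, pad[length(pad)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(radius + 1L):(radius + n)])
}

# 2-D Gaussian blur on a (row, col) matrix; sigma in px. Returns a matrix.
.gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# Integer-shift a matrix by (drow, dcol), filling vacated pixels with `fill`.
.shift_int <- function(m, drow, dcol, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- seq_len(h) - drow; sc <- seq_len(w) - dcol
  ok_r <- sr >= 1L & sr <= h; ok_c <- sc >= 1L & sc <= w
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c]]
  out
}

# Bilinear interpolation of matrix m at fractional (row, col) coordinates.
# Coordinates outside the image return `fill`.
.bilinear <- function(m, rows, cols, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- rep(fill, length(rows))
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= h & c0 + 1 <= w
  # clamp exact bottom/right edge onto the last cell
  edge <- (rows >= 1 & cols >= 1 & rows <= h & cols <= w) & !ok
  if (any(edge)) {
    r0[edge] <- pmin(r0[edge], h - 1L); c0[edge] <- pmin(c0[edge], w - 1L)
    fr[edge] <- rows[edge] - r0[edge]; fc[edge] <- cols[edge] - c0[edge]
    ok <- ok | edge
  }
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1L, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1L); i11 <- cbind(r0[ok] + 1L, c0[ok] + 1L)
    val[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i11] * fr[ok] * fc[ok]
  }
  val
}

# Connected components of a logical matrix; connectivity 4 (EBImage) or 8
# (igraph over the pixel adjacency graph). Returns an integer label matrix.
.label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  if (connectivity == 4L) {
    return(matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                  nrow(mask), ncol(mask)))
  }
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(0L, h, w))
  pos <- matrix(0L, h, w)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nr <- r + d[1L]; nc <- cc + d[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    ni <- (nc[ok] - 1L) * h + nr[ok]
    has <- pos[ni] > 0L
    if (any(has)) {
      edges <- c(edges, rbind(pos[idx[ok]][has], pos[ni][has]))
    }
  }
  g <- igraph::make_graph(edges = as.numeric(edges), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, h, w)
  out[idx] <- as.integer(comp)
  out
}

# Optimal assignment for a square cost matrix (Hungarian algorithm,
# O(n^3) shortest augmenting path formulation). Returns, for each row,
# the assigned column. Costs may contain large finite "forbidden" values
# but not Inf/NA.
.solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # potentials and matching, 1-indexed with a 0 dummy slot
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L  # columns are stored at offset +1; j0 = 1 means virtual col 0
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        jj <- j + 1L
        if (!used[jj]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(n + 1L)) {
        if (used[jj]) {
          if (p[jj] > 0L) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) match_row[p[j + 1L]] <- j
  match_row
}
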