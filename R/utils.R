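# Internal raster convention: images are plain numeric matrices with
# rows = y (height) and cols = x (width); pixel (x, y) is m[y + 1, x + 1],
# coordinates 0-based at pixel centers. All EBImage calls are wrapped here so
# the convention is enforced in one place.

ps_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pombeseg_error", "error")))
}

#' @importFrom stats runif rnorm sd var
NULL

# shifted copy of m with replicate (nearest-edge) padding; value at (i, j)
# is m[i - dy, j - dx]
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 5-point Laplacian with zero-flux (Neumann) boundaries
laplacian_mat <- function(m) {
  shift_mat(m, 1L, 0L) + shift_mat(m, -1L, 0L) +
    shift_mat(m, 0L, 1L) + shift_mat(m, 0L, -1L) - 4 * m
}

# central-difference gradient (replicate edges)
gradient_mat <- function(m) {
  list(
    gx = (shift_mat(m, 0L, -1L) - shift_mat(m, 0L, 1L)) / 2,
    gy = (shift_mat(m, -1L, 0L) - shift_mat(m, 1L, 0L)) / 2
  )
}

# Sobel gradient magnitude
sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(m, kx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# disk-kernel mean filter, reflect-free replicate padding
mean_disk_filter <- function(m, radius) {
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  k <- k / sum(k)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

gaussian_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `mask`
# (0 inside the set, Inf when the set is empty)
dist_to_set <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  as.matrix(EBImage::distmap(ifelse(mask, 0, 1), metric = "euclidean"))
}

# 8-connected labelling built on EBImage's 4-connected bwlabel by merging
# labels that touch diagonally
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]      # (i,j) vs (i+1,j+1)
  c1 <- lab[-nr, -1]; d <- lab[-1, -nc]     # (i,j+1) vs (i+1,j)
  s1 <- a > 0L & b > 0L & a != b
  s2 <- c1 > 0L & d > 0L & c1 != d
  edges <- rbind(cbind(a[s1], b[s1]), cbind(c1[s2], d[s2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nmax - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  newlab <- lab
  newlab[lab > 0L] <- memb[lab[lab > 0L]]
  # compact to 1..K
  u <- sort(unique(newlab[newlab > 0L]))
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  newlab[newlab > 0L] <- remap[newlab[newlab > 0L]]
  newlab
}

component_sizes <- function(lab) {
  tabulate(lab[lab > 0L], nbins = max(lab, 0L))
}

# drop labelled components smaller than min_size, relabel 1..K
filter_components <- function(lab, min_size) {
  if (max(lab) == 0L) return(lab)
  sz <- component_sizes(lab)
  keep <- which(sz >= min_size)
  remap <- integer(length(sz))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

component_centroids <- function(lab) {
  n <- max(lab, 0L)
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cx <- tapply(idx[, 2] - 1, l, mean)
  cy <- tapply(idx[, 1] - 1, l, mean)
  cbind(x = as.numeric(cx), y = as.numeric(cy))
}

## ---- polygon helpers (vertices: matrix with columns x, y; closed
##      implicitly, no duplicated endpoint) ----

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_perimeter <- function(v) {
  dx <- diff(c(v[, 1], v[1, 1])); dy <- diff(c(v[, 2], v[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# resample a closed polygon to points equally spaced in arc length
resample_closed <- function(v, spacing = NULL, n = NULL, min_vertices = 8L) {
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(diff(vc[, 1])^2 + diff(vc[, 2])^2)
  len <- sum(seg)
  if (is.null(n)) n <- max(min_vertices, round(len / spacing))
  if (len <= 0) return(v[rep(1L, min_vertices), , drop = FALSE])
  s <- cumsum(c(0, seg))
  target <- seq(0, len, length.out = n + 1L)[-(n + 1L)]
  # strictly increasing knots for interpolation (drop zero-length segments)
  ok <- c(TRUE, diff(s) > 0)
  xs <- stats::approx(s[ok], vc[ok, 1], xout = target, rule = 2)$y
  ys <- stats::approx(s[ok], vc[ok, 2], xout = target, rule = 2)$y
  cbind(x = xs, y = ys)
}

# rasterize a closed polygon into a logical h x w matrix (pixel centers)
polygon_mask <- function(v, height, width) {
  out <- matrix(FALSE, height, width)
  if (nrow(v) < 3L) return(out)
  x0 <- max(0L, floor(min(v[, 1])))
  x1 <- min(width - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2])))
  y1 <- min(height - 1L, ceiling(max(v[, 2])))
  if (x1 < x0 || y1 < y0) return(out)
  gx <- x0:x1; gy <- y0:y1
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  inside <- mgcv::in.out(rbind(as.matrix(v[, 1:2]), v[1, 1:2, drop = FALSE]), pts)
  out[cbind(pts[inside, 2] + 1L, pts[inside, 1] + 1L)] <- TRUE
  out
}

# bilinear interpolation of field at 0-based (x, y) positions (clamped)
bilinear_sample <- function(field, x, y) {
  nr <- nrow(field); nc <- ncol(field)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  f00 <- field[cbind(i0, j0)]
  f01 <- field[cbind(i0, j0 + 1)]
  f10 <- field[cbind(i0 + 1, j0)]
  f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}

# evaluate scoped RNG: run expr under a seed, restore global RNG state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
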