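#' Compute the gradient vector flow field of an edge map
#'
#' The GVF field (u, v) minimizes
#' `E = sum mu*(|grad u|^2 + |grad v|^2) + |grad f|^2 * |(u, v) - grad f|^2`,
#' diffusing the edge-map gradient into homogeneous regions while keeping it
#' close to `grad f` where the edge signal is strong. The minimizer is
#' approached by the explicit diffusion-reaction iteration
#' `u <- u + dt * (mu * lap(u) - (u - f_x) * (f_x^2 + f_y^2))` (and likewise
#' v), initialized at `(f_x, f_y)`.
#'
#' @param f edge map with values in `[0, 1]`.
#' @param mu regularization weight (default 0.8).
#' @param n_iter number of iterations.
#' @param dt time step; must satisfy the explicit-scheme stability bound
#'   `dt <= 1/(4*mu)` (default 90% of the bound).
#' @return object of class `gvf_field`: matrices `u`, `v`, plus `mu`,
#'   `iterations` and the gradient images `fx`, `fy`.
#' @export
compute_gvf <- function(f, mu = 0.8, n_iter = 80, dt = NULL) {
  if (mu <= 0) ps_error("compute_gvf: mu must be positive", "pombeseg_validation_error")
  if (is.null(dt)) dt <- 0.9 * 0.25 / mu
  if (dt > 1 / (4 * mu) + 1e-12)
    ps_error(sprintf("compute_gvf: dt = %.4g violates the stability bound 1/(4*mu) = %.4g",
                     dt, 1 / (4 * mu)), "pombeseg_validation_error")
  g <- gradient_mat(f)
  fx <- g$gx; fy <- g$gy
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  for (k in seq_len(n_iter)) {
    u <- u + dt * (mu * laplacian_mat(u) - (u - fx) * b)
    v <- v + dt * (mu * laplacian_mat(v) - (v - fy) * b)
  }
  structure(list(u = u, v = v, mu = mu, iterations = n_iter, dt = dt,
                 fx = fx, fy = fy),
            class = "gvf_field")
}

#' Discretized GVF energy
#'
#' Evaluates the energy functional minimized by the GVF field on the same
#' discretization as the solver: forward-difference gradients of (u, v) with
#' zero-flux boundaries, and the data term weighted by `f_x^2 + f_y^2`.
#'
#' @param u,v field components.
#' @param fx,fy edge-map gradient (central differences of f).
#' @param mu regularization weight.
#' @return scalar energy.
#' @export
gvf_energy <- function(u, v, fx, fy, mu) {
  fd <- function(m) {
    dx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    dy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    sum(dx^2) + sum(dy^2)
  }
  b <- fx^2 + fy^2
  mu * (fd(u) + fd(v)) + sum(b * ((u - fx)^2 + (v - fy)^2))
}

#' Discrete internal energy of a snake contour
#'
#' `E_int = sum(alpha * |x_s|^2 + beta * |x_ss|^2) / 2` with periodic
#' finite differences; alpha is the tension and beta the rigidity weight.
#'
#' @param contour vertex matrix (columns x, y; closed implicitly).
#' @param alpha,beta tension and rigidity weights.
#' @return scalar energy.
#' @export
internal_energy <- function(contour, alpha = 0.03, beta = 0.2) {
  v <- as.matrix(contour[, 1:2])
  n <- nrow(v)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  d1 <- v[nxt, ] - v
  d2 <- v[nxt, ] - 2 * v + v[prv, ]
  sum(alpha * rowSums(d1^2) + beta * rowSums(d2^2)) / 2
}

# cyclic internal-force system matrix: solve (I - dt*lambda1*A) x_new = rhs
# with A = -(alpha*K2 + beta*K4), K2 the cyclic second-difference Laplacian
snake_system <- function(n, alpha, beta, lambda1, dt) {
  K2 <- matrix(0, n, n)
  idx <- seq_len(n)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  K2[cbind(idx, idx)] <- -2
  K2[cbind(idx, nxt)] <- 1
  K2[cbind(idx, prv)] <- 1
  A <- alpha * K2 - beta * (K2 %*% K2)
  solve(diag(n) - dt * lambda1 * A)
}

#' Evolve a snake contour under GVF forces
#'
#' Semi-implicit evolution: internal (tension/rigidity) forces are treated
#' implicitly through the cyclic pentadiagonal system implied by alpha and
#' beta (weighted by lambda1); the external force is `lambda2 * (u, v)`
#' sampled at the vertices by bilinear interpolation. Vertices are resampled
#' to uniform spacing every `resample_every` iterations and clamped to the
#' image bounds. Evolution stops at `n_iter` or when the maximum vertex
#' displacement drops below `tol`.
#'
#' @param contour vertex matrix (columns x, y).
#' @param field a `gvf_field` on the same grid.
#' @param lambda1,lambda2 internal / external force weights.
#' @param alpha,beta tension and rigidity.
#' @param n_iter iteration cap.
#' @param dt time step.
#' @param resample_every resampling period (iterations).
#' @param spacing target vertex spacing (px).
#' @param tol stopping displacement (px).
#' @return final contour matrix; attribute `"degenerate"` is TRUE when the
#'   contour collapsed below 8 vertices (flagged, not fatal).
#' @export
evolve_snake <- function(contour, field, lambda1 = 1, lambda2 = 1,
                         alpha = 0.03, beta = 0.2, n_iter = 200, dt = 1,
                         resample_every = 10, spacing = 2, tol = 0.05) {
  v <- as.matrix(contour[, 1:2, drop = FALSE])
  h <- nrow(field$u); w <- ncol(field$u)
  # unit-max normalization of the external force: the GVF field decays with
  # distance from edges, so raw magnitudes depend on image size and edge
  # density; scaling by the field maximum makes the snake step size (and the
  # iteration budget) comparable across images without changing force
  # directions or zeros
  fmax <- sqrt(max(field$u^2 + field$v^2))
  fscale <- if (fmax > 0) 1 / fmax else 1
  degenerate <- FALSE
  n <- nrow(v)
  if (n < 8L) degenerate <- TRUE
  S <- if (!degenerate) snake_system(n, alpha, beta, lambda1, dt) else NULL
  if (!degenerate) for (k in seq_len(n_iter)) {
    if (k %% resample_every == 0L) {
      per <- polygon_perimeter(v)
      if (per < 8 * 0.5) { degenerate <- TRUE; break }
      v2 <- resample_closed(v, spacing = spacing)
      if (nrow(v2) != n) {
        n <- nrow(v2)
        if (n < 8L) { degenerate <- TRUE; break }
        S <- snake_system(n, alpha, beta, lambda1, dt)
      }
      v <- v2
    }
    fu <- fscale * bilinear_sample(field$u, v[, 1], v[, 2])
    fv <- fscale * bilinear_sample(field$v, v[, 1], v[, 2])
    # keep only the component normal to the contour: the tangential part of
    # the external force merely reparameterizes the curve, and on pixel-rough
    # edge maps it bunches vertices at local attractors
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    tx <- v[nxt, 1] - v[prv, 1]; ty <- v[nxt, 2] - v[prv, 2]
    tl <- pmax(sqrt(tx^2 + ty^2), 1e-12)
    nx <- -ty / tl; ny <- tx / tl
    fn <- fu * nx + fv * ny
    rhs <- v + dt * lambda2 * cbind(fn * nx, fn * ny)
    vnew <- S %*% rhs
    vnew[, 1] <- pmin(pmax(vnew[, 1], 0), w - 1)
    vnew[, 2] <- pmin(pmax(vnew[, 2], 0), h - 1)
    disp <- max(abs(vnew - v))
    v <- vnew
    if (disp < tol) break
  }
  colnames(v) <- c("x", "y")
  attr(v, "degenerate") <- degenerate
  attr(v, "component") <- attr(contour, "component")
  v
}

#' Segment all cells of a resolved class map
#'
#' Orchestrates initial contours -> membrane edge map -> GVF -> snake
#' evolution, then rasterizes the final contours into an instance label
#' mask. Pixels claimed by several contours are resolved smaller-area-wins,
#' then first-come.
#'
#' @param cmap resolved `pixel_class_map`.
#' @param config a [pipeline_config()].
#' @return list: `contours` (final contours, one per interior component,
#'   with degeneracy flags), `label_mask` (integer matrix, k = contour k),
#'   `edge_map`, `gvf` (the field).
#' @export
segment_cells <- function(cmap, config = pipeline_config()) {
  init <- initial_contours(cmap, config$min_cell_area, config$contour_spacing)
  h <- nrow(cmap$labels); w <- ncol(cmap$labels)
  if (length(init) == 0L) {
    return(list(contours = list(), label_mask = matrix(0L, h, w),
                edge_map = membrane_edge_map(cmap), gvf = NULL))
  }
  f <- membrane_edge_map(cmap)
  gvf <- compute_gvf(f, mu = config$mu_gvf, n_iter = config$gvf_iters,
                     dt = config$gvf_dt)
  contours <- lapply(init, function(cc)
    evolve_snake(cc, gvf, lambda1 = config$lambda1, lambda2 = config$lambda2,
                 alpha = config$alpha, beta = config$beta,
                 n_iter = config$snake_iters, dt = config$snake_dt,
                 resample_every = config$resample_every,
                 spacing = config$contour_spacing))
  list(contours = contours,
       label_mask = contours_label_mask(contours, c(h, w)),
       edge_map = f, gvf = gvf)
}

#' Rasterize contours into an instance label mask
#'
#' @param contours list of contour matrices; mask value k corresponds to
#'   `contours[[k]]`.
#' @param dims image `c(height, width)`.
#' @return integer matrix; contested pixels go to the smaller contour, then
#'   first-come.
#' @export
contours_label_mask <- function(contours, dims) {
  mask <- matrix(0L, dims[1], dims[2])
  if (length(contours) == 0L) return(mask)
  areas <- vapply(contours, function(v) polygon_area(as.matrix(v[, 1:2])), 0)
  for (k in order(areas)) {
    pm <- polygon_mask(contours[[k]], dims[1], dims[2])
    claim <- pm & mask == 0L
    mask[claim] <- k
  }
  mask
}
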