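# Shared fixtures, built once per test run and cached (several files reuse
# the same scenes and the trained validator).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_scene <- function(preset = "wildtype", seed = 7) {
  cached(paste0("scene_", preset, "_", seed),
         generate_scene(scene_preset(preset, seed = seed)))
}

# small scene for fast unit tests
small_scene <- function(seed = 3) {
  cached(paste0("small_", seed),
         generate_scene(scene_spec(shape = c(256L, 256L), n_cells = 8L,
                                   seed = seed)))
}

test_model <- function() {
  cached("model", {
    tr <- cached("training_set", make_training_set(seed = 42))
    train_validators(tr, seed = 42)
  })
}

# circular-ridge edge map fixture: ridge of radius r centred in an n x n frame
circle_edge_map <- function(n = 64, r = 20, sigma = 1) {
  ctr <- (n - 1) / 2
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  d <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  f <- exp(-(d - r)^2 / (2 * sigma^2))
  f / max(f)
}

circle_contour <- function(r, n_pts = 40, ctr) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  cbind(x = ctr + r * cos(th), y = ctr + r * sin(th))
}

# brute-force Otsu oracle on an 8-bit histogram: exhaustive scan over all
# split points, computing class means directly
otsu_oracle_8bit <- function(counts) {
  vals <- 0:255
  best_k <- NA_integer_; best_var <- -Inf
  tot <- sum(counts)
  for (k in 0:254) {
    sel <- vals <= k
    w0 <- sum(counts[sel]); w1 <- tot - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[sel] * vals[sel]) / w0
    m1 <- sum(counts[!sel] * vals[!sel]) / w1
    v <- (w0 / tot) * (w1 / tot) * (m0 - m1)^2
    if (v > best_var) { best_var <- v; best_k <- k }
  }
  list(split = best_k, between_var = best_var)
}

# independent GVF gradient-descent oracle: sparse-matrix gradient of the
# discretized energy, plain gradient descent with step dt/2
gvf_descent_oracle <- function(f, mu, n_iter, dt) {
  nr <- nrow(f); nc <- ncol(f)
  # central-difference gradient of f with replicated edges
  rep_shift <- function(m, dy, dx) {
    ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
    m[ri, ci]
  }
  fx <- (rep_shift(f, 0, -1) - rep_shift(f, 0, 1)) / 2
  fy <- (rep_shift(f, -1, 0) - rep_shift(f, 1, 0)) / 2
  g <- fx^2 + fy^2
  D1 <- function(n) {
    Matrix::bandSparse(n - 1, n, k = 0:1,
                       diagonals = list(rep(-1, n - 1), rep(1, n - 1)))
  }
  Iy <- Matrix::Diagonal(nr); Ix <- Matrix::Diagonal(nc)
  # vec(m) stacks columns; x-differences act on columns, y on rows
  Dx <- Matrix::kronecker(D1(nc), Iy)
  Dy <- Matrix::kronecker(Ix, D1(nr))
  K <- Matrix::crossprod(Dx) + Matrix::crossprod(Dy)
  gv <- as.numeric(g)
  descend <- function(u0, f0) {
    u <- as.numeric(u0)
    step <- dt / 2
    for (i in seq_len(n_iter)) {
      grad <- 2 * (mu * as.numeric(K %*% u) + gv * (u - as.numeric(f0)))
      u <- u - step * grad
    }
    matrix(u, nr, nc)
  }
  list(u = descend(fx, fx), v = descend(fy, fy), fx = fx, fy = fy)
}

# plain-R reference for the ambiguous-pixel resolution rule: explicit loops,
# brute-force Euclidean distances
resolve_reference <- function(labels) {
  dist_set <- function(lab, cls) {
    idx <- which(lab == cls, arr.ind = TRUE)
    out <- matrix(Inf, nrow(lab), ncol(lab))
    if (nrow(idx) == 0) return(out)
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
    out
  }
  L <- labels
  repeat {
    X <- which(L == CLASS_AMBIGUOUS, arr.ind = TRUE)
    if (nrow(X) == 0) break
    Db <- dist_set(L, CLASS_BACKGROUND)
    Dc <- dist_set(L, CLASS_INTERIOR)
    Dm <- dist_set(L, CLASS_MEMBRANE)
    changed <- FALSE
    newL <- L
    for (k in seq_len(nrow(X))) {
      i <- X[k, 1]; j <- X[k, 2]
      if (Db[i, j] <= Dc[i, j] && Db[i, j] < Dm[i, j]) {
        newL[i, j] <- CLASS_BACKGROUND; changed <- TRUE
      } else if (Dc[i, j] < Db[i, j] && Dc[i, j] < Dm[i, j]) {
        newL[i, j] <- CLASS_INTERIOR; changed <- TRUE
      }
    }
    L <- newL
    if (!changed) break
  }
  L[L == CLASS_AMBIGUOUS] <- CLASS_MEMBRANE
  L
}
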