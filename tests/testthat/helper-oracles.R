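# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force summations, finite differences,
# dense quadrature, constrained generic optimizers.

# centered cubic B-spline, support (-2, 2)
bspline3 <- function(s) {
  a <- abs(s)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# naive full-lattice FFD summation
ffd_brute <- function(transform, pts) {
  cp <- control_points(transform)
  h <- transform$control_spacing
  A <- transform$pre_affine
  base <- sweep(pts %*% t(A$matrix), 2, A$translation, "+")
  disp <- t(vapply(seq_len(nrow(pts)), function(i) {
    w <- bspline3((pts[i, 1] - cp[, 1]) / h[1]) *
      bspline3((pts[i, 2] - cp[, 2]) / h[2]) *
      bspline3((pts[i, 3] - cp[, 3]) / h[3])
    colSums(w * transform$coefficients)
  }, numeric(3)))
  base + disp
}

# central finite-difference Jacobian determinant
jacdet_fd <- function(transform, p, h = NULL) {
  if (is.null(h)) h <- 1e-3 * min(transform$control_spacing)
  G <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    G[, j] <- (ffd_apply(transform, p + e) - ffd_apply(transform, p - e)) /
      (2 * h)
  }
  det(G)
}

# second-order central-difference squared Frobenius norm of the Hessian of T
hess_frob2_fd <- function(transform, p, h = 1e-3) {
  s <- 0
  f0 <- ffd_apply(transform, p)
  for (j in 1:3) for (k in 1:3) {
    ej <- numeric(3); ej[j] <- h
    ek <- numeric(3); ek[k] <- h
    H <- if (j == k) {
      (ffd_apply(transform, p + ej) - 2 * f0 + ffd_apply(transform, p - ej)) /
        h^2
    } else {
      (ffd_apply(transform, p + ej + ek) - ffd_apply(transform, p + ej - ek) -
         ffd_apply(transform, p - ej + ek) +
         ffd_apply(transform, p - ej - ek)) / (4 * h^2)
    }
    s <- s + sum(H^2)
  }
  s
}

# brute-force trilinear interpolation of a volume_image at one point
trilerp_brute <- function(v, p, fill = -1000) {
  u <- (p - v$origin) / v$spacing
  d <- dim(v$data)
  if (any(u < 0) || any(u > d - 1)) return(fill)
  i <- pmin(floor(u), d - 2)
  t <- u - i
  val <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a) t[1] else 1 - t[1]) * (if (b) t[2] else 1 - t[2]) *
      (if (cc) t[3] else 1 - t[3])
    val <- val + w * v$data[i[1] + a + 1, i[2] + b + 1, i[3] + cc + 1]
  }
  val
}

# brute-force binary morphology with Euclidean-ball offsets
ball_offsets <- function(r) {
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= r^2, ])
}

dilate_brute <- function(mask, r) {
  if (r == 0) return(mask)
  d <- dim(mask)
  out <- array(FALSE, d)
  off <- ball_offsets(r)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    m <- sweep(idx, 2, off[k, ], "+")
    ok <- m[, 1] >= 1 & m[, 1] <= d[1] & m[, 2] >= 1 & m[, 2] <= d[2] &
      m[, 3] >= 1 & m[, 3] <= d[3]
    out[m[ok, , drop = FALSE]] <- TRUE
  }
  out
}

erode_brute <- function(mask, r) {
  if (r == 0) return(mask)
  !dilate_brute(!mask, r)
}

close_brute <- function(mask, r) erode_brute(dilate_brute(mask, r), r)

# exact point-to-triangle distance via a constrained generic optimizer
# (convex QP over the barycentric simplex, solved with constrOptim)
point_tri_dist_oracle <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a
  f <- function(uv) sum((p - (a + uv[1] * e1 + uv[2] * e2))^2)
  gr <- function(uv) {
    r <- a + uv[1] * e1 + uv[2] * e2 - p
    2 * c(sum(r * e1), sum(r * e2))
  }
  # u >= 0, v >= 0, u + v <= 1
  ui <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  ci <- c(0, 0, -1)
  best <- Inf
  for (st in list(c(1, 1) / 3, c(0.05, 0.05), c(0.9, 0.05), c(0.05, 0.9))) {
    r <- tryCatch(
      stats::constrOptim(st, f, gr, ui = ui, ci = ci,
                         control = list(reltol = 1e-14)),
      error = function(e)
        stats::constrOptim(st, f, grad = NULL, ui = ui, ci = ci,
                           control = list(reltol = 1e-12)))
    best <- min(best, r$value)
  }
  # also check the vertices (constrOptim needs a strictly interior start)
  best <- min(best, f(c(0, 0)), f(c(1, 0)), f(c(0, 1)))
  sqrt(best)
}

# signed in-circumcircle predicate for Delaunay verification
incircle_oracle <- function(a, b, c, d) {
  if ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]) < 0) {
    tmp <- b; b <- c; c <- tmp
  }
  det(rbind(c(a - d, sum((a - d)^2)),
            c(b - d, sum((b - d)^2)),
            c(c - d, sum((c - d)^2))))
}

polygon_area <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

random_ffd <- function(shape = c(8, 8, 8), spacing = c(5, 5, 5),
                       origin = c(-10, -10, -10), sd = 0.5,
                       pre_affine = affine_transform()) {
  ffd_transform(origin, spacing, shape,
                matrix(stats::rnorm(prod(shape) * 3, sd = sd), ncol = 3),
                pre_affine = pre_affine)
}
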