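#' Probability density specification for one uncertain parameter
#'
#' Either a truncated Gaussian (renormalized to integrate to 1 over its
#' bounds) or a uniform density. The defaults used for the registration
#' study are a truncated `N(20, 4)` on `[8, 32]` mm for the finest grid
#' spacing and a uniform density on `[0, 1000]` for the regularization
#' weight.
#'
#' @param kind `"truncated_gaussian"` or `"uniform"`.
#' @param mean,sd Gaussian parameters (ignored for uniform).
#' @param bounds length-2 numeric interval.
#' @return An object of class `pdf_spec`.
#' @export
pdf_spec <- function(kind = c("truncated_gaussian", "uniform"),
                     mean = 0, sd = 1, bounds = c(0, 1)) {
  kind <- match.arg(kind)
  stopifnot(length(bounds) == 2L, bounds[2] > bounds[1],
            all(is.finite(bounds)))
  if (kind == "truncated_gaussian") stopifnot(sd > 0)
  structure(list(kind = kind, mean = mean, sd = sd, bounds = bounds),
            class = "pdf_spec")
}

#' Evaluate a parameter density
#'
#' @param spec a [pdf_spec()].
#' @param x numeric vector of parameter values.
#' @return density values (0 outside the bounds).
#' @export
pdf_eval <- function(spec, x) {
  inb <- x >= spec$bounds[1] & x <= spec$bounds[2]
  out <- numeric(length(x))
  if (spec$kind == "uniform") {
    out[inb] <- 1 / diff(spec$bounds)
  } else {
    z <- stats::pnorm(spec$bounds, spec$mean, spec$sd)
    out[inb] <- stats::dnorm(x[inb], spec$mean, spec$sd) / (z[2] - z[1])
  }
  out
}

pdf_sample <- function(spec, n) {
  u <- stats::runif(n)
  if (spec$kind == "uniform") {
    spec$bounds[1] + u * diff(spec$bounds)
  } else {
    z <- stats::pnorm(spec$bounds, spec$mean, spec$sd)
    stats::qnorm(z[1] + u * (z[2] - z[1]), spec$mean, spec$sd)
  }
}

#' Two-dimensional uncertain-parameter space
#'
#' @param bounds 2 x 2 matrix, one row per parameter: `(min, max)`.
#' @param pdfs list of two [pdf_spec()]s (independent parameters).
#' @return An object of class `parameter_space`.
#' @export
parameter_space <- function(bounds = rbind(c(8, 32), c(0, 1000)),
                            pdfs = list(
                              pdf_spec("truncated_gaussian", mean = 20,
                                       sd = 4, bounds = c(8, 32)),
                              pdf_spec("uniform", bounds = c(0, 1000)))) {
  bounds <- as.matrix(bounds)
  stopifnot(all(dim(bounds) == c(2, 2)), length(pdfs) == 2L)
  for (i in 1:2)
    stopifnot(isTRUE(all.equal(pdfs[[i]]$bounds, as.numeric(bounds[i, ]))))
  structure(list(n = 2L, bounds = bounds, pdfs = pdfs),
            class = "parameter_space")
}

#' Unit-square parameter space with uniform densities
#' @return a [parameter_space()] on `[0,1]^2`.
#' @export
unit_square_space <- function() {
  parameter_space(rbind(c(0, 1), c(0, 1)),
                  list(pdf_spec("uniform", bounds = c(0, 1)),
                       pdf_spec("uniform", bounds = c(0, 1))))
}

space_pdf <- function(space, pts) {
  pdf_eval(space$pdfs[[1]], pts[, 1]) * pdf_eval(space$pdfs[[2]], pts[, 2])
}

space_area <- function(space) prod(space$bounds[, 2] - space$bounds[, 1])

space_corners <- function(space) {
  b <- space$bounds
  cbind(c(b[1, 1], b[1, 2], b[1, 1], b[1, 2]),
        c(b[2, 1], b[2, 1], b[2, 2], b[2, 2]))
}

space_sample <- function(space, n) {
  cbind(pdf_sample(space$pdfs[[1]], n), pdf_sample(space$pdfs[[2]], n))
}

# ---------------------------------------------------------------------------
# 2D Delaunay triangulation (Bowyer-Watson with a super-triangle)

orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

in_circumcircle <- function(a, b, c, d) {
  # assumes (a, b, c) counter-clockwise; > 0 means d strictly inside
  m <- rbind(c(a[1] - d[1], a[2] - d[2], (a[1] - d[1])^2 + (a[2] - d[2])^2),
             c(b[1] - d[1], b[2] - d[2], (b[1] - d[1])^2 + (b[2] - d[2])^2),
             c(c[1] - d[1], c[2] - d[2], (c[1] - d[1])^2 + (c[2] - d[2])^2))
  det(m)
}

#' Delaunay triangulation of 2D points (Bowyer-Watson)
#'
#' Incremental insertion with a super-triangle. Suited to the moderate
#' sample counts of the stochastic-collocation loop (hundreds of points);
#' tests verify the empty-circumcircle property by brute force.
#'
#' @param pts N x 2 matrix of distinct points, not all collinear.
#' @return M x 3 integer matrix of triangles (1-based, counter-clockwise).
#' @export
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("delaunay_triangulate: need at least 3 points")
  if (anyDuplicated(apply(pts, 1, paste, collapse = "|")))
    stop("delaunay_triangulate: duplicate points")
  # triangulate in range-normalized coordinates: triangle quality (and the
  # empty-circumcircle property) is then independent of the parameter units,
  # which differ by orders of magnitude between grid spacing and penalty
  # weight
  ctr <- colMeans(pts)
  scl <- pmax(apply(pts, 2, function(x) diff(range(x))), 1e-300)
  p <- sweep(sweep(pts, 2, ctr), 2, scl, "/")
  big <- 1e3 # far enough that removing the super-triangle leaves a Delaunay
             # triangulation of the interior, small enough for a well-
             # conditioned incircle predicate
  sup <- rbind(c(0, 3 * big), c(-3 * big, -2 * big), c(3 * big, -2 * big))
  p <- rbind(p, sup)
  si <- n + 1:3
  tris <- matrix(si, 1, 3)
  for (i in seq_len(n)) {
    d <- p[i, ]
    bad <- which(vapply(seq_len(nrow(tris)), function(t) {
      in_circumcircle(p[tris[t, 1], ], p[tris[t, 2], ], p[tris[t, 3], ], d) >
        1e-14
    }, logical(1)))
    if (length(bad) == 0L) {
      # on/outside every circumcircle (degenerate); attach to the triangle
      # whose circumcircle is closest to containing it
      scores <- vapply(seq_len(nrow(tris)), function(t)
        in_circumcircle(p[tris[t, 1], ], p[tris[t, 2], ], p[tris[t, 3], ], d),
        numeric(1))
      bad <- which.max(scores)
    }
    edges <- do.call(rbind, lapply(bad, function(t)
      rbind(tris[t, c(1, 2)], tris[t, c(2, 3)], tris[t, c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    # enforce counter-clockwise orientation
    for (r in seq_len(nrow(newt))) {
      if (orient2d(p[newt[r, 1], ], p[newt[r, 2], ], p[newt[r, 3], ]) < 0)
        newt[r, 1:2] <- newt[r, 2:1]
    }
    tris <- rbind(tris, newt)
  }
  keep <- rowSums(matrix(tris %in% si, nrow(tris))) == 0L
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L)
    stop("delaunay_triangulate: points are collinear (degenerate)")
  unname(tris)
}

# ---------------------------------------------------------------------------
# The simplex-tessellation metamodel

new_tessellation <- function(vertices, values, space) {
  structure(list(vertices = vertices, values = values,
                 triangles = delaunay_triangulate(vertices), space = space),
            class = "simplex_tessellation")
}

#' @export
print.simplex_tessellation <- function(x, ...) {
  cat(sprintf("<simplex_tessellation> %d samples, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Initial stochastic-collocation tessellation
#'
#' Draws `n0` samples from the parameter density, optionally adds the 4
#' domain corners (so the convex hull covers the whole domain and the linear
#' metamodel is defined everywhere), Delaunay-triangulates, and evaluates
#' the quantity of interest at every vertex.
#'
#' @param space a [parameter_space()].
#' @param n0 number of random initial samples (>= 3 when corners are
#'   excluded).
#' @param qoi evaluator `lambda -> scalar`.
#' @param seed RNG seed (deterministic tessellation).
#' @param include_corners add the 4 domain corners (default TRUE).
#' @return An object of class `simplex_tessellation` with fields `vertices`,
#'   `values`, `triangles`, `space`.
#' @export
initial_tessellation <- function(space, n0, qoi, seed = 1L,
                                 include_corners = TRUE) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pts <- space_sample(space, n0)
  if (include_corners) pts <- rbind(space_corners(space), pts)
  # redraw any draw that collides with an existing point
  for (tries in 1:50) {
    dup <- duplicated(apply(pts, 1, paste, collapse = "|"))
    if (!any(dup)) break
    message("initial_tessellation: redrawing ", sum(dup),
            " duplicate sample(s)")
    pts[dup, ] <- space_sample(space, sum(dup))
  }
  vals <- apply(pts, 1, function(l) qoi(l))
  new_tessellation(pts, as.numeric(vals), space)
}

# barycentric coordinates of points w.r.t. one triangle
barycentric <- function(a, b, c, pts) {
  T <- cbind(b - a, c - a)
  dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  rel <- sweep(pts, 2, a)
  l2 <- (rel[, 1] * T[2, 2] - rel[, 2] * T[1, 2]) / dt
  l3 <- (rel[, 2] * T[1, 1] - rel[, 1] * T[2, 1]) / dt
  cbind(1 - l2 - l3, l2, l3)
}

#' Evaluate the piecewise-linear metamodel
#'
#' Barycentric linear interpolation of the vertex QoI values inside the
#' containing triangle. Points outside the convex hull raise an error.
#'
#' @param tess a `simplex_tessellation`.
#' @param lambda a 2-vector or N x 2 matrix of evaluation points.
#' @return numeric vector of interpolated values.
#' @export
metamodel_eval <- function(tess, lambda) {
  pts <- if (is.null(dim(lambda))) matrix(lambda, ncol = 2) else
    as.matrix(lambda)
  out <- rep(NA_real_, nrow(pts))
  todo <- seq_len(nrow(pts))
  for (t in seq_len(nrow(tess$triangles))) {
    if (length(todo) == 0L) break
    tri <- tess$triangles[t, ]
    bc <- barycentric(tess$vertices[tri[1], ], tess$vertices[tri[2], ],
                      tess$vertices[tri[3], ], pts[todo, , drop = FALSE])
    inside <- rowSums(bc < -1e-9) == 0L
    if (any(inside)) {
      sel <- todo[inside]
      out[sel] <- bc[inside, , drop = FALSE] %*% tess$values[tri]
      todo <- todo[!inside]
    }
  }
  if (length(todo))
    stop("metamodel_eval: ", length(todo), " point(s) outside the hull")
  out
}

#' Monte-Carlo estimate of the density-weighted L1 interpolation error
#'
#' Estimates `E[|Q - metamodel|]` under the parameter density by fixed-seed
#' Monte-Carlo quadrature, for analytic/test quantities of interest whose
#' true value is evaluable anywhere.
#'
#' @param tess a `simplex_tessellation`.
#' @param qoi_true evaluator `lambda -> scalar` (vectorized over rows).
#' @param space a [parameter_space()]; defaults to the tessellation's.
#' @param n_mc number of quadrature points (default 10000).
#' @param seed quadrature seed (fixed so errors are comparable across
#'   tessellations).
#' @return scalar error estimate.
#' @export
interpolation_error_l1 <- function(tess, qoi_true, space = tess$space,
                                   n_mc = 10000L, seed = 99L) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pts <- space_sample(space, n_mc)
  truev <- qoi_true(pts)
  if (length(truev) != n_mc)
    truev <- apply(pts, 1, function(l) qoi_true(l))
  mean(abs(truev - metamodel_eval(tess, pts)))
}

#' Estimate the QoI Hessian at a tessellation vertex
#'
#' Weighted least-squares quadratic fit over the `k` nearest samples
#' (Gaussian distance weights, bandwidth = the median neighbour distance),
#' in range-normalized coordinates for conditioning. Exact for quadratic
#' QoIs. The parameter-density weighting of the continuous error model is
#' applied separately (see [optimal_metric()]).
#'
#' @param tess a `simplex_tessellation`.
#' @param vertex vertex index.
#' @param k neighbourhood size (default 10; enlarged, then ridge-regularized
#'   if the fit is rank-deficient).
#' @return 2 x 2 symmetric Hessian matrix (raw parameter units).
#' @export
estimate_qoi_hessian <- function(tess, vertex, k = 10L) {
  pts <- tess$vertices
  n <- nrow(pts)
  if (n < 6L) stop("estimate_qoi_hessian: need at least 6 samples")
  scl <- tess$space$bounds[, 2] - tess$space$bounds[, 1]
  p <- sweep(pts, 2, scl, "/")
  v0 <- p[vertex, ]
  d2 <- (p[, 1] - v0[1])^2 + (p[, 2] - v0[2])^2
  fit_k <- function(k) {
    k <- min(max(k, 6L), n)
    nb <- order(d2)[seq_len(k)]
    u <- p[nb, 1] - v0[1]; v <- p[nb, 2] - v0[2]
    h <- stats::median(sqrt(d2[nb][-1]))
    w <- exp(-d2[nb] / (2 * max(h, 1e-12)^2))
    X <- cbind(1, u, v, u^2, u * v, v^2)
    XtW <- t(X * w)
    A <- XtW %*% X
    list(A = A, b = XtW %*% tess$values[nb])
  }
  f <- fit_k(k)
  co <- tryCatch(solve(f$A, f$b), error = function(e) NULL)
  if (is.null(co)) {
    f <- fit_k(n)
    co <- tryCatch(solve(f$A, f$b), error = function(e) NULL)
    if (is.null(co)) {
      message("estimate_qoi_hessian: rank-deficient neighbourhood at vertex ",
              vertex, "; ridge-regularized")
      co <- solve(f$A + 1e-10 * max(diag(f$A)) * diag(6), f$b)
    }
  }
  Hn <- matrix(c(2 * co[4], co[5], co[5], 2 * co[6]), 2, 2)
  D <- diag(1 / scl)
  D %*% Hn %*% D
}

abs_spd <- function(M, floor = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(abs(e$values), floor)
  e$vectors %*% diag(vals) %*% t(e$vectors)
}

# per-vertex density-weighted absolute Hessians pi(l) * |H(Q)(l)|
weighted_hessian_field <- function(tess, k = 10L, floor = 1e-12) {
  n <- nrow(tess$vertices)
  lapply(seq_len(n), function(i) {
    H <- estimate_qoi_hessian(tess, i, k = k)
    pdf <- space_pdf(tess$space, tess$vertices[i, , drop = FALSE])
    abs_spd(pdf * H, floor = floor)
  })
}

tri_areas <- function(vertices, triangles) {
  vapply(seq_len(nrow(triangles)), function(t) {
    a <- vertices[triangles[t, 1], ]; b <- vertices[triangles[t, 2], ]
    c_ <- vertices[triangles[t, 3], ]
    abs(orient2d(a, b, c_)) / 2
  }, numeric(1))
}

# midpoint (centroid) quadrature of det(A)^expo over the tessellation, with
# A the vertex-averaged weighted Hessian per triangle
hessian_integral <- function(tess, field, expo) {
  total <- 0
  areas <- tri_areas(tess$vertices, tess$triangles)
  for (t in seq_len(nrow(tess$triangles))) {
    tri <- tess$triangles[t, ]
    A <- (field[[tri[1]]] + field[[tri[2]]] + field[[tri[3]]]) / 3
    total <- total + det(A)^expo * areas[t]
  }
  total
}

#' Optimal Riemannian metric for adaptive refinement
#'
#' The closed-form metric field minimizing the continuous interpolation
#' error under a sample-budget constraint (complexity `C`): for parameter
#' dimension `n = 2`,
#' `M(l) = C * I^{-1} * det(pi |H|)^{-1/4} * (pi |H|)(l)` with
#' `I = integral of det(pi |H|)^{1/4}`, where `|H|` is the eigenvalue-wise
#' absolute Hessian of the QoI, floored at 1e-12 for positive-definiteness.
#' The integral uses centroid quadrature over the current tessellation.
#'
#' @param tess a `simplex_tessellation`.
#' @param space a [parameter_space()]; defaults to the tessellation's.
#' @param budget target sample count `C`.
#' @param k Hessian-estimation neighbourhood size.
#' @return list of per-vertex 2 x 2 SPD matrices (class `metric_field`),
#'   with attribute `integral` = `I`.
#' @export
optimal_metric <- function(tess, space = tess$space, budget, k = 10L) {
  field <- weighted_hessian_field(tess, k = k)
  trivial <- all(vapply(field, function(A) max(abs(A)) <= 2e-12, logical(1)))
  if (trivial) {
    warning("optimal_metric: Hessian field is zero everywhere; ",
            "falling back to a uniform isotropic metric")
    m <- budget / space_area(space)
    out <- lapply(seq_len(nrow(tess$vertices)), function(i) m * diag(2))
    attr(out, "integral") <- NA_real_
    class(out) <- "metric_field"
    return(out)
  }
  I <- hessian_integral(tess, field, 1 / 4)
  out <- lapply(field, function(A) {
    M <- budget * I^(-1) * det(A)^(-1 / 4) * A
    (M + t(M)) / 2
  })
  attr(out, "integral") <- I
  class(out) <- "metric_field"
  out
}

#' Optimal-metric error estimate
#'
#' Closed-form estimate of the density-weighted interpolation error
#' attainable with `budget` samples: for `n = 2`,
#' `E = 2 * C^{-1} * (integral of det(pi |H|)^{1/4})^2`, predicting
#' first-order convergence in the sample budget.
#'
#' @param space a [parameter_space()].
#' @param hessian_field list of per-vertex weighted absolute Hessians, or a
#'   `simplex_tessellation` (field estimated from it).
#' @param budget sample budget `C`.
#' @param tess tessellation carrying the quadrature (defaults to
#'   `hessian_field` when that is a tessellation).
#' @return scalar error estimate.
#' @export
error_on_metric <- function(space, hessian_field, budget, tess = NULL) {
  if (inherits(hessian_field, "simplex_tessellation")) {
    tess <- hessian_field
    hessian_field <- weighted_hessian_field(tess)
  }
  if (is.null(tess)) stop("error_on_metric: need a tessellation for quadrature")
  I <- hessian_integral(tess, hessian_field, 1 / 4)
  2 * budget^(-1) * I^2
}

#' Metric-driven tessellation refinement
#'
#' Inserts new vertices at the midpoints of the edges with the greatest
#' metric length `l_M(e) = sqrt(e' M e)` (endpoint-averaged metric), ties
#' broken by lowest vertex index, re-triangulates by Delaunay, and evaluates
#' the QoI at the new vertices only. This is the in-package replacement for
#' an external anisotropic mesh generator: anisotropic, metric-conforming
#' and budget-respecting.
#'
#' @param tess a `simplex_tessellation`.
#' @param metric per-vertex metric field from [optimal_metric()].
#' @param n_new number of vertices to insert (>= 1).
#' @param qoi evaluator `lambda -> scalar`.
#' @param seed RNG seed (only used to perturb degenerate duplicate
#'   insertions).
#' @return the refined `simplex_tessellation`.
#' @export
refine <- function(tess, metric, n_new, qoi, seed = 1L) {
  stopifnot(n_new >= 1L)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tris <- tess$triangles
  edges <- unique(t(apply(rbind(tris[, c(1, 2)], tris[, c(2, 3)],
                                tris[, c(3, 1)]), 1, sort)))
  ev <- tess$vertices[edges[, 2], , drop = FALSE] -
    tess$vertices[edges[, 1], , drop = FALSE]
  elen <- vapply(seq_len(nrow(edges)), function(i) {
    Mbar <- (metric[[edges[i, 1]]] + metric[[edges[i, 2]]]) / 2
    sqrt(drop(ev[i, ] %*% Mbar %*% ev[i, ]))
  }, numeric(1))
  ord <- order(-elen, edges[, 1], edges[, 2])
  existing <- apply(tess$vertices, 1, paste, collapse = "|")
  newpts <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    if (nrow(newpts) >= n_new) break
    mid <- (tess$vertices[edges[i, 1], ] + tess$vertices[edges[i, 2], ]) / 2
    key <- paste(mid, collapse = "|")
    if (key %in% existing || (nrow(newpts) &&
        key %in% apply(newpts, 1, paste, collapse = "|"))) {
      message("refine: perturbing duplicate insertion point")
      mid <- mid + 1e-9 * ev[i, ]
    }
    newpts <- rbind(newpts, mid)
  }
  if (nrow(newpts) < n_new) {
    # fewer edges than requested insertions: recurse on the refined grid
    t2 <- new_tessellation(rbind(tess$vertices, newpts),
                           c(tess$values, apply(newpts, 1, qoi)), tess$space)
    return(refine(t2, c(metric, rep(list(diag(2)), nrow(newpts))),
                  n_new - nrow(newpts), qoi, seed))
  }
  newvals <- apply(newpts, 1, function(l) qoi(l))
  new_tessellation(rbind(tess$vertices, unname(newpts)),
                   c(tess$values, as.numeric(newvals)), tess$space)
}

#' Adaptation configuration
#'
#' @param budget total sample budget (final vertex count never exceeds it).
#' @param n_adap number of adaptation rounds.
#' @param n0 initial random samples (the 4 domain corners are added on top).
#' @param seed RNG seed.
#' @param k Hessian-estimation neighbourhood size.
#' @return An object of class `adapt_config`.
#' @export
adapt_config <- function(budget = 100L, n_adap = 4L, n0 = 12L, seed = 1L,
                         k = 10L) {
  stopifnot(budget >= n0 + 4L, n_adap >= 1L)
  structure(list(budget = as.integer(budget), n_adap = as.integer(n_adap),
                 n0 = as.integer(n0), seed = as.integer(seed),
                 k = as.integer(k)),
            class = "adapt_config")
}

#' Adaptive metamodel construction over the parameter space
#'
#' The full stochastic-collocation loop: initial density-drawn tessellation,
#' then `n_adap` rounds of (Hessian estimation -> optimal metric -> metric-
#' driven refinement), spending the remaining sample budget evenly across
#' rounds. Returns the final metamodel together with the density-weighted
#' mean and variance of the metamodel (its statistical moments, by fixed-
#' seed Monte-Carlo quadrature).
#'
#' @param space a [parameter_space()].
#' @param qoi evaluator `lambda -> scalar`.
#' @param cfg an [adapt_config()].
#' @return list of class `uq_result`: `tessellation`, `mean`, `variance`,
#'   `n_evaluations`, `error_estimate` (the optimal-metric error estimate at
#'   the final budget), `cfg`.
#' @export
adapt <- function(space, qoi, cfg = adapt_config()) {
  qsafe <- function(l) {
    v <- tryCatch(qoi(l), error = function(e) {
      warning("adapt: QoI evaluation failed at (",
              paste(signif(l, 4), collapse = ", "), "): ",
              conditionMessage(e))
      NA_real_
    })
    as.numeric(v)
  }
  tess <- initial_tessellation(space, cfg$n0, qsafe, seed = cfg$seed)
  ok <- is.finite(tess$values)
  if (!all(ok)) tess <- new_tessellation(tess$vertices[ok, , drop = FALSE],
                                         tess$values[ok], space)
  for (l in seq_len(cfg$n_adap)) {
    remaining <- cfg$budget - nrow(tess$vertices)
    if (remaining <= 0L) break
    n_new <- if (l == cfg$n_adap) remaining else
      max(1L, remaining %/% (cfg$n_adap - l + 1L))
    metric <- suppressWarnings(
      optimal_metric(tess, space, budget = cfg$budget, k = cfg$k))
    tess <- refine(tess, metric, n_new, qsafe, seed = cfg$seed + l)
    ok <- is.finite(tess$values)
    if (!all(ok)) tess <- new_tessellation(tess$vertices[ok, , drop = FALSE],
                                           tess$values[ok], space)
  }
  field <- weighted_hessian_field(tess, k = cfg$k)
  err <- tryCatch(
    error_on_metric(space, field, cfg$budget, tess = tess),
    error = function(e) NA_real_)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed + 10000L)
  mc <- space_sample(space, 10000L)
  mv <- metamodel_eval(tess, mc)
  structure(list(tessellation = tess, mean = mean(mv),
                 variance = stats::var(mv),
                 n_evaluations = nrow(tess$vertices),
                 error_estimate = err, cfg = cfg),
            class = "uq_result")
}

#' @export
print.uq_result <- function(x, ...) {
  cat(sprintf(paste0("<uq_result> %d QoI evaluations, metamodel mean %.4g, ",
                     "variance %.4g\n"),
              x$n_evaluations, x$mean, x$variance))
  invisible(x)
}

#' Registration quantity of interest for the UQ loop
#'
#' Builds the plug-in QoI evaluator `lambda = (lambda1, lambda2) -> scalar`
#' that runs the full registration at the given finest grid spacing and
#' penalty weight, morphs the reference organ mesh through the recovered
#' transform, and measures either the point-to-surface accuracy against
#' surface evaluation points (the soft-tissue study) or the node-to-node
#' distance to a reference warped mesh (the bone-based study).
#'
#' @param fixed,moving,fixed_side,moving_side,fixed_landmarks,moving_landmarks
#'   registration inputs (see [register()]).
#' @param organ_mesh reference [tet_mesh()] in the fixed frame.
#' @param base_cfg a [registration_config()] whose `lambda1`/`lambda2` are
#'   overridden per evaluation.
#' @param mode `"surface"` (accuracy against `surface_points`) or
#'   `"node_to_node"` (distance to `reference_mesh`).
#' @param surface_points evaluation points (moving frame) for
#'   `mode = "surface"`.
#' @param reference_mesh reference warped mesh for `mode = "node_to_node"`.
#' @param mask optional precomputed head/neck [mask_volume()].
#' @param organ_mask optional organ mask; when given, the evaluator records
#'   J10% and the selection score as attributes `"j10"` and `"score"`.
#' @return a function `lambda -> scalar` with attribute `"details"`: an
#'   environment accumulating a data frame of (lambda1, lambda2, accuracy,
#'   j10, score) rows across evaluations.
#' @export
registration_qoi <- function(fixed, moving, fixed_side, moving_side,
                             fixed_landmarks, moving_landmarks, organ_mesh,
                             base_cfg = registration_config(),
                             mode = c("surface", "node_to_node"),
                             surface_points = NULL, reference_mesh = NULL,
                             mask = NULL, organ_mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "surface" && is.null(surface_points))
    stop("registration_qoi: surface mode needs surface_points")
  if (mode == "node_to_node" && is.null(reference_mesh))
    stop("registration_qoi: node_to_node mode needs reference_mesh")
  details <- new.env(parent = emptyenv())
  details$rows <- list()
  f <- function(lambda) {
    cfg <- base_cfg
    cfg$lambda1 <- lambda[1]
    cfg$weights <- cost_weights(alpha = cfg$weights$alpha,
                                beta = cfg$weights$beta, lambda2 = lambda[2])
    res <- register(fixed, moving, fixed_side, moving_side,
                    fixed_landmarks, moving_landmarks, cfg, mask = mask)
    warped <- warp_mesh(organ_mesh, res$transform)
    acc <- if (mode == "surface")
      as.numeric(point_to_surface_accuracy(surface_points, warped))
    else as.numeric(node_to_node_accuracy(warped, reference_mesh))
    jq <- if (!is.null(organ_mask)) j10(res$transform, organ_mask) else NA_real_
    details$rows[[length(details$rows) + 1L]] <-
      data.frame(lambda1 = lambda[1], lambda2 = lambda[2], accuracy = acc,
                 j10 = jq,
                 score = if (is.na(jq)) NA_real_ else prediction_score(acc, jq))
    acc
  }
  attr(f, "details") <- details
  f
}
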