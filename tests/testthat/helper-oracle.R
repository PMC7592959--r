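# Independent clearance oracle: dense two-sided boundary sampling with
# exact containment, polished by quasi-Newton minimisation over the
# parametric surfaces.  Deliberately a different numerical route from the
# package's projection-based engine (which it is used to check), so the
# two can only agree if both are right.

oracle_rotmat <- function(rot) {
  t <- rot$angle * pi / 180
  switch(rot$axis,
    none = diag(3),
    y = matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3),
    z = matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  )
}

# Smooth parametric patches covering the boundary of a solid.
# Each block maps (u, v) in [0,1]^2 to a room point; periodic blocks wrap u.
oracle_blocks <- function(s) {
  R <- oracle_rotmat(s$rotation)
  C <- s$scale
  d <- s$translation
  w2r <- function(p) as.vector(R %*% (C * p + d))
  if (s$kind == "box") {
    blocks <- list()
    for (k in 1:3) {
      for (sgn in c(-0.5, 0.5)) {
        o <- setdiff(1:3, k)
        f <- local({
          k0 <- k; s0 <- sgn; o0 <- o
          function(u, v) {
            p <- numeric(3)
            p[k0] <- s0; p[o0[1]] <- u - 0.5; p[o0[2]] <- v - 0.5
            w2r(p)
          }
        })
        blocks[[length(blocks) + 1L]] <- list(f = f, periodic = FALSE)
      }
    }
    blocks
  } else if (s$kind == "cylinder") {
    side <- function(u, v) {
      th <- 2 * pi * (u - floor(u))
      w2r(c(0.5 * cos(th), 0.5 * sin(th), v - 0.5))
    }
    cap <- function(z0) function(u, v) {
      th <- 2 * pi * (u - floor(u))
      w2r(c(0.5 * v * cos(th), 0.5 * v * sin(th), z0))
    }
    list(list(f = side, periodic = TRUE),
         list(f = cap(0.5), periodic = TRUE),
         list(f = cap(-0.5), periodic = TRUE))
  } else {
    f <- function(u, v) {
      th <- 2 * pi * (u - floor(u)); ph <- pi * v
      w2r(0.5 * c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph)))
    }
    list(list(f = f, periodic = TRUE))
  }
}

# Grid-sample every block; keep the parameters of each sample for polishing.
oracle_sample <- function(s, n = 24L) {
  blocks <- oracle_blocks(s)
  u <- seq(0, 1, length.out = n)
  grid <- expand.grid(u = u, v = u)
  pts <- NULL; par <- NULL
  for (bi in seq_along(blocks)) {
    f <- blocks[[bi]]$f
    P <- t(mapply(function(uu, vv) f(uu, vv), grid$u, grid$v))
    pts <- rbind(pts, P)
    par <- rbind(par, cbind(block = bi, u = grid$u, v = grid$v))
  }
  list(pts = pts, par = par, blocks = blocks)
}

# Exact containment written from the local-frame inequalities.
oracle_inside <- function(s, P) {
  W <- sweep(P %*% oracle_rotmat(s$rotation), 2L, s$translation)
  U <- sweep(W, 2L, s$scale, "/")
  switch(s$kind,
    box = abs(U[, 1]) <= 0.5 & abs(U[, 2]) <= 0.5 & abs(U[, 3]) <= 0.5,
    cylinder = U[, 1]^2 + U[, 2]^2 <= 0.25 & abs(U[, 3]) <= 0.5,
    ellipsoid = U[, 1]^2 + U[, 2]^2 + U[, 3]^2 <= 0.25
  )
}

oracle_center <- function(s) as.vector(oracle_rotmat(s$rotation) %*% s$translation)

# Chunked nearest cross-pair search: returns the k best (i, j) candidates.
oracle_nearest_pairs <- function(A, B, k = 4L, chunk = 1024L) {
  nb2 <- rowSums(B^2)
  best <- NULL
  for (i0 in seq(1L, nrow(A), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(A))
    D2 <- outer(rowSums(A[idx, , drop = FALSE]^2), nb2, "+") -
      2 * A[idx, , drop = FALSE] %*% t(B)
    m <- arrayInd(which.min(D2), dim(D2))
    best <- rbind(best, c(idx[m[1]], m[2], D2[m]))
  }
  best <- best[order(best[, 3]), , drop = FALSE]
  best[seq_len(min(k, nrow(best))), , drop = FALSE]
}

oracle_pair_clearance <- function(a, b, n = 24L, k_starts = 4L) {
  A <- oracle_sample(a, n)
  B <- oracle_sample(b, n)
  inter <- any(oracle_inside(b, A$pts)) || any(oracle_inside(a, B$pts)) ||
    oracle_inside(b, rbind(oracle_center(a)))[1] ||
    oracle_inside(a, rbind(oracle_center(b)))[1]
  if (inter) return(list(distance = 0, intersecting = TRUE))
  cand <- oracle_nearest_pairs(A$pts, B$pts, k = k_starts)
  d_best <- sqrt(cand[1, 3])
  for (r in seq_len(nrow(cand))) {
    pa <- A$par[cand[r, 1], ]; pb <- B$par[cand[r, 2], ]
    fa <- A$blocks[[pa[["block"]]]]$f
    fb <- B$blocks[[pb[["block"]]]]$f
    lo <- c(if (A$blocks[[pa[["block"]]]]$periodic) -1 else 0, 0,
            if (B$blocks[[pb[["block"]]]]$periodic) -1 else 0, 0)
    hi <- c(if (A$blocks[[pa[["block"]]]]$periodic) 2 else 1, 1,
            if (B$blocks[[pb[["block"]]]]$periodic) 2 else 1, 1)
    obj <- function(p) sqrt(sum((fa(p[1], p[2]) - fb(p[3], p[4]))^2))
    fit <- tryCatch(
      stats::optim(c(pa[["u"]], pa[["v"]], pb[["u"]], pb[["v"]]), obj,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < d_best) d_best <- fit$value
  }
  list(distance = d_best, intersecting = FALSE)
}
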