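# Multi-scale mean/Gaussian curvature from an oriented point cloud by local
# quadric (Monge patch) fitting in each point's tangent frame.

#' Curvature scale set
#'
#' Five neighborhood radii (Angstrom) spanning 1-10 A, strictly increasing.
#'
#' @param scales Numeric vector of 5 radii.
#' @return Validated numeric vector of class `curvature_scales`.
#' @export
curvature_scales <- function(scales = c(1.0, 2.0, 3.5, 6.0, 10.0)) {
  scales <- as.numeric(scales)
  if (length(scales) != 5L || any(diff(scales) <= 0) ||
      scales[1] < 1 || scales[5] > 10) {
    stop("curvature_scales: need 5 strictly increasing radii within [1, 10] Angstrom",
         call. = FALSE)
  }
  structure(scales, class = "curvature_scales")
}

# Orthonormal tangent basis (e1, e2) for unit normal n.
tangent_basis <- function(n) {
  a <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2)
}

# H and K from a quadratic height fit h(u,v) = c0 + c1 u + c2 v +
# c3 u^2 + c4 uv + c5 v^2 measured along the outward normal. Sign convention:
# convex (sphere exterior, outward normals) => H > 0.
monge_curvature <- function(U, V, Hgt) {
  A <- cbind(1, U, V, U^2, U * V, V^2)
  AtA <- crossprod(A)
  diag(AtA) <- diag(AtA) + 1e-10
  cf <- tryCatch(solve(AtA, crossprod(A, Hgt)), error = function(e) NULL)
  if (is.null(cf)) return(c(0, 0))
  p <- cf[2]; q <- cf[3]; r <- 2 * cf[4]; s <- cf[5]; t <- 2 * cf[6]
  w <- 1 + p^2 + q^2
  Hm <- -(((1 + q^2) * r - 2 * p * q * s + (1 + p^2) * t) / (2 * w^1.5))
  Km <- (r * t - s^2) / w^2
  c(Hm, Km)
}

#' Mean and Gaussian curvature at five scales
#'
#' For every surface point and every scale radius, neighbors within the
#' radius are expressed in the tangent frame of the point's normal and a
#' quadratic height function is fitted by least squares; mean curvature H
#' and Gaussian curvature K follow from the Monge-patch formulas. Convex
#' regions have H > 0 under the outward-normal convention, concave pockets
#' H < 0. Scales with fewer than 6 neighbors (self included) yield 0.
#'
#' @param cloud A [surface_cloud()] with unit normals.
#' @param scales A [curvature_scales()] object (or 5-vector of radii).
#' @return N x 10 matrix ordered H(s1), K(s1), ..., H(s5), K(s5).
#' @export
compute_curvature_features <- function(cloud, scales = curvature_scales()) {
  if (!inherits(scales, "curvature_scales")) scales <- curvature_scales(scales)
  X <- cloud$coords
  Nrm <- cloud$normals
  n <- nrow(X)
  out <- matrix(0, n, 10L)
  smax2 <- max(scales)^2
  # neighbor lists at the largest scale, computed in column blocks
  block <- max(1L, floor(2e7 / n))
  starts <- seq(1L, n, by = block)
  for (b in starts) {
    idx <- b:min(n, b + block - 1L)
    D2 <- pairwise_dist2(X[idx, , drop = FALSE], X)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      d2i <- D2[ii, ]
      nb_all <- which(d2i <= smax2 + 1e-12)
      if (length(nb_all) < 3L) next
      d <- sweep(X[nb_all, , drop = FALSE], 2, X[i, ], "-")
      B <- tangent_basis(Nrm[i, ])
      u <- d %*% B[, 1]; v <- d %*% B[, 2]
      hgt <- d %*% Nrm[i, ]
      d2nb <- d2i[nb_all]
      for (s in seq_len(5L)) {
        sel <- d2nb <= scales[s]^2 + 1e-12
        if (sum(sel) < 6L) next
        out[i, c(2 * s - 1, 2 * s)] <- monge_curvature(u[sel], v[sel], hgt[sel])
      }
    }
  }
  out[!is.finite(out)] <- 0
  out
}
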