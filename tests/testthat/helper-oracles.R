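# Independent brute-force oracles used across the suite.

# Thorpe displacements by explicit stable selection sort (lowest original
# index wins ties), independent of the package's order()-based path.
oracle_displacements <- function(depth, sigma) {
  n <- length(sigma)
  remaining <- seq_len(n)
  disp <- numeric(n)
  for (k in seq_len(n)) {
    m <- remaining[which.min(sigma[remaining])]  # first minimum: stable
    disp[m] <- depth[k] - depth[m]
    remaining <- setdiff(remaining, m)
  }
  disp
}

# OLS slope via explicit normal equations.
oracle_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[2]
}

# Percentile by direct linear interpolation of sorted order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Discrete divergence-theorem oracle: sums, over every cell inside the
# polygon, the outward face transports computed from scratch with the same
# centred face reconstruction (mean u through meridional faces, mean of
# v*cos(lat) through zonal faces, mean concentration). Interior faces cancel
# in exact arithmetic, so this equals the boundary-face sum.
oracle_divergence_sum <- function(C, U, V, lon, lat, inside, H) {
  R <- 6371000; DEG <- pi / 180
  nlon <- length(lon); nlat <- length(lat)
  dlam <- mean(diff(lon)) * DEG
  dphi <- mean(diff(lat)) * DEG
  cosl <- cos(lat * DEG)
  gv <- function(M, i, j) if (i >= 1 && i <= nlon && j >= 1 && j <= nlat)
    M[i, j] else NA_real_
  total_out <- 0
  for (i in seq_len(nlon)) for (j in seq_len(nlat)) {
    if (!inside[i, j]) next
    for (f in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ni <- i + f[1]; nj <- j + f[2]
      cf <- mean(c(C[i, j], gv(C, ni, nj)), na.rm = TRUE)
      if (f[1] != 0) {
        un <- mean(c(U[i, j], gv(U, ni, nj)), na.rm = TRUE)
        tr <- un * R * dphi * f[1]          # outward if f points east(+)/west(-)
      } else {
        vc <- mean(c(V[i, j] * cosl[j],
                     gv(V, ni, nj) * if (nj >= 1 && nj <= nlat)
                       cosl[nj] else NA_real_), na.rm = TRUE)
        tr <- vc * R * dlam * f[2]
      }
      total_out <- total_out + tr * cf * H
    }
  }
  total_out  # umol/s out of the volume
}

# A velocity_field wrapper for hand-built constant/analytic fields.
make_velocity_field <- function(lon, lat, u, v, time = 0) {
  structure(list(lon = lon, lat = lat, time = time,
                 u = if (is.matrix(u)) u else matrix(u, length(lon), length(lat)),
                 v = if (is.matrix(v)) v else matrix(v, length(lon), length(lat))),
            class = "velocity_field")
}

# Random stably-stratified profile with a shuffled segment.
random_permuted_profile <- function(n) {
  depth <- sort(runif(n, 1, 200))
  depth <- depth + seq_len(n) * 1e-6  # guarantee strictly increasing
  sigma <- sort(runif(n, 1023, 1028))
  sigma <- sample(sigma)  # fully permuted
  density_profile(depth, sigma)
}
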