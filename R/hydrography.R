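#' Parameters of the Thorpe-scale mixing method
#'
#' Collects the constants used to turn detected density overturns into a
#' vertical eddy diffusivity. The dissipation of turbulent kinetic energy in a
#' patch is taken as \eqn{\epsilon = (a L_T)^2 N^3} (Ozmidov/Thorpe scaling)
#' and the diffusivity as \eqn{K_z = \Gamma \epsilon / N^2 = \Gamma a^2 L_T^2 N}
#' (Osborn relation).
#'
#' @param gamma mixing efficiency \eqn{\Gamma} (dimensionless, default 0.2).
#' @param ozmidov_ratio Ozmidov-to-Thorpe scale ratio \eqn{a} (default 0.8).
#' @param noise_threshold minimum density range (kg m\eqn{^{-3}}) a patch must
#'   span to be accepted; inversions smaller than this are treated as sensor
#'   noise (default 0.002).
#' @param min_patch_samples minimum number of samples in an accepted patch
#'   (default 3).
#' @param background_kz diffusivity floor (m\eqn{^2} s\eqn{^{-1}}) assigned to
#'   depth bins without overturns, so that geometric means are defined
#'   (default 1e-6).
#' @param g gravitational acceleration, m s\eqn{^{-2}}.
#' @param rho0 reference density, kg m\eqn{^{-3}}.
#' @param despike_k spikes further than `despike_k * noise_threshold` from the
#'   running window median are removed during preprocessing (default 5).
#' @param despike_window window width (samples, odd) of the despiking median
#'   filter (default 5).
#' @param n2_method how the patch buoyancy frequency is computed from the
#'   sorted (statically stable) profile: `"endpoint"` difference over the patch
#'   or a linear `"fit"`.
#'
#' @return An object of class `mixing_params` (a named list).
#' @export
#' @examples
#' mixing_params(gamma = 0.2, ozmidov_ratio = 0.8)
mixing_params <- function(gamma = 0.2, ozmidov_ratio = 0.8,
                          noise_threshold = 0.002, min_patch_samples = 3L,
                          background_kz = 1e-6, g = 9.81, rho0 = 1025,
                          despike_k = 5, despike_window = 5L,
                          n2_method = c("endpoint", "fit")) {
  n2_method <- match.arg(n2_method)
  p <- list(gamma = gamma, ozmidov_ratio = ozmidov_ratio,
            noise_threshold = noise_threshold,
            min_patch_samples = as.integer(min_patch_samples),
            background_kz = background_kz, g = g, rho0 = rho0,
            despike_k = despike_k, despike_window = as.integer(despike_window),
            n2_method = n2_method)
  num <- p[c("gamma", "ozmidov_ratio", "noise_threshold", "min_patch_samples",
             "background_kz", "g", "rho0", "despike_k", "despike_window")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1))))
    stop("all mixing parameters must be single positive finite numbers")
  structure(p, class = "mixing_params")
}

#' Construct a CTD density profile
#'
#' A depth-ordered profile of potential density anomaly (\eqn{\sigma_\theta}).
#' Depth is positive downward throughout the package.
#'
#' @param depth depths, m, positive downward.
#' @param sigma potential density anomaly, kg m\eqn{^{-3}}.
#' @param cast_id identifier for the cast.
#' @param time time stamp (any scalar; ISO-8601 string recommended).
#' @param temperature,salinity optional ancillary columns.
#' @param strict if `TRUE` (default), require strictly increasing depth and at
#'   least 3 finite samples; raw profiles with pressure reversals must be
#'   built with `strict = FALSE` and cleaned with [preprocess_profile()].
#'
#' @return A `density_profile` object (a data frame with attributes).
#' @export
density_profile <- function(depth, sigma, cast_id = "cast", time = NA,
                            temperature = NULL, salinity = NULL,
                            strict = TRUE) {
  if (length(depth) != length(sigma))
    stop("depth and sigma must have equal length")
  d <- data.frame(depth = as.numeric(depth), sigma = as.numeric(sigma))
  if (!is.null(temperature)) d$temperature <- as.numeric(temperature)
  if (!is.null(salinity)) d$salinity <- as.numeric(salinity)
  if (strict) {
    if (nrow(d) < 3L) stop("a density profile needs at least 3 samples")
    if (any(!is.finite(d$sigma)) || any(!is.finite(d$depth)))
      stop("all depth and sigma values must be finite")
    if (any(diff(d$depth) <= 0))
      stop("depth must be strictly increasing; preprocess raw profiles first")
  }
  structure(d, cast_id = cast_id, time = time,
            class = c("density_profile", "data.frame"))
}

#' Clean a raw CTD density profile
#'
#' Removes samples from pressure reversals (depth not exceeding all previous
#' depths), removes single-sample density spikes relative to a running window
#' median, and optionally bin-averages onto a uniform depth grid.
#'
#' @param raw a [density_profile()] (possibly built with `strict = FALSE`) or a
#'   data frame with `depth` and `sigma` columns.
#' @param params a [mixing_params()] object.
#' @param bin_size optional uniform bin width (m); `NULL` (default) keeps the
#'   native sampling.
#'
#' @return A strict, validated `density_profile`.
#' @export
preprocess_profile <- function(raw, params = mixing_params(), bin_size = NULL) {
  depth <- raw$depth
  sigma <- raw$sigma
  ok <- is.finite(depth) & is.finite(sigma)
  depth <- depth[ok]; sigma <- sigma[ok]
  if (length(depth) < 3L) stop("degenerate profile: fewer than 3 valid samples")
  # drop pressure reversals: keep a sample only if deeper than all before it
  keep <- c(TRUE, diff(cummax(depth)) > 0)
  depth <- depth[keep]; sigma <- sigma[keep]
  # despike against a running median
  if (length(sigma) >= params$despike_window) {
    med <- stats::runmed(sigma, params$despike_window, endrule = "median")
    spk <- abs(sigma - med) > params$despike_k * params$noise_threshold
    depth <- depth[!spk]; sigma <- sigma[!spk]
  }
  if (!is.null(bin_size)) {
    bins <- floor(depth / bin_size)
    depth <- tapply(depth, bins, mean)
    sigma <- tapply(sigma, bins, mean)
    o <- order(depth)
    depth <- as.numeric(depth[o]); sigma <- as.numeric(sigma[o])
  }
  if (length(depth) < 3L) stop("degenerate profile: fewer than 3 valid samples")
  density_profile(depth, sigma,
                  cast_id = attr(raw, "cast_id") %||% "cast",
                  time = attr(raw, "time") %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thorpe displacements of a density profile
#'
#' Sorts the profile into gravitational stability (ascending
#' \eqn{\sigma_\theta}, stable sort with index-order tie-breaking, so equal
#' densities produce zero displacement) and returns, for each sample, the
#' depth of the position it occupies after sorting minus its original depth.
#' Displacements sum to zero over the full profile.
#'
#' @param p a preprocessed [density_profile()].
#' @return A data frame with columns `depth` and `displacement` (m), of class
#'   `displacement_profile`.
#' @export
#' @examples
#' p <- density_profile(1:5, c(1025.0, 1025.3, 1025.1, 1025.2, 1025.4))
#' thorpe_displacements(p)$displacement  # 0  2 -1 -1  0
thorpe_displacements <- function(p) {
  n <- nrow(p)
  ord <- order(p$sigma, seq_len(n))  # stable: ties keep original order
  disp <- numeric(n)
  disp[ord] <- p$depth - p$depth[ord]
  structure(data.frame(depth = p$depth, displacement = disp),
            class = c("displacement_profile", "data.frame"))
}

#' Detect density overturns and compute patch mixing parameters
#'
#' Overturning patches are maximal contiguous runs over which the cumulative
#' sum of Thorpe displacements departs from zero and returns to zero. Patches
#' spanning a density range smaller than `noise_threshold`, or with fewer than
#' `min_patch_samples` samples, are rejected as noise. For accepted patches the
#' Thorpe length \eqn{L_T} is the rms displacement, \eqn{N^2} comes from the
#' sorted profile over the patch, \eqn{\epsilon = (a L_T)^2 N^3} and
#' \eqn{K_z = \Gamma a^2 L_T^2 N}.
#'
#' @param d the [thorpe_displacements()] of `p`.
#' @param p the preprocessed [density_profile()].
#' @param params a [mixing_params()] object.
#'
#' @return A data frame of class `overturn_segments` with one row per accepted
#'   patch: `start_depth`, `end_depth`, `n_samples`, `L_T` (m), `N` (1/s),
#'   `epsilon` (m2/s3), `K_z` (m2/s) and `sum_abs_disp` (m, used as a weight
#'   when mapping patches onto depth bins).
#' @export
detect_overturns <- function(d, p, params = mixing_params()) {
  n <- nrow(p)
  cs <- cumsum(d$displacement)
  tol <- 1e-9 * max(abs(p$depth), 1)
  sigma_sorted <- sort(p$sigma)
  out <- list()
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(start) && abs(cs[i]) > tol) start <- i
    if (!is.na(start) && abs(cs[i]) <= tol) {
      out[[length(out) + 1L]] <- c(start, i)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) out[[length(out) + 1L]] <- c(start, n)  # unclosed at end
  segs <- lapply(out, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (j - i + 1L < params$min_patch_samples) return(NULL)
    sig <- p$sigma[i:j]
    if (diff(range(sig)) < params$noise_threshold) return(NULL)
    dz <- p$depth[j] - p$depth[i]
    if (params$n2_method == "endpoint") {
      dsig <- sigma_sorted[j] - sigma_sorted[i]
      n2 <- (params$g / params$rho0) * dsig / dz
    } else {
      ss <- sigma_sorted[i:j]
      zz <- p$depth[i:j]
      slope <- stats::cov(zz, ss) / stats::var(zz)
      n2 <- (params$g / params$rho0) * slope
    }
    if (!is.finite(n2) || n2 <= 0) {
      warning(sprintf("patch %.1f-%.1f m rejected: non-positive N^2",
                      p$depth[i], p$depth[j]))
      return(NULL)
    }
    disp <- d$displacement[i:j]
    lt <- sqrt(mean(disp^2))
    nn <- sqrt(n2)
    eps <- (params$ozmidov_ratio * lt)^2 * nn^3
    kz <- params$gamma * eps / n2
    data.frame(start_depth = p$depth[i], end_depth = p$depth[j],
               n_samples = j - i + 1L, L_T = lt, N = nn,
               epsilon = eps, K_z = kz, sum_abs_disp = sum(abs(disp)))
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  res <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_depth = numeric(0), end_depth = numeric(0),
               n_samples = integer(0), L_T = numeric(0), N = numeric(0),
               epsilon = numeric(0), K_z = numeric(0),
               sum_abs_disp = numeric(0))
  structure(res, class = c("overturn_segments", "data.frame"))
}

#' Map patch diffusivities onto a uniform depth-bin grid for one cast
#'
#' Bins overlapped by one or more overturning patches carry the patch
#' \eqn{K_z} (a displacement-weighted mean when several patches overlap a
#' bin); all other bins carry the background diffusivity floor.
#'
#' @param segments an `overturn_segments` data frame from [detect_overturns()].
#' @param depth_bins numeric vector of uniform bin edges (m), length >= 2.
#' @param params a [mixing_params()] object.
#'
#' @return A data frame `depth_top`, `depth_bottom`, `kz` with one row per bin.
#' @export
cast_kz_profile <- function(segments, depth_bins, params = mixing_params()) {
  if (length(depth_bins) < 2L) stop("need at least two bin edges")
  w <- diff(depth_bins)
  if (max(abs(w - w[1])) > 1e-9 * w[1]) stop("depth_bins must be uniform")
  top <- depth_bins[-length(depth_bins)]
  bottom <- depth_bins[-1]
  kz <- rep(params$background_kz, length(top))
  if (nrow(segments)) {
    for (b in seq_along(top)) {
      ov <- segments$start_depth < bottom[b] & segments$end_depth > top[b]
      if (any(ov)) {
        kz[b] <- stats::weighted.mean(segments$K_z[ov],
                                      segments$sum_abs_disp[ov])
        kz[b] <- max(kz[b], params$background_kz)
      }
    }
  }
  data.frame(depth_top = top, depth_bottom = bottom, kz = kz)
}

#' Average per-cast diffusivity profiles with the geometric mean
#'
#' Diffusivity is approximately log-normally distributed across casts, so
#' profiles from repeated casts of a Lagrangian experiment are combined with
#' the per-bin geometric mean.
#'
#' @param cast_profiles a list of per-cast profiles from [cast_kz_profile()],
#'   all sharing the same depth bins.
#' @return A data frame of class `diffusivity_profile` with columns
#'   `depth_top`, `depth_bottom`, `kz_geomean`, `n_casts`.
#' @export
average_kz <- function(cast_profiles) {
  if (!length(cast_profiles)) stop("no cast profiles supplied")
  ref <- cast_profiles[[1]]
  for (cp in cast_profiles)
    if (nrow(cp) != nrow(ref) ||
        max(abs(cp$depth_top - ref$depth_top)) > 1e-9)
      stop("all cast profiles must share the same depth bins")
  m <- vapply(cast_profiles, function(cp) log(cp$kz), numeric(nrow(ref)))
  m <- matrix(m, nrow = nrow(ref))
  structure(data.frame(depth_top = ref$depth_top,
                       depth_bottom = ref$depth_bottom,
                       kz_geomean = exp(rowMeans(m)),
                       n_casts = length(cast_profiles)),
            class = c("diffusivity_profile", "data.frame"))
}

#' Thorpe-scale diffusivity from a set of raw casts
#'
#' Convenience wrapper: preprocess each cast, compute displacements, detect
#' overturns, map onto depth bins and geometric-mean across casts.
#'
#' @param casts a list of raw [density_profile()] objects.
#' @param depth_bins uniform bin edges (m).
#' @param params a [mixing_params()] object.
#' @return A `diffusivity_profile` (see [average_kz()]); the per-cast segment
#'   tables are attached as attribute `"segments"`.
#' @export
thorpe_kz <- function(casts, depth_bins, params = mixing_params()) {
  segs <- list()
  profs <- lapply(seq_along(casts), function(k) {
    p <- preprocess_profile(casts[[k]], params)
    d <- thorpe_displacements(p)
    s <- detect_overturns(d, p, params)
    segs[[k]] <<- s
    cast_kz_profile(s, depth_bins, params)
  })
  out <- average_kz(profs)
  attr(out, "segments") <- segs
  out
}
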