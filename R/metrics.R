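#' Occupancy-normalised rate map
#'
#' Bins a per-step activity series over the arena, divides by occupancy, and
#' applies NA-aware Gaussian smoothing.  Bins never visited are `NA` and are
#' excluded from all downstream correlations.
#'
#' @param x,y Positions (a.u.).
#' @param activity Aligned activity/spike series.
#' @param L Arena side length.
#' @param bin_size Bin size in a.u. (default 2.5, i.e. 40 x 40 bins).
#' @param smooth_sd Gaussian smoothing width in bins (default 1; 0 = none).
#' @return Object of class `rate_map`: list with `rate` (matrix, x indexes
#'   rows), `counts`, `bin_size`, `L`.
#' @export
rate_map <- function(x, y, activity, L, bin_size = 2.5, smooth_sd = 1) {
  if (length(x) == 0) stop("empty trajectory")
  stopifnot(length(x) == length(y), length(x) == length(activity))
  nb <- as.integer(round(L / bin_size))
  ix <- pmin(pmax(floor(x / bin_size) + 1, 1), nb)
  iy <- pmin(pmax(floor(y / bin_size) + 1, 1), nb)
  idx <- ix + nb * (iy - 1)
  counts <- matrix(tabulate(idx, nb * nb), nb, nb)
  sums <- matrix(0, nb, nb)
  agg <- rowsum(activity, idx)
  sums[as.integer(rownames(agg))] <- agg
  rate <- sums / counts
  rate[counts == 0] <- NA
  if (smooth_sd > 0) rate <- smooth_na(rate, smooth_sd)
  structure(list(rate = rate, counts = counts, bin_size = bin_size, L = L),
            class = "rate_map")
}

# NA-aware (normalised-convolution) Gaussian smoothing
smooth_na <- function(m, sd_bins) {
  r <- max(1L, ceiling(3 * sd_bins))
  k <- outer(stats::dnorm(-r:r, sd = sd_bins),
             stats::dnorm(-r:r, sd = sd_bins))
  valid <- is.finite(m)
  m0 <- ifelse(valid, m, 0)
  num <- conv2d(m0, k); den <- conv2d(valid + 0, k)
  out <- num / den
  out[!valid] <- NA
  out
}

conv2d <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- (nrow(k) - 1L) / 2L
  pr <- nr + 2L * kr; pc <- nc + 2L * kr
  mp <- matrix(0, pr, pc)
  mp[(kr + 1):(kr + nr), (kr + 1):(kr + nc)] <- m
  kp <- matrix(0, pr, pc)
  kp[1:nrow(k), 1:ncol(k)] <- k
  f <- stats::fft(stats::fft(mp) * stats::fft(kp), inverse = TRUE)
  Re(f)[(2 * kr + 1):(2 * kr + nr), (2 * kr + 1):(2 * kr + nc)] / (pr * pc)
}

#' Spatial autocorrelogram of a rate map
#'
#' Lag-wise Pearson correlation of the map with itself over the overlapping
#' valid bins, computed for all lags up to the map size.  Lags with fewer
#' than `min_overlap` overlapping bins are `NA`.  The surface is 1 at zero
#' lag and centro-symmetric.
#'
#' @param map A [rate_map()] or a plain matrix (NA = missing).
#' @param min_overlap Minimum overlapping bins per lag (default 20).
#' @return `(2n-1) x (2n-1)` correlation matrix (class `autocorr`).
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  m <- if (inherits(map, "rate_map")) map$rate else map
  valid <- is.finite(m)
  if (sum(valid) < 2) stop("need at least 2 valid bins")
  nr <- nrow(m); nc <- ncol(m)
  M <- valid + 0
  X <- ifelse(valid, m, 0)
  pr <- 2L * nr; pc <- 2L * nc
  pad <- function(a) { p <- matrix(0, pr, pc); p[1:nr, 1:nc] <- a; p }
  fM <- stats::fft(pad(M)); fX <- stats::fft(pad(X)); fX2 <- stats::fft(pad(X^2))
  cc <- function(fa, fb) # sum_s a(s) b(s + d)
    Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
  wrap <- function(a) {
    # assemble full lag range -(nr-1)..(nr-1) from the circular correlation
    out <- matrix(NA_real_, 2 * nr - 1, 2 * nc - 1)
    iu <- c((pr - nr + 2):pr, 1:nr)   # lags -(nr-1)..(nr-1)
    iv <- c((pc - nc + 2):pc, 1:nc)
    out[] <- a[iu, iv]
    out
  }
  nn <- wrap(cc(fM, fM)); nn <- round(nn)
  Sx <- wrap(cc(fX, fM)); Sy <- wrap(cc(fM, fX))
  Sxy <- wrap(cc(fX, fX))
  Sxx <- wrap(cc(fX2, fM)); Syy <- wrap(cc(fM, fX2))
  vx <- nn * Sxx - Sx^2; vy <- nn * Syy - Sy^2
  vx[vx < 0] <- 0; vy[vy < 0] <- 0
  r <- (nn * Sxy - Sx * Sy) / sqrt(vx * vy)
  r[nn < min_overlap | vx <= 1e-12 | vy <= 1e-12] <- NA
  r <- pmin(pmax(r, -1), 1)
  structure(r, class = c("autocorr", "matrix"))
}

# local maxima (8-neighbour) of the autocorrelogram, excluding the center
autocorr_peaks <- function(ac, exclude_radius = 2) {
  a <- unclass(ac)
  nr <- nrow(a); nc <- ncol(a)
  a0 <- ifelse(is.finite(a), a, -Inf)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  res <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- a0[i, j]
    if (!is.finite(v) || v <= 0) next
    nb <- a0[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v < max(nb)) next
    if (sum(nb == v) > 1 && which.max(nb) != 5) next  # plateau tie-break
    d <- sqrt((i - ctr[1])^2 + (j - ctr[2])^2)
    if (d <= exclude_radius) next
    res <- rbind(res, c(i = i, j = j, dist = d, value = v))
  }
  res
}

# ring crop + polar resampling + rotational Pearson correlations.
# The annulus is sampled on a polar grid (2.5 deg steps) so that a rotation
# is an exact circular shift of the angular samples.
ring_correlations <- function(ac, angles) {
  pk <- autocorr_peaks(ac)
  if (is.null(pk) || nrow(pk) == 0) return(NULL)
  pk <- pk[order(pk[, "dist"]), , drop = FALSE]
  near <- pk[seq_len(min(6, nrow(pk))), , drop = FALSE]
  r_in <- 0.5 * min(near[, "dist"])
  r_out <- min(1.25 * mean(near[, "dist"]),
               (min(dim(ac)) - 1) / 2)
  if (r_out <= r_in) return(NULL)
  a <- unclass(ac)
  ctr <- c((nrow(a) + 1) / 2, (ncol(a) + 1) / 2)
  nth <- 144L                       # 2.5 degree angular step
  radii <- seq(r_in, r_out, length.out = max(8L, ceiling(r_out - r_in) + 1L))
  th <- 2 * pi * (0:(nth - 1)) / nth
  px <- ctr[1] + outer(radii, cos(th))
  py <- ctr[2] + outer(radii, sin(th))
  vals <- matrix(bilinear_na(a, px, py), length(radii), nth)
  sapply(angles, function(ang) {
    k <- as.integer(round(ang / (360 / nth)))
    rot <- vals[, ((seq_len(nth) - 1 + k) %% nth) + 1, drop = FALSE]
    ok <- is.finite(vals) & is.finite(rot)
    if (sum(ok) < 8) return(NA_real_)
    v1 <- vals[ok]; v2 <- rot[ok]
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
    stats::cor(v1, v2)
  })
}

bilinear_na <- function(a, px, py) {
  nr <- nrow(a); nc <- ncol(a)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  get <- function(i, j) {
    out <- rep(NA_real_, length(i))
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out[ok] <- a[cbind(i[ok], j[ok])]
    out
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Hexagonal and square gridness scores
#'
#' An annulus is cropped from the autocorrelogram (inner radius half the
#' nearest-peak distance, outer radius 1.25 x the mean distance of the six
#' peaks closest to the center) and correlated with rotated copies of itself.
#' Hexagonal score: `1/2 (C60 + C120) - 1/3 (C30 + C90 + C150)`; square
#' score: `C90 - 1/2 (C45 + C135)`.  `NA` when no peaks are detectable.
#'
#' @param ac An [autocorrelogram()].
#' @return Scalar score (nominal range `[-2, 2]`).
#' @export
gridness_hex <- function(ac) {
  gridness_combine_hex(ring_correlations(ac, c(30, 60, 90, 120, 150)))
}

#' @rdname gridness_hex
#' @export
gridness_square <- function(ac) {
  gridness_combine_square(ring_correlations(ac, c(45, 90, 135)))
}

# score combiners; identically zero whenever all correlations are equal
gridness_combine_hex <- function(C) {
  if (is.null(C) || anyNA(C)) return(NA_real_)
  0.5 * (C[2] + C[4]) - (C[1] + C[3] + C[5]) / 3
}
gridness_combine_square <- function(C) {
  if (is.null(C) || anyNA(C)) return(NA_real_)
  C[2] - 0.5 * (C[1] + C[3])
}

#' Entropy suite of a place-field event distribution
#'
#' Shannon entropy `H = -sum p_i log p_i` of the per-cell event probabilities,
#' its maximum `log n`, the entropy ratio H/log(n), complexity ratio
#' `R = 1 - r`, information difference `I = log n - H`, and the decomposition
#' `H = S + Z` into spatial entropy `S = -sum p_i log(p_i / dx_i)` and
#' information density `Z = -sum p_i log dx_i` for event sizes `dx_i`
#' (default 20 a.u., fixed across simulations).
#'
#' @param p Probability vector (must sum to 1; `0 log 0 = 0`).
#' @param dx Event size(s), scalar or per-event.
#' @param base Logarithm base (default natural log).
#' @return List `H, H_max, r, R, I, S, Z, n`.
#' @export
entropy_suite <- function(p, dx = 20, base = exp(1)) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  lg <- function(x) log(x, base = base)
  n <- length(p)
  dx <- rep_len(dx, n)
  if (any(dx <= 0)) stop("event sizes must be positive")
  pos <- p > 0
  H <- -sum(p[pos] * lg(p[pos]))
  S <- -sum(p[pos] * lg(p[pos] / dx[pos]))
  Z <- -sum(p[pos] * lg(dx[pos]))
  Hmax <- lg(n)
  list(H = H, H_max = Hmax, r = if (n > 1) H / Hmax else 1,
       R = if (n > 1) 1 - H / Hmax else 0, I = Hmax - H, S = S, Z = Z, n = n)
}

#' Cross-entropy measures between an event and a reference distribution
#'
#' `H(p) = -sum p_i log q_i` (evenness of `p` against the reference density
#' `q`), `H(q) = -sum q_i log q_i`, their difference `H(p/q) = H(q) - H(p)`,
#' and the information difference `I = sum p_i log(p_i / q_i)`.  When `p = q`
#' the difference vanishes.
#'
#' @param p,q Probability vectors (`q_i > 0` wherever `p_i > 0`).
#' @param base Logarithm base.
#' @return List `Hp, Hq, Hpq, I`.
#' @export
cross_entropy_measures <- function(p, q, base = exp(1)) {
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("distributions must sum to 1")
  if (any(p > 0 & q <= 0)) stop("q must be positive on the support of p")
  lg <- function(x) log(x, base = base)
  pos <- p > 0
  Hp <- -sum(p[pos] * lg(q[pos]))
  qp <- q > 0
  Hq <- -sum(q[qp] * lg(q[qp]))
  list(Hp = Hp, Hq = Hq, Hpq = Hq - Hp,
       I = sum(p[pos] * lg(p[pos] / q[pos])))
}

#' Position-error summaries across grid modules
#'
#' Per-module Euclidean error series against the true trajectory, the
#' cross-module variance and spread (`E = sqrt(sd_x^2 + sd_y^2)`, sample sd)
#' series, and per-module error means over `n_bins` time bins.
#'
#' @param estimates List of steps x 2 per-module estimates.
#' @param truth Steps x 2 true positions.
#' @param n_bins Number of time bins for the binned means (default 100).
#' @return List `error` (steps x modules), `E_error`, `variance` (steps),
#'   `binned` (data frame `bin, module, mean_error`).
#' @export
error_summaries <- function(estimates, truth, n_bins = 100) {
  truth <- as.matrix(truth)
  n <- nrow(truth)
  if (any(vapply(estimates, nrow, 0L) != n))
    stop("estimate series and trajectory lengths differ")
  nm <- length(estimates)
  err <- vapply(estimates, function(e)
    sqrt(rowSums((e - truth)^2)), numeric(n))
  ex <- vapply(estimates, function(e) e[, 1], numeric(n))
  ey <- vapply(estimates, function(e) e[, 2], numeric(n))
  vx <- apply(ex, 1, stats::var); vy <- apply(ey, 1, stats::var)
  bins <- pmin(n_bins, n)
  bin_id <- ceiling(seq_len(n) / n * bins)
  binned <- do.call(rbind, lapply(seq_len(nm), function(m)
    data.frame(bin = seq_len(bins), module = m,
               mean_error = as.numeric(tapply(err[, m], bin_id, mean)))))
  list(error = err, E_error = sqrt(vx + vy), variance = vx + vy,
       binned = binned)
}
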