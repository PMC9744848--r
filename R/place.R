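#' Initial sensor-to-place-cell weights
#'
#' Weights are drawn as `w = (1 + exp((gamma - E(gamma)) / (2 sigma^2)))^-1`
#' with `gamma ~ U(0, 1)` and `E(gamma) = 0.5`, which spreads initial
#' preferences over the whole arena (fields can emerge both near and far from
#' the walls).  The distribution is symmetric about 0.5 and confined to (0, 1).
#'
#' @param n Number of draws.
#' @param sigma Shape parameter of the initialisation logistic (default
#'   0.25; preferences span the whole arena, walls included).
#' @return Numeric vector in (0, 1). Uses the current R random stream.
#' @export
weight_init <- function(n, sigma = 0.25) {
  gam <- stats::runif(n)
  1 / (1 + exp((gam - 0.5) / (2 * sigma^2)))
}

#' Construct the place-cell network
#'
#' `N_pc` place cells receive the `N_s = 3` proximity sensors through a weight
#' matrix, carry their own Hodgkin-Huxley unit, a per-cell spike energy
#' `C ~ N(188, 10)` nJ, tuning width `sigma_j ~ N(0.03, 0.005)`, and two
#' preferred visual-blob feature sets M1, M2 (area, orientation, solidity,
#' centroid) drawn uniformly over each feature's range.
#'
#' @param n_cells Number of place cells (default 2000).
#' @param n_sensors Number of proximity sensors (default 3).
#' @param seed Integer seed for all initial draws.
#' @param R_m Maximum firing rate, Hz (default 20).
#' @param P_thr Firing-power threshold (default 0.3).
#' @param mu Competitive learning rate (default 0.001).
#' @param sigma_init Weight-initialisation shape parameter (default 0.25).
#' @return An object of class `place_network`.
#' @export
place_network <- function(n_cells = 2000, n_sensors = 3, seed = 1L,
                          R_m = 20, P_thr = 0.3, mu = 0.001,
                          sigma_init = 0.25) {
  stopifnot(n_cells >= 1, n_sensors >= 1, R_m > 0, P_thr > 0, mu > 0)
  net <- with_seed(seed, {
    W <- matrix(weight_init(n_sensors * n_cells, sigma_init),
                nrow = n_sensors, ncol = n_cells)
    C <- stats::rnorm(n_cells, 188, 10)
    sigma_j <- pmax(1e-3, stats::rnorm(n_cells, 0.03, 0.005))
    feat_lo <- c(area = 0, orientation = 0, solidity = 0.3, cu = 0, cv = 0)
    feat_hi <- c(area = 1, orientation = pi, solidity = 1, cu = 1, cv = 1)
    rand_feats <- function() {
      m <- matrix(stats::runif(n_cells * 5), n_cells, 5)
      sweep(sweep(m, 2, feat_hi - feat_lo, "*"), 2, feat_lo, "+")
    }
    list(W = W, C = C, sigma_j = sigma_j, M1 = rand_feats(),
         M2 = rand_feats(), V0 = stats::runif(n_cells, -75, -55))
  })
  net$n_cells <- n_cells; net$n_sensors <- n_sensors
  net$R_m <- R_m; net$P_thr <- P_thr; net$mu <- mu
  # random initial potentials spread the H-H limit-cycle phases across cells
  net$hh <- list(V = net$V0, m = rep(0.5, n_cells),
                 h = rep(0.06, n_cells), n = rep(0.5, n_cells))
  colnames(net$M1) <- colnames(net$M2) <-
    c("area", "orientation", "solidity", "cu", "cv")
  class(net) <- "place_network"
  net
}

#' @export
print.place_network <- function(x, ...) {
  cat(sprintf("<place_network> %d cells, %d sensors, R_m=%g Hz, P_thr=%g\n",
              x$n_cells, x$n_sensors, x$R_m, x$P_thr))
  invisible(x)
}

#' Proximity-driven firing power of the place cells
#'
#' `P_j = C_j R_m exp(-((1/n)||X'/L - w_j||)^2 / (2 sigma_j^2))`, where `n` is
#' the number of sensory inputs and `w_j` the cell's sensor weight vector.
#' Maximal (`C_j R_m`) exactly when the normalised sensor vector matches the
#' weights.
#'
#' @param net A [place_network()] (or a list with `W`, `C`, `sigma_j`, `R_m`).
#' @param X_noisy Length-`n_sensors` noisy sensor reading.
#' @param L Arena side length.
#' @return Per-cell firing power (nonnegative).
#' @export
firing_power <- function(net, X_noisy, L) {
  d2 <- colSums((X_noisy / L - net$W)^2)
  n <- nrow(net$W)
  net$C * net$R_m * exp(-(d2 / n^2) / (2 * net$sigma_j^2))
}

#' Competitive update of sensor weights
#'
#' For the responding set `J`, `w_j <- w_j + mu (X'/L - w_j)`; other weights
#' are untouched.  Repeated updates under a constant input contract
#' geometrically (ratio `1 - mu`) to `X'/L`.
#'
#' @param net A [place_network()].
#' @param X_noisy Noisy sensor reading.
#' @param L Arena side.
#' @param J Integer (or logical) index of responding cells.
#' @return The updated network.
#' @export
competitive_update <- function(net, X_noisy, L, J) {
  if (length(J) == 0) return(net)
  x <- X_noisy / L
  net$W[, J] <- net$W[, J] + net$mu * (x - net$W[, J])
  net
}

#' Gaussian feature similarity
#'
#' `G(x, mu, sigma) = exp(-((x - mu)/sigma)^2)`, in (0, 1], equal to 1 iff
#' `x = mu`.  The sensitivity parameter `sigma_f` is 0.5 for all features.
#'
#' @param x_f,mu_f Feature value and preferred value.
#' @param sigma_f Sensitivity (default 0.5).
#' @export
feature_similarity <- function(x_f, mu_f, sigma_f = 0.5) {
  stopifnot(sigma_f > 0)
  exp(-((x_f - mu_f) / sigma_f)^2)
}

# Squared feature distance of each blob to each cell's preferred set
# (cells x blobs).  The centroid counts as one 2-D feature.
blob_match_matrix <- function(blobs, M, sigma_f = 0.5) {
  nb <- nrow(blobs)
  out <- matrix(0, nrow(M), nb)
  for (b in seq_len(nb)) {
    d2 <- (M[, "area"] - blobs$area[b])^2 +
      (M[, "orientation"] - blobs$orientation[b])^2 +
      (M[, "solidity"] - blobs$solidity[b])^2 +
      (M[, "cu"] - blobs$cu[b])^2 + (M[, "cv"] - blobs$cv[b])^2
    out[, b] <- exp(-d2 / sigma_f^2)
  }
  out
}

#' Conjunctive two-blob activation of the place cells
#'
#' Each cell holds two preferred feature sets M1 and M2.  Its response to blob
#' `B_i` is the product of Gaussian feature similarities over area,
#' orientation, solidity and (2-D) centroid; the activation is the best
#' ordered pair of distinct blobs, `A = max_i A1_i * max_{j != i} A2_j`.
#' Fewer than two visible blobs give `A = 0` for every cell.
#'
#' @param blobs Data frame from [generate_blobs()].
#' @param net A [place_network()] (uses `M1`, `M2`), or a list with `M1`,`M2`
#'   single-row matrices for one cell.
#' @param sigma_f Feature sensitivity (default 0.5).
#' @return List: `A` (per-cell activation in `[0, 1]`), `best1`, `best2`
#'   (per-cell indices of the winning blob pair, NA when `A = 0`).
#' @export
place_activation <- function(blobs, net, sigma_f = 0.5) {
  nc <- nrow(net$M1)
  if (is.null(nc)) stop("net$M1 must be a matrix (cells x features)")
  if (nrow(blobs) < 2)
    return(list(A = numeric(nc), best1 = rep(NA_integer_, nc),
                best2 = rep(NA_integer_, nc)))
  A1 <- blob_match_matrix(blobs, net$M1, sigma_f)
  A2 <- blob_match_matrix(blobs, net$M2, sigma_f)
  nb <- ncol(A1)
  i2max <- max.col(A2, ties.method = "first")
  a2max <- A2[cbind(seq_len(nc), i2max)]
  A2s <- A2; A2s[cbind(seq_len(nc), i2max)] <- -Inf
  i2sec <- max.col(A2s, ties.method = "first")
  a2sec <- A2[cbind(seq_len(nc), i2sec)]
  best <- rep(-Inf, nc); b1 <- b2 <- integer(nc)
  for (b in seq_len(nb)) {
    sel <- i2max == b
    other <- a2max; other[sel] <- a2sec[sel]
    oidx <- i2max; oidx[sel] <- i2sec[sel]
    cand <- A1[, b] * other
    upd <- cand > best
    best[upd] <- cand[upd]; b1[upd] <- b; b2[upd] <- oidx[upd]
  }
  list(A = best, best1 = b1, best2 = b2)
}

#' Adapt a winning cell's preferred features towards the observed blob pair
#'
#' Winner-take-all competitive adaptation: each preferred feature value moves
#' as a convex combination `mu_f <- alpha x_f + (1 - alpha) mu_f`
#' (`alpha = 0.5`), so repeated exposure to the same pair converges on it.
#'
#' @param M 1 x 5 (or n x 5) matrix of preferred features.
#' @param x Observed blob feature vector (same layout).
#' @param alpha_adapt Adaptation rate in (0, 1] (default 0.5).
#' @return Updated matrix.
#' @export
adapt_feature_centers <- function(M, x, alpha_adapt = 0.5) {
  stopifnot(alpha_adapt > 0, alpha_adapt <= 1)
  alpha_adapt * x + (1 - alpha_adapt) * M
}

blob_feature_vector <- function(blobs, i) {
  c(area = blobs$area[i], orientation = blobs$orientation[i],
    solidity = blobs$solidity[i], cu = blobs$cu[i], cv = blobs$cv[i])
}

#' Power-weighted place-field center
#'
#' Discrete form of the field-center integral: the firing-power-weighted
#' centroid of the (noisy) positions at which the cell responded.
#'
#' @param P Vector of firing powers (at least one positive).
#' @param X n x 2 matrix of the corresponding positions.
#' @return Length-2 center.
#' @export
field_center <- function(P, X) {
  X <- rbind(X)
  if (length(P) == 0 || sum(P) <= 0)
    stop("field center undefined: no positive firing power")
  colSums(X * P) / sum(P)
}

#' Decode the animal's location from the place population
#'
#' `Loc(t) = sum_J P_j C_j / sum_J P_j` over the responding set
#' `J = {j : P_j > P_thr}` restricted to cells with a defined field center.
#' The normalised decoding error is `||Loc - pos|| / (L / sqrt(2))`, clipped
#' to `[0, 1]`, so that unselective population activity (Loc pinned near the
#' arena center regardless of position) produces errors of order 1.
#'
#' @param P Per-cell firing power.
#' @param centers n x 2 matrix of field centers (NA rows = no field).
#' @param pos True position (for the error; may be NULL).
#' @param L Arena side.
#' @param P_thr Response threshold.
#' @return List `loc` (length 2, NA when no responder) and `err_norm`
#'   (1 when no estimate is available).
#' @export
decode_location <- function(P, centers, pos = NULL, L = 100, P_thr = 0.3) {
  ok <- which(P > P_thr & is.finite(centers[, 1]))
  if (length(ok) == 0)
    return(list(loc = c(NA_real_, NA_real_), err_norm = 1))
  w <- P[ok]
  loc <- colSums(centers[ok, , drop = FALSE] * w) / sum(w)
  err <- if (is.null(pos)) NA_real_ else
    min(1, sqrt(sum((loc - pos)^2)) / (L / sqrt(2)))
  list(loc = loc, err_norm = err)
}
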