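# Independent oracles used to cross-check the implementation.  These are
# deliberately written from the underlying definitions, not by calling the
# package's own code paths.

# Weighted least-squares Fourier coefficients via the normal equations
# (A'A) p = A' b -- an independent linear solve, no SVD.
oracle_wls_fourier <- function(theta, y, sigma, order) {
  w <- 2 * pi / 360
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(i) {
    cbind(cos(i * w * theta), sin(i * w * theta))
  })))
  A <- X / sigma
  b <- y / sigma
  solve(crossprod(A), crossprod(A, b))[, 1]
}

# Direct wrapped-Gaussian summation from the definition (9 wrap terms on the
# already-wrapped offset).
oracle_wg <- function(theta, a, b, c, d, N = 4) {
  vapply(theta, function(t) {
    delta <- ((t - c + 180) %% 360) - 180
    d + a * sum(exp(-0.5 * ((delta + 360 * (-N:N)) / b)^2))
  }, 0)
}

# Regularized upper incomplete gamma via numerical quadrature.
oracle_gamma_Q <- function(shape, x) {
  stats::integrate(function(t) t^(shape - 1) * exp(-t), lower = x,
                   upper = Inf, rel.tol = 1e-10)$value / gamma(shape)
}

# Exact two-group Kruskal-Wallis p-value by enumerating every assignment of
# the pooled observations to the two groups.
oracle_kw_exact <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled); na <- length(a)
  r <- rank(pooled)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H_of <- function(idx) {
    Ra <- sum(r[idx]); Rb <- sum(r) - Ra
    (12 / (N * (N + 1)) * (Ra^2 / na + Rb^2 / (N - na)) - 3 * (N + 1)) / C
  }
  H_obs <- H_of(seq_len(na))
  sets <- utils::combn(N, na)
  H_all <- apply(sets, 2, H_of)
  mean(H_all >= H_obs - 1e-10)
}

# Exact two-sample Kolmogorov-Smirnov tail P(D >= d_obs) by lattice-path
# counting: paths from (0,0) to (n,m) staying strictly inside the band
# |i/n - j/m| < d_obs correspond to orderings with D < d_obs.
oracle_ks_exact <- function(n, m, d_obs) {
  cnt <- matrix(0, n + 1, m + 1)
  cnt[1, 1] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      if (abs(i / n - j / m) >= d_obs - 1e-12) { cnt[i + 1, j + 1] <- 0; next }
      up <- if (i > 0) cnt[i, j + 1] else 0
      rt <- if (j > 0) cnt[i + 1, j] else 0
      cnt[i + 1, j + 1] <- up + rt
    }
  }
  1 - cnt[n + 1, m + 1] / choose(n + m, n)
}

# Exhaustive-scan feature oracle: re-derives the positional features of a
# sampled curve by brute-force index scans.
oracle_scan_features <- function(theta, v, modality) {
  n <- length(theta)
  res <- 360 / n
  out <- list()
  gmin <- v[1]; gmax <- v[1]
  for (x in v) { if (x < gmin) gmin <- x; if (x > gmax) gmax <- x }
  out$GlobalMinimum <- gmin
  out$GlobalMaximum <- gmax
  gma <- min(theta[v == gmin])
  out$GlobalMinimumAngle <- if (gma > 240) gma - 360 else gma
  band <- function(peak_i, ptp) {
    sapply(c(25, 50, 75), function(X) {
      thr <- X / 100 * ptp
      lo <- 0; hi <- 0
      repeat {
        k <- (peak_i - 1 + hi + 1) %% n + 1
        if (hi - lo >= n - 1 || v[k] - gmin < thr) break
        hi <- hi + 1
      }
      repeat {
        k <- (peak_i - 1 + lo - 1) %% n + 1
        if (hi - lo >= n - 1 || v[k] - gmin < thr) break
        lo <- lo - 1
      }
      if (hi - lo >= n - 1) 360 else (hi - lo) * res
    })
  }
  if (modality == "unimodal") {
    p <- min(which(v == gmax))
    out$MaximumRight <- gmax
    out$MaximumAngleRight <- theta[p]
    out$PeakToPeakRight <- gmax - gmin
    bw <- band(p, gmax - gmin)
    out$Bandwidth25Right <- bw[1]; out$Bandwidth50Right <- bw[2]
    out$Bandwidth75Right <- bw[3]
    return(out)
  }
  li <- which(theta < 180); ri <- which(theta >= 180)
  ml <- max(v[li]); mr <- max(v[ri])
  cl <- li[v[li] == ml]
  dl <- pmin(abs(theta[cl] - 120), 360 - abs(theta[cl] - 120))
  pl <- cl[dl == min(dl)][1]
  cr <- ri[v[ri] == mr]
  dr <- pmin(abs(theta[cr] - 240), 360 - abs(theta[cr] - 240))
  pr <- cr[dr == min(dr)][1]
  out$MaximumLeft <- ml; out$MaximumRight <- mr
  out$MaximumAngleLeft <- theta[pl]; out$MaximumAngleRight <- theta[pr]
  out$PeakToPeakLeft <- ml - gmin; out$PeakToPeakRight <- mr - gmin
  out$DeltaPeakToPeak <- out$PeakToPeakRight - out$PeakToPeakLeft
  inner <- which(theta > theta[pl] & theta < theta[pr])
  if (length(inner)) {
    im <- min(v[inner])
    ia <- min(theta[inner][v[inner] == im])
    out$InnerMinimum <- im
    out$InnerMinimumAngle <- ia
    out$InnerWidthLeft <- ia - theta[pl]
    out$InnerWidthRight <- theta[pr] - ia
    out$DeltaInnerWidth <- out$InnerWidthRight - out$InnerWidthLeft
  }
  outer <- which(theta > theta[pr] | theta < theta[pl])
  if (length(outer)) {
    om <- min(v[outer])
    oa <- min(theta[outer][v[outer] == om])
    out$OuterMinimumAngle <- oa
    out$OuterWidthLeft <- (theta[pl] - oa) %% 360
    out$OuterWidthRight <- (oa - theta[pr]) %% 360
    out$DeltaOuterWidth <- out$OuterWidthRight - out$OuterWidthLeft
  }
  bl <- band(pl, out$PeakToPeakLeft); br <- band(pr, out$PeakToPeakRight)
  out$Bandwidth25Left <- bl[1]; out$Bandwidth50Left <- bl[2]
  out$Bandwidth75Left <- bl[3]
  out$Bandwidth25Right <- br[1]; out$Bandwidth50Right <- br[2]
  out$Bandwidth75Right <- br[3]
  out
}

# Random 12-point curve with unique values (avoids tie-rule ambiguity in
# cross-checks that exercise both implementations).
random_curve_values <- function(seed) {
  set.seed(seed)
  round(runif(12, 0, 40), 3) + seq(0, 0.0011, by = 1e-4)
}
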