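#' Multi-delay multi-echo acquisition protocol
#'
#' The saturation-recovery multi-echo spin-echo timing grid: every
#' combination of saturation delay and echo time yields one image, so the
#' default protocol produces a 4 x 5 = 20-image matrix per slice.
#'
#' @param saturation_delays ms, strictly increasing (default
#'   100, 400, 1380, 2860).
#' @param echo_times ms, strictly increasing and > 0 (default
#'   14, 28, 42, 56, 70).
#' @param repetition_time ms (default 2950); all delays must be below it.
#' @param gain arbitrary scanner scaling factor (default 1).
#' @return Object of class `acq_protocol`.
#' @export
acq_protocol <- function(saturation_delays = c(100, 400, 1380, 2860),
                         echo_times = c(14, 28, 42, 56, 70),
                         repetition_time = 2950,
                         gain = 1) {
  stopifnot(all(diff(saturation_delays) > 0),
            all(saturation_delays < repetition_time),
            all(diff(echo_times) > 0), all(echo_times > 0), gain > 0)
  structure(list(saturation_delays = saturation_delays,
                 echo_times = echo_times,
                 repetition_time = repetition_time,
                 gain = gain),
            class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("acq_protocol: %d delays x %d echoes = %d images, TR %g ms\n",
              length(x$saturation_delays), length(x$echo_times),
              length(x$saturation_delays) * length(x$echo_times),
              x$repetition_time))
  invisible(x)
}

#' Forward signal model
#'
#' Mono-exponential saturation recovery crossed with transverse decay:
#' `S = gain * PD * (1 - exp(-delay * R1)) * exp(-echo * R2)`, with delay
#' and echo in ms and the rates in 1/s. Monotone increasing in delay and
#' decreasing in echo. All arguments are vectorised.
#'
#' @param R1,R2 relaxation rates, 1/s (>= 0).
#' @param PD proton density, % (>= 0).
#' @param delay saturation delay, ms.
#' @param echo echo time, ms.
#' @param gain scanner scaling factor.
#' @return non-negative signal intensity.
#' @export
predict_signal <- function(R1, R2, PD, delay, echo, gain = 1) {
  stopifnot(all(R1 >= 0), all(R2 >= 0), all(PD >= 0),
            all(delay >= 0), all(echo >= 0), all(gain >= 0))
  gain * PD * (1 - exp(-delay / 1000 * R1)) * exp(-echo / 1000 * R2)
}

#' Simulate a signal stack from parameter maps
#'
#' Evaluates the forward model on every (delay, echo) pair of the protocol
#' and adds Gaussian acquisition noise with SD `noise_sigma` times the
#' maximum noiseless signal; negative values are clamped at 0 (magnitude
#' data).
#'
#' @param maps a `parameter_maps` object.
#' @param protocol an [acq_protocol()].
#' @param noise_sigma noise SD as a fraction of the maximum noiseless
#'   signal (0 for a noiseless stack).
#' @param seed optional integer seed.
#' @return Object of class `signal_stack`: `data` array indexed
#'   (delay, echo, x, y, z), `protocol`, `geometry`.
#' @export
simulate_signal_stack <- function(maps, protocol = acq_protocol(),
                                  noise_sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  nd <- length(protocol$saturation_delays)
  ne <- length(protocol$echo_times)
  sh <- maps$geometry$shape
  nv <- prod(sh)
  r1 <- as.vector(maps$R1); r2 <- as.vector(maps$R2); pd <- as.vector(maps$PD)
  rec <- outer(protocol$saturation_delays / 1000, r1,
               function(d, r) 1 - exp(-d * r))          # nd x V
  dec <- outer(protocol$echo_times / 1000, r2,
               function(e, r) exp(-e * r))               # ne x V
  dat <- array(0, c(nd, ne, nv))
  for (e in seq_len(ne))
    dat[, e, ] <- rec * rep(protocol$gain * pd * dec[e, ], each = nd)
  if (noise_sigma > 0) {
    s <- noise_sigma * max(dat)
    dat <- pmax(dat + stats::rnorm(length(dat), 0, s), 0)
  }
  dim(dat) <- c(nd, ne, sh)
  structure(list(data = dat, protocol = protocol, geometry = maps$geometry),
            class = "signal_stack")
}

#' @export
print.signal_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("signal_stack: %d delays x %d echoes on %dx%dx%d voxels\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Fit R1/R2/PD maps from a signal stack
#'
#' Per-voxel nonlinear least squares under the forward model of
#' [predict_signal()]. A two-stage initialiser (log-linear transverse decay
#' per delay across echoes, then saturation recovery of the echo-extrapolated
#' amplitudes, solved by bisection) seeds a vectorised Levenberg-Marquardt
#' refinement of (amplitude, R1, R2) jointly. Voxels whose maximum intensity
#' over the acquisition grid is below `floor_frac` of the stack maximum are
#' treated as background and excluded. Voxels where the refinement does not
#' reduce the residual fall back to the initialiser and are counted in the
#' QC field.
#'
#' The fitted amplitude equals `gain * PD`; if `csf_mask` is supplied, PD is
#' re-expressed in % of the median amplitude inside that pure-CSF reference
#' region (100 % = pure water), excluding voxels whose fitted recovery at
#' the longest delay is below 35 % — for such slow-recovery voxels the
#' amplitude is weakly identified and heavy-tailed. Otherwise the amplitude
#' is divided by the protocol gain.
#'
#' @param stack a `signal_stack`.
#' @param csf_mask optional logical array: pure-CSF reference region for PD
#'   calibration.
#' @param floor_frac background intensity floor as a fraction of the stack
#'   maximum (default 0.05).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return A `parameter_maps` object with attribute `qc`: list
#'   `n_fit`, `n_fallback`, `rmse` (in-mask residual RMSE).
#' @export
fit_parameter_maps <- function(stack, csf_mask = NULL, floor_frac = 0.05,
                               max_iter = 20L) {
  pr <- stack$protocol
  nd <- length(pr$saturation_delays)
  ne <- length(pr$echo_times)
  d <- dim(stack$data)
  stopifnot(d[1] == nd, d[2] == ne, nd >= 2, ne >= 2)
  sh <- d[3:5]
  nv <- prod(sh)
  S <- matrix(aperm(stack$data, c(3, 4, 5, 1, 2)), nv, nd * ne)  # V x (nd*ne)
  # column j corresponds to (delay di, echo ei):
  di <- rep(seq_len(nd), times = ne)
  ei <- rep(seq_len(ne), each = nd)
  tau <- pr$saturation_delays[di] / 1000     # s
  te <- pr$echo_times[ei] / 1000             # s

  smax <- max(S)
  mask <- matrixStats_rowMax(S) >= floor_frac * smax
  Sm <- S[mask, , drop = FALSE]
  V <- nrow(Sm)
  eps <- smax * 1e-9

  # --- stage 1: log-linear R2 and amplitude per delay
  lS <- log(pmax(Sm, eps))
  tes <- pr$echo_times / 1000
  A <- matrix(0, V, nd)        # echo-extrapolated amplitude per delay
  r2acc <- numeric(V); wacc <- numeric(V)
  mte <- mean(tes); vte <- sum((tes - mte)^2)
  for (dd in seq_len(nd)) {
    cols <- which(di == dd)
    Y <- lS[, cols, drop = FALSE]
    slope <- (Y %*% (tes - mte)) / vte
    inter <- rowMeans(Y) - slope * mte
    A[, dd] <- exp(inter)
    w <- rowMeans(Sm[, cols, drop = FALSE])  # weight late delays more
    r2acc <- r2acc + pmax(-slope, 0) * w
    wacc <- wacc + w
  }
  R2 <- as.vector(r2acc / pmax(wacc, eps))

  # --- stage 2: R1 from the recovery of the amplitudes, by bisection on
  # the ratio of the first to the last delay (monotone in R1)
  taus <- pr$saturation_delays / 1000
  ratio <- pmin(pmax(A[, 1] / pmax(A[, nd], eps), 1e-6), 1 - 1e-6)
  # R1 floor 0.05 1/s (T1 <= 20 s): below this the amplitude and R1 are
  # degenerate at these delays and M blows up
  lo <- rep(0.05, V); hi <- rep(20, V)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f <- (1 - exp(-taus[1] * mid)) / (1 - exp(-taus[nd] * mid))
    up <- f < ratio
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  R1 <- (lo + hi) / 2
  u <- 1 - exp(-outer(R1, taus))             # V x nd
  M <- rowSums(A * u) / pmax(rowSums(u * u), 1e-12)

  # --- joint Levenberg-Marquardt refinement
  model <- function(M, R1, R2) {
    (M * (1 - exp(-outer(R1, tau)))) * exp(-outer(R2, te))
  }
  sse <- function(M, R1, R2) rowSums((Sm - model(M, R1, R2))^2)
  cur <- sse(M, R1, R2)
  init <- list(M = M, R1 = R1, R2 = R2, sse = cur)
  lambda <- rep(1e-3, V)
  for (it in seq_len(max_iter)) {
    Erec <- exp(-outer(R1, tau)); U <- 1 - Erec
    Edec <- exp(-outer(R2, te))
    P <- U * Edec
    r <- Sm - M * P
    jM <- P
    jR1 <- (M * Erec * Edec) * rep(tau, each = V)
    jR2 <- -(M * P) * rep(te, each = V)
    a11 <- rowSums(jM * jM); a12 <- rowSums(jM * jR1); a13 <- rowSums(jM * jR2)
    a22 <- rowSums(jR1 * jR1); a23 <- rowSums(jR1 * jR2)
    a33 <- rowSums(jR2 * jR2)
    g1 <- rowSums(jM * r); g2 <- rowSums(jR1 * r); g3 <- rowSums(jR2 * r)
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    d33 <- a33 * (1 + lambda)
    det <- d11 * (d22 * d33 - a23^2) - a12 * (a12 * d33 - a23 * a13) +
      a13 * (a12 * a23 - d22 * a13)
    det[abs(det) < 1e-300] <- 1e-300
    s1 <- (g1 * (d22 * d33 - a23^2) + g2 * (a13 * a23 - a12 * d33) +
             g3 * (a12 * a23 - a13 * d22)) / det
    s2 <- (g1 * (a23 * a13 - a12 * d33) + g2 * (d11 * d33 - a13^2) +
             g3 * (a13 * a12 - d11 * a23)) / det
    s3 <- (g1 * (a12 * a23 - d22 * a13) + g2 * (a12 * a13 - d11 * a23) +
             g3 * (d11 * d22 - a12^2)) / det
    Mn <- M + s1
    R1n <- pmin(pmax(R1 + s2, 0.05), 50)
    R2n <- pmin(pmax(R2 + s3, 1e-4), 200)
    new <- sse(Mn, R1n, R2n)
    better <- new < cur & is.finite(new)
    M[better] <- Mn[better]; R1[better] <- R1n[better]; R2[better] <- R2n[better]
    cur[better] <- new[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-10)
    lambda[!better] <- pmin(lambda[!better] * 5, 1e8)
    if (!any(better)) break
    if (it > 6L && mean(better) < 0.001) break
  }
  fallback <- cur > init$sse + 1e-12
  M[fallback] <- init$M[fallback]
  R1[fallback] <- init$R1[fallback]
  R2[fallback] <- init$R2[fallback]

  full <- function(x, fillv = 0) {
    out <- rep(fillv, nv); out[mask] <- x; array(out, sh)
  }
  Mmap <- full(M)
  if (!is.null(csf_mask)) {
    # the amplitude is only well determined where a decent part of the
    # recovery is actually sampled; slow-recovery voxels have degenerate
    # (M, R1) and heavy-tailed M, so they are excluded from the reference
    # and the median is used
    rec_max <- full(1 - exp(-max(taus) * R1))
    inref <- csf_mask & array(mask, sh)
    good <- inref & rec_max >= 0.35
    if (!any(good)) good <- inref
    ref <- stats::median(Mmap[good])
    if (!is.finite(ref) || ref <= 0)
      stop("CSF reference region has no fitted voxels")
    PDmap <- Mmap / ref * 100
  } else {
    PDmap <- Mmap / pr$gain
  }
  out <- parameter_maps(full(R1), full(R2), PDmap, stack$geometry,
                        mask = array(mask, sh))
  attr(out, "qc") <- list(n_fit = V, n_fallback = sum(fallback),
                          rmse = sqrt(mean(cur) / (nd * ne)))
  out
}

# rowMax without extra dependencies
matrixStats_rowMax <- function(x) {
  out <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) out <- pmax(out, x[, j])
  out
}

#' Synthesize a contrast-weighted image from parameter maps
#'
#' Spin-echo contrast reconstruction
#' `S = PD * (1 - exp(-repetition * R1)) * exp(-echo * R2)` (synthetic MRI).
#' With a long repetition time and a long echo time this yields a
#' T2-weighted image in which CSF is bright; such images are used as the
#' source images for spatial normalization.
#'
#' @param maps a `parameter_maps` object.
#' @param echo echo time, ms (> 0).
#' @param repetition repetition time, ms (> 0).
#' @return 3-D array of signal intensities.
#' @export
synthesize_contrast_image <- function(maps, echo = 100, repetition = 4500) {
  stopifnot(echo > 0, repetition > 0)
  maps$PD * (1 - exp(-repetition / 1000 * maps$R1)) *
    exp(-echo / 1000 * maps$R2)
}
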