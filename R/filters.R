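# Zero-phase IIR filtering via zero-pole-gain design and second-order
# sections. Transfer-function (b, a) forms are numerically unusable for the
# high-order Chebyshev II high-pass at 0.3 Hz relative to a 128 Hz rate
# (polynomial root clustering near z = 1), so filters are designed in zpk
# form with closed-form prototypes, mapped by the bilinear transform, and run
# as a cascade of biquads, each applied forward-backward.

# analog Butterworth lowpass prototype poles (cutoff 1 rad/s)
.butterProto <- function(n) {
  k <- seq_len(n)
  list(z = complex(0),
       p = exp(1i * (pi / 2 + (2 * k - 1) * pi / (2 * n))),
       k = 1)
}

# analog Chebyshev type II (inverse Chebyshev) lowpass prototype,
# stop-band edge 1 rad/s, stop-band attenuation Rs dB
.cheby2Proto <- function(n, Rs) {
  eps <- 1 / sqrt(10^(Rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- (2 * k - 1) * pi / (2 * n)
  p1 <- complex(real = -sinh(mu) * sin(theta),
                imaginary = cosh(mu) * cos(theta))
  p <- 1 / p1
  ct <- cos(theta)
  z <- 1i / ct[abs(ct) > 1e-12]   # odd n: one zero at infinity
  kk <- Re(prod(-p) / prod(-z))   # unity DC gain
  list(z = z, p = p, k = kk)
}

# lowpass (wc) / highpass frequency transform of an analog prototype
.lpTransform <- function(proto, wc) {
  list(z = proto$z * wc, p = proto$p * wc,
       k = proto$k * wc^(length(proto$p) - length(proto$z)))
}

.hpTransform <- function(proto, wc) {
  nz <- length(proto$z)
  np <- length(proto$p)
  z <- c(wc / proto$z, rep(0 + 0i, np - nz))
  p <- wc / proto$p
  k <- proto$k * Re(prod(-proto$z) / prod(-proto$p))
  list(z = z, p = p, k = k)
}

# bilinear transform with gain fixed at a digital reference point
.bilinearZpk <- function(analog, fs, refz) {
  f2 <- 2 * fs
  zd <- (f2 + analog$z) / (f2 - analog$z)
  pd <- (f2 + analog$p) / (f2 - analog$p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  h <- prod(refz - zd) / prod(refz - pd)
  k <- 1 / Mod(h)
  list(z = zd, p = pd, k = k)
}

#' @noRd
.designFilter <- function(n, fc, fs, type = c("low", "high"), design = c("butter", "cheby2"),
                          Rs = 40) {
  type <- match.arg(type)
  design <- match.arg(design)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  proto <- if (design == "butter") .butterProto(n) else .cheby2Proto(n, Rs)
  wc <- 2 * fs * tan(pi * fc / fs)  # prewarped
  analog <- if (type == "low") .lpTransform(proto, wc) else .hpTransform(proto, wc)
  refz <- if (type == "low") 1 + 0i else -1 + 0i
  dig <- .bilinearZpk(analog, fs, refz)
  .zpk2sos(dig$z, dig$p, dig$k)
}

# pair conjugate roots into real biquads; poles nearest the unit circle are
# paired with the nearest remaining zeros
.zpk2sos <- function(z, p, k) {
  pairUp <- function(r) {
    out <- list()
    r <- r[order(-abs(Im(r)), Re(r))]
    used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-9) {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-7)[1]
        if (is.na(j)) stop("unpaired complex root")
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j])
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-9)[1]
        if (!is.na(j)) {
          used[j] <- TRUE
          out[[length(out) + 1]] <- c(r[i], r[j])
        } else {
          out[[length(out) + 1]] <- r[i]
        }
      }
    }
    out
  }
  polyFromRoots <- function(rr) {
    if (length(rr) == 2) c(1, -Re(rr[1] + rr[2]), Re(rr[1] * rr[2]))
    else c(1, -Re(rr[1]), 0)
  }
  pGroups <- pairUp(p)
  # sort pole sections by distance to unit circle (closest last for stability
  # of intermediate signals)
  ord <- order(vapply(pGroups, function(g) max(abs(g)), numeric(1)))
  pGroups <- pGroups[ord]
  zPool <- z
  sections <- list()
  for (g in rev(pGroups)) {     # nearest-unit-circle poles pick zeros first
    if (length(zPool)) {
      d <- abs(zPool - g[1])
      zi <- which.min(d)
      zsel <- zPool[zi]
      zPool <- zPool[-zi]
      if (abs(Im(zsel)) > 1e-9) {
        zj <- which.min(abs(zPool - Conj(zsel)))
        zsel <- c(zsel, zPool[zj])
        zPool <- zPool[-zj]
      } else if (length(zPool) && any(abs(Im(zPool)) <= 1e-9)) {
        zj <- which(abs(Im(zPool)) <= 1e-9)[1]
        zsel <- c(zsel, zPool[zj])
        zPool <- zPool[-zj]
      }
      b <- polyFromRoots(zsel)
      if (length(zsel) == 1) b <- c(b[1], b[2], 0)
    } else {
      b <- c(1, 0, 0)
    }
    a <- polyFromRoots(g)
    if (length(g) == 1) a <- c(a[1], a[2], 0)
    sections[[length(sections) + 1]] <- list(b = b, a = a)
  }
  list(sections = rev(sections), gain = k)
}

# zero-phase cascade: each biquad run forward-backward (compiled, with
# odd-reflection padding and steady-state initial conditions), so the overall
# response is |H|^2 with H the designed single-pass filter; the scalar gain
# enters squared accordingly
.sosFiltFilt <- function(sos, x) {
  m <- t(vapply(sos$sections, function(s) c(s$b, s$a), numeric(6)))
  as.numeric(.sosFiltFiltCpp(m, x)) * sos$gain^2
}

# single-pass frequency response of an sos cascade (used in tests)
.sosFreqResponse <- function(sos, f, fs) {
  z <- exp(2i * pi * f / fs)
  h <- rep(complex(real = sos$gain), length(z))
  for (s in sos$sections) {
    h <- h * (s$b[1] + s$b[2] / z + s$b[3] / z^2) /
      (s$a[1] + s$a[2] / z + s$a[3] / z^2)
  }
  h
}

# analytic signal by FFT (Hilbert transform); envelope = Mod(analyticSignal(x))
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# integer-factor decimation with zero-phase anti-alias lowpass at 0.8 of the
# target Nyquist
.decimateBy <- function(x, q) {
  if (q == 1) return(x)
  fsNorm <- 1
  sos <- .designFilter(8, 0.4 / q, fsNorm, type = "low", design = "butter")
  y <- .sosFiltFilt(sos, x)
  y[seq(1, length(x), by = q)]
}
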