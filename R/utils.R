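#' Canonical EEG frequency bands
#'
#' The four bands used throughout the pipeline, with (low, high) edges in Hz:
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-30.
#'
#' @return named list of numeric(2) band edges.
#' @export
bandTable <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30))
}

#' Standard 32-channel 10-20 montage labels
#'
#' @param n number of channels (labels are recycled generically past 32).
#' @return character vector of channel labels.
#' @export
montageLabels <- function(n = 32L) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
            "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
            "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("EX%02d", seq_len(n - length(base))))
}

# 31 cortical regions per hemisphere (62 total), grouped into 7 areas.
.dktRegions <- c(
  "lateralorbitofrontal", "medialorbitofrontal", "parsopercularis",
  "parsorbitalis", "parstriangularis", "rostralmiddlefrontal",  # prefrontal
  "superiorfrontal", "caudalmiddlefrontal",                      # frontal
  "precentral", "postcentral", "paracentral",                    # central
  "superiorparietal", "inferiorparietal", "supramarginal", "precuneus",
  "lateraloccipital", "lingual", "cuneus", "pericalcarine",      # occipital
  "superiortemporal", "middletemporal", "inferiortemporal",
  "transversetemporal", "fusiform",                              # temporal
  "caudalanteriorcingulate", "rostralanteriorcingulate",
  "posteriorcingulate", "isthmuscingulate", "parahippocampal",
  "entorhinal", "insula"                                         # limbic
)
.dktAreaOf <- c(
  rep("prefrontal", 6), rep("frontal", 2), rep("central", 3),
  rep("parietal", 4), rep("occipital", 4), rep("temporal", 5),
  rep("limbic", 7)
)

#' Cortical atlas region labels and area grouping
#'
#' 62 region names (31 per hemisphere, Desikan-Killiany-Tourville
#' parcellation) grouped into 7 areas: prefrontal, frontal, central,
#' parietal, occipital, temporal, limbic.
#'
#' @return data.frame with columns \code{roi}, \code{hemisphere},
#'   \code{area}.
#' @export
dktAtlasTable <- function() {
  data.frame(
    roi = c(paste0("lh_", .dktRegions), paste0("rh_", .dktRegions)),
    hemisphere = rep(c("lh", "rh"), each = length(.dktRegions)),
    area = rep(.dktAreaOf, 2),
    stringsAsFactors = FALSE
  )
}

# deterministic child-seed derivation: keeps every derived seed in [1, 2^31-2]
childSeed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s + 1)
}

# analytic signal via FFT: zero the negative frequencies, double the positive
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# pink (1/f) noise by spectral shaping of white Gaussian noise,
# scaled to the requested standard deviation
pinkNoise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  S <- W / sqrt(f)
  x <- Re(stats::fft(S, inverse = TRUE) / n)
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

# von Mises sampler, Best & Fisher (1979) rejection scheme; kappa = 0 gives
# the circular uniform
rVonMises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(mu, n) + stats::rnorm(n, 0, 1 / sqrt(kappa)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrapPhase(out + mu)
}

# wrap angles into (-pi, pi]
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# circular mean of angles
circularMean <- function(x) Arg(mean(exp(1i * x)))
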