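# Internal helpers shared across modules.

ACTIVITIES <- c("Sitting", "Lying", "Standing", "StairsUp", "StairsDown", "Walking")
STATIONARY <- c("Sitting", "Lying", "Standing")
AMBULATORY <- c("StairsUp", "StairsDown", "Walking")
SESSIONS <- c("Lab1", "Home", "Lab2")

#' @noRd
session_environment <- function(session) {
  ifelse(session == "Home", "home", "lab")
}

# Evaluate expr under a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a string key; stays < 2^31.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

# Population (biased) skewness; 0 for degenerate signals.
moment_skew <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Population kurtosis, non-excess (3 for a normal); 0 for degenerate signals.
moment_kurt <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2
}

rms <- function(x) sqrt(mean(x^2))

# Largest-remainder allocation of n items to proportions p, with a per-cell
# minimum. Deterministic; sums to n exactly.
allocate_counts <- function(n, p, minimum = 0L) {
  stopifnot(abs(sum(p) - 1) < 1e-8, n >= minimum * length(p))
  base <- pmax(floor(p * n), minimum)
  while (sum(base) > n) {
    elig <- which(base > minimum)   # never shave below the per-cell minimum
    i <- elig[which.max(base[elig] - p[elig] * n)]
    base[i] <- base[i] - 1L
  }
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - floor(p * n)
    ord <- order(frac, decreasing = TRUE)
    for (i in ord[seq_len(rem)]) base[i] <- base[i] + 1L
  }
  as.integer(base)
}

# Uniformly random 3-D rotation matrix (via QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Small rotation about a random axis with angle ~ N(0, sd_rad).
jitter_rotation <- function(sd_rad) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, sd_rad)
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# AR(1) smooth noise with stationary SD `sd`.
smooth_noise <- function(n, sd, phi = 0.97) {
  if (n == 0) return(numeric(0))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  stats::filter(e, phi, method = "recursive", init = stats::rnorm(1, 0, sd))[seq_len(n)]
}

# Band-limited postural sway: a few low-frequency sinusoids (0.1-0.8 Hz) with
# random amplitude/phase, scaled to total SD `sd`. Smooth by construction, so
# clean stationary signal scores low sample entropy.
band_sway <- function(t, sd, n_comp = 3) {
  if (!length(t)) return(numeric(0))
  a <- abs(stats::rnorm(n_comp))
  a <- a / sqrt(sum(a^2) / 2) * sd
  out <- numeric(length(t))
  for (k in seq_len(n_comp)) {
    out <- out + a[k] * sin(2 * pi * stats::runif(1, 0.1, 0.8) * t +
                              stats::runif(1, 0, 2 * pi))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
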