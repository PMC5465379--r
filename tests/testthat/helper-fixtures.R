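# Shared fixture builders for the test suite. Everything is generated in code;
# nothing is read from disk.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# A small cohort specification for fast end-to-end tests.
tiny_spec <- function(..., rng_seed = 1L) {
  args <- list(...)
  defaults <- list(n_healthy = 2, n_mild = 1, n_moderate = 1, n_severe = 1,
                   stroke_sessions = "Home", bouts_home = 8, bouts_lab = 8,
                   artifact_rate = 0, mislabel_rate = 0, drop_rate = 0,
                   rng_seed = rng_seed)
  defaults[names(args)] <- args
  do.call(cohort_spec, defaults)
}

# Uniform synthetic bout segment of duration T seconds, as produced by
# preprocess_recording(): grid-aligned resampled streams.
make_segment <- function(T, activity = "Walking", rate_in = 50, rate_baro = 6,
                         with_baro = TRUE) {
  n_in <- round(T * rate_in)
  n_b <- round(T * rate_baro)
  list(subject_id = "T01", session = "Home", environment = "home",
       cohort = "stroke", impairment = "moderate", gait_speed = 0.6,
       bout_id = "T01_b1", activity = activity, start_s = 0,
       duration_s = min(n_in / rate_in, if (with_baro) n_b / rate_baro else Inf),
       rate_inertial = rate_in, rate_baro = rate_baro,
       acc = matrix(stats::rnorm(3 * n_in), n_in, 3),
       gyr = matrix(stats::rnorm(3 * n_in), n_in, 3),
       baro = if (with_baro) stats::rnorm(n_b, 1000, 0.05) else NULL)
}

# Instance table with controllable class/subject structure and plain Gaussian
# features; used by evaluation-layer tests that do not need real signals.
make_toy_table <- function(n_subjects = 6, clips_per_class = 12,
                           activities = c("Sitting", "Standing", "Walking"),
                           n_noise = 5, subject_sd = 0.5, cohort = "stroke",
                           sessions = "Home", seed = 1) {
  set.seed(seed)
  meta <- NULL; feats <- NULL
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", substr(cohort, 1, 1), s)
    off <- stats::rnorm(1, 0, subject_sd)
    speed <- stats::runif(1, 0.2, 1.3)
    for (ses in sessions) {
      for (a in activities) {
        k <- clips_per_class
        f <- cbind(sig = match(a, activities) + off + stats::rnorm(k, 0, 0.3),
                   matrix(stats::rnorm(k * n_noise), k, n_noise))
        colnames(f) <- c("sig", paste0("noise", seq_len(n_noise)))
        start <- stats::runif(1, 0, 500) + seq_len(k)
        meta <- rbind(meta, data.frame(
          subject_id = sid, session = ses,
          environment = ifelse(ses == "Home", "home", "lab"), cohort = cohort,
          impairment = impairment_from_speed(speed, cohort),
          gait_speed = speed, bout_id = paste0(sid, "_", ses, "_", a),
          activity = a, clip_start_s = start, clip_end_s = start + 10,
          stringsAsFactors = FALSE))
        feats <- rbind(feats, f)
      }
    }
  }
  instance_table(meta, feats)
}

# 6-class imbalanced toy with two ~1.5% prevalence classes on overlapping
# Gaussian blobs; RUSBoost's motivating scenario.
make_imbalanced_xy <- function(n_major = 330, n_rare = 20, sd = 0.9) {
  ctr <- rbind(A = c(0, 0), B = c(3, 0), C = c(0, 3), D = c(3, 3),
               E = c(1.5, 0.2), F = c(0.2, 1.5))
  ns <- c(rep(n_major, 4), n_rare, n_rare)
  x <- NULL; y <- NULL
  for (k in 1:6) {
    x <- rbind(x, sweep(matrix(stats::rnorm(2 * ns[k], 0, sd), ns[k], 2),
                        2, ctr[k, ], "+"))
    y <- c(y, rep(rownames(ctr)[k], ns[k]))
  }
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

# Brute-force one-sided periodogram by direct DFT (independent of stats::fft).
oracle_periodogram <- function(x, rate) {
  n <- length(x)
  xc <- x - mean(x)
  ks <- 0:(n %/% 2)
  pw <- vapply(ks, function(k) {
    re <- sum(xc * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xc * sin(-2 * pi * k * (0:(n - 1)) / n))
    (re^2 + im^2) / n
  }, 0)
  list(freq = ks * rate / n, power = pw)
}

# Brute-force sample entropy by explicit template enumeration. Both template
# lengths are enumerated over the first n - m start positions.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(len) {
    nt <- n - m
    tot <- 0L
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          tot <- tot + 1L
        }
      }
    }
    tot
  }
  b <- count(m); a <- count(m + 1)
  if (a == 0 || b == 0) return(Inf)
  -log(a / b)
}
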