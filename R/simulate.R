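#' Describe a planted class-discriminative burst
#'
#' A planted pattern is a Gabor-like transient: a sinusoid at `carrier_freq`
#' under a Hann envelope of length `duration`, centred at `center_time`,
#' loaded onto the channels of a set of sensor sites. Class identity is
#' carried by per-class loadings: either a vector (one amplitude per class,
#' same spatial profile) or a matrix `[n_classes x length(sites)]` giving
#' each class its own spatial profile over the pattern's sites. When
#' `class_loadings = NULL`, [generate_epochs()] draws a seeded loading
#' matrix built from a shared evoked profile plus a class-specific part
#' (see `class_separation` in [sim_config()]), scaled to unit RMS per
#' channel.
#'
#' @param center_time burst centre, seconds after stimulus onset.
#' @param duration burst (Hann envelope) length in seconds.
#' @param carrier_freq carrier frequency in Hz; must be below Nyquist.
#' @param sites integer site indices the burst is loaded on (1-based).
#' @param class_loadings `NULL`, a numeric vector of length `n_classes`, or a
#'   matrix `[n_classes x length(sites)]`.
#' @param amplitude per-pattern scale multiplying the dataset-level `snr`
#'   (lets one configuration carry a dominant component plus weaker ones).
#' @return A `planted_pattern` list.
#' @export
planted_pattern <- function(center_time, duration, carrier_freq, sites,
                            class_loadings = NULL, amplitude = 1) {
  stopifnot(duration > 0, carrier_freq >= 0, length(sites) >= 1,
            amplitude >= 0)
  structure(
    list(center_time = center_time, duration = duration,
         carrier_freq = carrier_freq, sites = as.integer(sites),
         class_loadings = class_loadings, amplitude = amplitude),
    class = "planted_pattern"
  )
}

#' Configuration of the synthetic MEG-like generator
#'
#' Defines a dataset of `n_classes * n_trials_per_class` balanced trials of
#' `3 * n_sites` channels. Each trial is the sum of
#' \itemize{
#'   \item band-limited `1/f^noise_exponent` background noise, generated as
#'     independent unit-variance sources and spatially mixed by a seeded
#'     random orthonormal matrix (realistic channel covariance);
#'   \item white sensor noise (`sensor_noise_sd`);
#'   \item the trial's class pattern: every planted burst scaled by `snr`
#'     (burst peak amplitude relative to the unit background deviation);
#'   \item optionally `n_adversarial` high-variance *non-discriminative*
#'     spatial components (variance `adversarial_variance`), drawn orthogonal
#'     to the discriminative spatial subspace. These make variance-ranked
#'     channel truncation (PCA) discard the signal while a supervised
#'     projection can keep it.
#' }
#'
#' @param n_classes number of stimulus classes (>= 2).
#' @param n_trials_per_class repetitions per class.
#' @param n_sites sensor sites; channels = `3 * n_sites`.
#' @param sfreq sampling rate, Hz.
#' @param epoch_len epoch length, seconds; `epoch_len * sfreq` must be an
#'   integer >= 10.
#' @param noise_exponent slope of the `1/f` background (0 = white).
#' @param snr burst amplitude relative to unit background deviation (>= 0).
#' @param class_separation fraction of each planted response that is
#'   class-specific: default loadings are built as a shared (stimulus-
#'   generic) evoked profile plus `class_separation` times a per-class
#'   profile, then scaled to unit RMS. 1 = fully class-specific responses;
#'   small values emulate the realistic regime where most of the evoked
#'   deflection is common to all stimuli. Ignored for explicit
#'   `class_loadings`.
#' @param patterns list of [planted_pattern()]s.
#' @param adversarial_variance variance of the non-discriminative components.
#' @param n_adversarial number of such components (used when
#'   `adversarial_variance > 0`).
#' @param field_spread spatial leakage scale (layout distance units): each
#'   planted response also appears at other sites scaled by
#'   `exp(-(d / field_spread)^2)`, emulating the smooth sensor-space
#'   footprint of a magnetic source. 0 disables leakage (responses stay
#'   confined to their sites).
#' @param sensor_noise_sd white sensor noise standard deviation.
#' @param f_lo,f_hi band limits of the background noise, Hz.
#' @param t0 time of first sample relative to onset, seconds.
#' @param seed integer seed; identical configs give bit-identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 8L, n_trials_per_class = 20L,
                       n_sites = 10L, sfreq = 100, epoch_len = 0.9,
                       noise_exponent = 1, snr = 1, class_separation = 0.3,
                       patterns = list(), adversarial_variance = 0,
                       n_adversarial = 20L, field_spread = 0.45,
                       sensor_noise_sd = 0.3,
                       f_lo = 0.1, f_hi = 25, t0 = 0, seed = 1L) {
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (sfreq <= 0) stop("`sfreq` must be positive")
  n_times <- epoch_len * sfreq
  if (abs(n_times - round(n_times)) > 1e-9 || round(n_times) < 10)
    stop("`epoch_len * sfreq` must be an integer >= 10")
  if (snr < 0) stop("`snr` must be >= 0")
  if (class_separation < 0 || class_separation > 1)
    stop("`class_separation` must be in [0, 1]")
  for (p in patterns) {
    if (p$center_time - p$duration / 2 < t0 ||
        p$center_time + p$duration / 2 > t0 + epoch_len)
      stop("pattern extends outside the epoch")
    if (p$carrier_freq >= sfreq / 2)
      stop("pattern carrier frequency at or above Nyquist")
    if (any(p$sites < 1L | p$sites > n_sites))
      stop("pattern site index out of range")
  }
  structure(
    list(n_classes = as.integer(n_classes),
         n_trials_per_class = as.integer(n_trials_per_class),
         n_sites = as.integer(n_sites), sfreq = sfreq,
         epoch_len = epoch_len, n_times = as.integer(round(n_times)),
         noise_exponent = noise_exponent, snr = snr,
         class_separation = class_separation, patterns = patterns,
         adversarial_variance = adversarial_variance,
         n_adversarial = as.integer(n_adversarial),
         field_spread = field_spread,
         sensor_noise_sd = sensor_noise_sd, f_lo = f_lo, f_hi = f_hi,
         t0 = t0, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one band-limited 1/f^a source, unit variance (unless the band is empty)
rfft_noise <- function(n_times, sfreq, exponent, f_lo, f_hi, rng) {
  freqs <- (0:(n_times %/% 2)) * sfreq / n_times
  amp <- numeric(length(freqs))
  sel <- freqs > 0 & freqs >= f_lo & freqs <= f_hi
  amp[sel] <- freqs[sel]^(-exponent / 2)
  nb <- sum(sel)
  coef <- complex(length.out = length(freqs))
  coef[sel] <- amp[sel] *
    complex(real = rng$rnorm(nb), imaginary = rng$rnorm(nb))
  # hermitian completion -> real signal
  full <- complex(length.out = n_times)
  full[seq_along(freqs)] <- coef
  if (n_times %% 2 == 0) full[n_times / 2 + 1] <- complex(real = Re(full[n_times / 2 + 1]))
  if (n_times > 1)
    full[n_times:(n_times %/% 2 + 2)] <- Conj(full[2:((n_times + 1) %/% 2)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n_times
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Per-class loading matrix [n_classes x 3 * n_sites(pattern)], one column
# per channel of the pattern's sites. `class_loadings` may be NULL (seeded
# random unit-norm rows, the default: distinct spatial profile per class),
# a vector of per-class amplitudes (shared spatial profile), a site-level
# matrix [n_classes x n_sites_p] (replicated over each site's 3 channels),
# or a full channel-level matrix [n_classes x 3 * n_sites_p].
pattern_loadings <- function(pattern, config, rng) {
  n_sites_p <- length(pattern$sites)
  n_ch_p <- 3L * n_sites_p
  cl <- pattern$class_loadings
  if (is.null(cl)) {
    # shared evoked profile + class-specific modulation, unit RMS per
    # channel: `snr` is the typical per-channel response amplitude in
    # units of the background deviation, while `class_separation` sets
    # how much of it discriminates between classes
    shared <- rng$rnorm(n_ch_p)
    uniq <- matrix(rng$rnorm(config$n_classes * n_ch_p),
                   nrow = config$n_classes)
    # equalise the class-specific energy across the pattern's sites so a
    # pattern's spatial footprint is set by its amplitude, not draw luck
    for (j in seq_len(n_sites_p)) {
      block <- (j - 1L) * 3L + 1:3
      uniq[, block] <- uniq[, block] /
        sqrt(rowSums(uniq[, block, drop = FALSE]^2) / 3)
    }
    sep <- config$class_separation
    cl <- matrix(shared, config$n_classes, n_ch_p, byrow = TRUE) *
      (1 - sep) + uniq * sep
    cl <- cl / sqrt(rowSums(cl^2) / n_ch_p)
  } else if (is.null(dim(cl))) {
    if (length(cl) != config$n_classes)
      stop("class_loadings vector must have one entry per class")
    cl <- matrix(rep(cl, n_ch_p), ncol = n_ch_p) / sqrt(n_ch_p)
  } else if (all(dim(cl) == c(config$n_classes, n_sites_p))) {
    cl <- cl[, rep(seq_len(n_sites_p), each = 3L), drop = FALSE] / sqrt(3)
  } else if (!all(dim(cl) == c(config$n_classes, n_ch_p))) {
    stop("class_loadings matrix must be [n_classes x sites] or ",
         "[n_classes x 3*sites] of the pattern")
  }
  if (nrow(unique(round(cl, 12))) < 2)
    stop("pattern is non-discriminative: all class loadings identical")
  cl
}

#' Generate a synthetic epoched dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{epochs}{a [meg_epochs()] object, shape
#'       `[n_classes * n_trials_per_class, 3 * n_sites, epoch_len * sfreq]`,
#'       labels `0 .. n_classes - 1`, balanced.}
#'     \item{truth}{ground truth: per-pattern time windows (s), site sets and
#'       frequency bands, the discriminative channel-space basis
#'       (`signal_basis`), and the adversarial basis if any.}
#'   }
#' @examples
#' cfg <- sim_config(n_classes = 3, n_trials_per_class = 4, n_sites = 4,
#'                   snr = 2, patterns = list(planted_pattern(0.45, 0.2, 10, 1:2)))
#' d <- generate_epochs(cfg)
#' dim(d$epochs)
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  n_trials <- config$n_classes * config$n_trials_per_class
  n_channels <- 3L * config$n_sites
  nt <- config$n_times
  layout <- make_sensor_layout(config$n_sites, seed = config$seed)

  # spatial mixing of the background: random orthonormal matrix
  mix <- qr.Q(qr(matrix(rng$rnorm(n_channels^2), n_channels)))

  # class-level channel loadings per pattern, and burst waveforms
  times <- config$t0 + (seq_len(nt) - 1L) / config$sfreq
  pat_load <- list(); pat_wave <- list()
  signal_dirs <- NULL
  for (i in seq_along(config$patterns)) {
    p <- config$patterns[[i]]
    cl <- pattern_loadings(p, config, rng)
    chan_load <- matrix(0, config$n_classes, n_channels)
    for (j in seq_along(p$sites)) {
      ch <- layout$site_channels[[p$sites[j]]]
      chan_load[, ch] <- chan_load[, ch] + cl[, (j - 1L) * 3L + 1:3]
    }
    if (config$field_spread > 0 && config$n_sites > 1) {
      # smooth sensor-space footprint: leak each site's loading to other
      # sites with Gaussian distance decay (self-weight 1)
      dmat <- as.matrix(stats::dist(layout$positions))
      wmat <- exp(-(dmat / config$field_spread)^2)
      for (k in seq_len(config$n_classes)) {
        m <- matrix(chan_load[k, ], nrow = 3L)     # [3 x n_sites]
        chan_load[k, ] <- as.vector(m %*% wmat)
      }
    }
    env <- numeric(nt)
    in_burst <- abs(times - p$center_time) <= p$duration / 2
    ph <- (times[in_burst] - p$center_time)
    env[in_burst] <- 0.5 * (1 + cos(2 * pi * ph / p$duration)) *
      cos(2 * pi * p$carrier_freq * ph)
    pat_load[[i]] <- chan_load
    pat_wave[[i]] <- env
    signal_dirs <- rbind(signal_dirs, chan_load)
  }

  # adversarial components: high-variance spatial directions orthogonal to
  # the discriminative subspace, with their own 1/f time courses
  adv_basis <- NULL
  if (config$adversarial_variance > 0 && config$n_adversarial > 0) {
    k <- config$n_adversarial
    raw <- matrix(rng$rnorm(n_channels * k), n_channels, k)
    if (!is.null(signal_dirs)) {
      sb <- qr.Q(qr(t(signal_dirs)))[, seq_len(qr(t(signal_dirs))$rank), drop = FALSE]
      raw <- raw - sb %*% (t(sb) %*% raw)
    }
    adv_basis <- qr.Q(qr(raw))[, seq_len(min(k, ncol(raw))), drop = FALSE]
  }

  labels <- rep(0:(config$n_classes - 1L), times = config$n_trials_per_class)
  data <- array(0, dim = c(n_trials, n_channels, nt))
  for (tr in seq_len(n_trials)) {
    src <- vapply(seq_len(n_channels), function(i)
      rfft_noise(nt, config$sfreq, config$noise_exponent,
                 config$f_lo, config$f_hi, rng), numeric(nt))
    x <- tcrossprod(mix, src)                      # [channels x times]
    x <- x + matrix(rng$rnorm(n_channels * nt, sd = config$sensor_noise_sd),
                    n_channels, nt)
    cls <- labels[tr] + 1L
    for (i in seq_along(config$patterns))
      x <- x + config$snr * config$patterns[[i]]$amplitude *
        tcrossprod(pat_load[[i]][cls, ], pat_wave[[i]])
    if (!is.null(adv_basis)) {
      amp <- sqrt(config$adversarial_variance)
      z <- matrix(rng$rnorm(ncol(adv_basis) * nt, sd = amp),
                  ncol(adv_basis), nt)
      x <- x + adv_basis %*% z
    }
    data[tr, , ] <- x
  }

  truth <- list(
    windows = lapply(config$patterns, function(p)
      c(p$center_time - p$duration / 2, p$center_time + p$duration / 2)),
    sites = lapply(config$patterns, function(p) p$sites),
    bands = lapply(config$patterns, function(p)
      c(max(0, p$carrier_freq - 1 / p$duration),
        p$carrier_freq + 1 / p$duration)),
    carrier_freqs = vapply(config$patterns, function(p) p$carrier_freq,
                           numeric(1)),
    signal_basis = if (is.null(signal_dirs)) NULL else t(signal_dirs),
    adversarial_basis = adv_basis,
    config = config
  )
  list(epochs = meg_epochs(data, labels, config$sfreq, config$t0, layout),
       truth = truth)
}

#' Mean power spectral density of an epochs object
#'
#' Average of the per-trial, per-channel periodograms; used to check the
#' spectral shape of generated data (e.g. the `1/f` background slope).
#'
#' @param epochs a `meg_epochs` object.
#' @return data.frame with `freq` (Hz, DC through Nyquist) and `power`.
#' @export
psd_check <- function(epochs) {
  d <- dim(epochs$data)
  if (any(d == 0)) stop("empty epochs")
  nt <- d[3L]
  nb <- nt %/% 2 + 1L
  acc <- numeric(nb)
  for (tr in seq_len(d[1L])) {
    m <- matrix(epochs$data[tr, , ], nrow = d[2L])   # [channels x times]
    sp <- stats::mvfft(t(m))
    acc <- acc + rowMeans(Mod(sp[seq_len(nb), , drop = FALSE])^2) / nt
  }
  data.frame(freq = (0:(nb - 1L)) * epochs$sfreq / nt,
             power = acc / d[1L])
}

#' Ready-made generator configurations for the package's study conditions
#'
#' Four named conditions used throughout the documentation and tests:
#' \describe{
#'   \item{`"standard"`}{8 classes, 20 trials/class, 10 sites, 100 Hz,
#'     0.9 s epochs, `1/f` background; one strong burst (snr 5) at
#'     100--200 ms, 10 Hz carrier, sites 2--3.}
#'   \item{`"chance"`}{the same with `snr = 0`: no class signal at all.}
#'   \item{`"adversarial"`}{the standard burst plus 20 high-variance
#'     non-discriminative spatial components orthogonal to it, so that
#'     variance-ranked channel truncation discards the signal.}
#'   \item{`"two_window"`}{two bursts in disjoint windows (100--200 ms at
#'     10 Hz on sites 2--3; 500--600 ms at 6 Hz on sites 7--8) at moderate
#'     snr 3, so full-epoch decoding can integrate evidence no single
#'     window contains.}
#' }
#'
#' @param type one of `"standard"`, `"chance"`, `"adversarial"`,
#'   `"two_window"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
benchmark_config <- function(type = c("standard", "chance", "adversarial",
                                      "two_window"),
                             seed = 1L, ...) {
  type <- match.arg(type)
  # Evoked cascade emulating a visual response: a dominant early component
  # (100--200 ms, 10 Hz, sites 2--3) followed by weaker, slower components
  # on partially overlapping sites -- gives the smooth temporal and spatial
  # gradients seen in real accuracy profiles while keeping the dominant
  # component unambiguous.
  cascade <- list(
    planted_pattern(center_time = 0.15, duration = 0.1, carrier_freq = 10,
                    sites = c(2L, 3L), amplitude = 1),
    planted_pattern(center_time = 0.325, duration = 0.3, carrier_freq = 10,
                    sites = c(3L, 4L), amplitude = 0.4),
    planted_pattern(center_time = 0.55, duration = 0.3, carrier_freq = 4,
                    sites = c(1L, 2L), amplitude = 0.25),
    planted_pattern(center_time = 0.675, duration = 0.35, carrier_freq = 10,
                    sites = c(5L, 6L), amplitude = 0.2))
  burst <- cascade[[1L]]
  # complementary loadings for the two-window condition: each burst only
  # separates one half of the classes (the other half shares one profile),
  # so no single window carries full class information but the full epoch
  # does -- the mechanism by which full-epoch decoding wins.
  half_informative <- function(informative, n_classes = 8L, n_ch = 6L,
                               rng) {
    cl <- matrix(rng$rnorm(n_classes * n_ch), n_classes)
    shared <- rng$rnorm(n_ch)
    cl[setdiff(seq_len(n_classes), informative), ] <-
      matrix(shared, length(setdiff(seq_len(n_classes), informative)),
             n_ch, byrow = TRUE)
    cl / sqrt(rowSums(cl^2) / n_ch)
  }
  rng <- local_rng(seed)
  args <- switch(type,
    standard = list(snr = 5, patterns = cascade,
                    n_trials_per_class = 30L),
    chance = list(snr = 0, patterns = cascade),
    adversarial = list(snr = 5, patterns = list(burst),
                       adversarial_variance = 16, n_adversarial = 20L),
    two_window = list(snr = 3, patterns = list(
      planted_pattern(center_time = 0.15, duration = 0.1,
                      carrier_freq = 10, sites = c(2L, 3L),
                      class_loadings = half_informative(1:4, rng = rng)),
      planted_pattern(center_time = 0.55, duration = 0.1,
                      carrier_freq = 6, sites = c(7L, 8L),
                      class_loadings = half_informative(5:8, rng = rng))))
  )
  do.call(sim_config, utils::modifyList(c(args, list(seed = seed)),
                                        list(...)))
}
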