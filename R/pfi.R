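#' Permutation plan for feature-importance runs
#'
#' @param n_permutations number of independent permutation repetitions per
#'   feature block (default 10). One permutation is drawn per (block,
#'   repetition) and applied to all evaluated trials, so repetitions are
#'   interpretable as plan-level samples; per-repetition losses are
#'   retained for confidence intervals.
#' @param seed integer seed; a fixed plan gives bit-identical maps.
#' @return A `pfi_plan` list.
#' @export
pfi_plan <- function(n_permutations = 10L, seed = 1L) {
  stopifnot(n_permutations >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "pfi_plan")
}

model_accuracy <- function(model, data, labels) {
  mean(predict(model, data) == labels)
}

new_pfi_map <- function(df, type, baseline) {
  structure(df, type = type, baseline = baseline,
            class = c("meg_pfi", "data.frame"))
}

#' @export
print.meg_pfi <- function(x, ...) {
  cat("<meg_pfi> type = ", attr(x, "type"), ", baseline accuracy = ",
      signif(attr(x, "baseline"), 3), ", ",
      max(x$rep), " permutation repetition(s)\n", sep = "")
  invisible(x)
}

#' Summarise a PFI map across permutation repetitions
#'
#' @param map a `meg_pfi` map.
#' @param level confidence level of the percentile interval across
#'   repetitions.
#' @return data.frame with the coordinate columns, `mean_loss`, `lo`, `hi`.
#' @export
pfi_summary <- function(map, level = 0.95) {
  coord <- setdiff(names(map), c("rep", "loss"))
  key <- interaction(map[coord], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(map)), key), function(i) {
    row <- map[i[1L], coord, drop = FALSE]
    q <- stats::quantile(map$loss[i],
                         c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    cbind(row, mean_loss = mean(map$loss[i]), lo = q[1L], hi = q[2L])
  }))
  rownames(agg) <- NULL
  agg[do.call(order, agg[coord]), , drop = FALSE]
}

#' Temporal permutation feature importance
#'
#' For each sliding time window, channels are permuted jointly across the
#' whole window (one random channel reordering per window and repetition,
#' applied at every timepoint inside the window and to all evaluated
#' trials; the rest of the trial is untouched). The drop from the baseline
#' validation accuracy measures how much discriminative information the
#' window carries. With `per_timepoint = TRUE` an independent channel
#' permutation is drawn for every timepoint in the window instead.
#'
#' @param model a decoder whose [predict()] accepts a raw
#'   `[n x channels x times]` array (e.g. [fit_decoder()] output).
#' @param epochs a [meg_epochs()] object in original sensor space.
#' @param idx trial indices to evaluate (typically the validation set).
#' @param window window length in samples (default 100 ms worth).
#' @param step window hop in samples.
#' @param plan a [pfi_plan()].
#' @param per_timepoint draw an independent permutation per timepoint.
#' @return A `meg_pfi` data.frame with `center_s`, `rep`, `loss`; attribute
#'   `baseline` holds the undisrupted accuracy.
#' @export
temporal_pfi <- function(model, epochs, idx,
                         window = round(0.1 * epochs$sfreq), step = 1L,
                         plan = pfi_plan(), per_timepoint = FALSE) {
  d <- dim(epochs$data)
  if (window > d[3L]) stop("window longer than epoch")
  spec <- sliding_windows(d[3L], window, step)
  if (spec$n_windows < 1) stop("no windows; epoch too short")
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  baseline <- model_accuracy(model, data, labels)
  rng <- local_rng(plan$seed)
  out <- vector("list", plan$n_permutations * spec$n_windows)
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (w in seq_len(spec$n_windows)) {
      sel <- window_samples(spec, w)
      x2 <- data
      if (per_timepoint) {
        for (t in sel) {
          perm <- rng$sample(d[2L])
          x2[, , t] <- data[, perm, t]
        }
      } else {
        perm <- rng$sample(d[2L])
        x2[, , sel] <- data[, perm, sel]
      }
      r <- r + 1L
      out[[r]] <- data.frame(
        center_s = window_centers_s(spec, epochs)[w], rep = rep_i,
        loss = baseline - model_accuracy(model, x2, labels))
    }
  }
  new_pfi_map(do.call(rbind, out), "temporal", baseline)
}

#' Spatial permutation feature importance
#'
#' For each sensor site, the timepoint order of each of its 3 co-located
#' channels is permuted independently (each channel gets its own random
#' time reordering), destroying that site's temporal structure while
#' leaving all other sites intact. The accuracy drop maps the site's
#' discriminative information.
#'
#' @inheritParams temporal_pfi
#' @return A `meg_pfi` data.frame with `site`, `rep`, `loss`.
#' @export
spatial_pfi <- function(model, epochs, idx, plan = pfi_plan()) {
  layout <- epochs$layout
  if (is.null(layout)) stop("epochs carry no sensor layout")
  d <- dim(epochs$data)
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  baseline <- model_accuracy(model, data, labels)
  rng <- local_rng(plan$seed)
  out <- vector("list", plan$n_permutations * layout$n_sites)
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (s in seq_len(layout$n_sites)) {
      x2 <- data
      for (ch in layout$site_channels[[s]]) {
        perm <- rng$sample(d[3L])
        x2[, ch, ] <- data[, ch, perm]
      }
      r <- r + 1L
      out[[r]] <- data.frame(
        site = s, rep = rep_i,
        loss = baseline - model_accuracy(model, x2, labels))
    }
  }
  new_pfi_map(do.call(rbind, out), "spatial", baseline)
}

#' Spatiotemporal permutation feature importance
#'
#' Blocks span a site neighbourhood (the site plus its 3 nearest sites, 12
#' channels) and one time window; all values inside the block are shuffled
#' jointly (block flattened, permuted with one random ordering shared by
#' all trials, reshaped).
#'
#' @inheritParams temporal_pfi
#' @return A `meg_pfi` data.frame with `site`, `center_s`, `rep`, `loss`.
#' @export
spatiotemporal_pfi <- function(model, epochs, idx,
                               window = round(0.1 * epochs$sfreq),
                               step = 1L, plan = pfi_plan()) {
  layout <- epochs$layout
  if (is.null(layout)) stop("epochs carry no sensor layout")
  d <- dim(epochs$data)
  spec <- sliding_windows(d[3L], window, step)
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  n <- length(idx)
  baseline <- model_accuracy(model, data, labels)
  rng <- local_rng(plan$seed)
  centers <- window_centers_s(spec, epochs)
  out <- vector("list", plan$n_permutations * layout$n_sites * spec$n_windows)
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (s in seq_len(layout$n_sites)) {
      ch <- neighborhood_channels(layout, s)
      for (w in seq_len(spec$n_windows)) {
        sel <- window_samples(spec, w)
        block <- matrix(data[, ch, sel], nrow = n)   # [n x (|ch|*len)]
        perm <- rng$sample(ncol(block))
        x2 <- data
        x2[, ch, sel] <- array(block[, perm],
                               dim = c(n, length(ch), length(sel)))
        r <- r + 1L
        out[[r]] <- data.frame(
          site = s, center_s = centers[w], rep = rep_i,
          loss = baseline - model_accuracy(model, x2, labels))
      }
    }
  }
  new_pfi_map(do.call(rbind, out), "spatiotemporal", baseline)
}

# ---- spectral machinery -----------------------------------------------

# band definitions -> list of DFT bin index vectors (0-based bins) and centers
resolve_bands <- function(bands, n_times, sfreq) {
  nyq_bin <- n_times %/% 2
  freqs <- (0:nyq_bin) * sfreq / n_times
  if (is.null(bands)) {
    list(bins = as.list(0:nyq_bin), centers = freqs)
  } else {
    # half-open [lo, hi) so adjacent bands never share a bin; the Nyquist
    # frequency itself is kept by a band ending exactly there
    bins <- lapply(bands, function(b) {
      if (b[1L] < 0 || b[2L] > sfreq / 2) stop("band outside [0, Nyquist]")
      keep <- freqs >= b[1L] & (freqs < b[2L] |
                                  (b[2L] == sfreq / 2 & freqs == b[2L]))
      which(keep) - 1L
    })
    list(bins = bins,
         centers = vapply(bands, function(b) mean(b), numeric(1)))
  }
}

# Apply a channel permutation to DFT bins `bins` (0-based) of channels
# `ch_sel`, returning the resulting time-domain delta added to `data`.
# fc: complex array [n, n_times, n_channels] of per-channel DFTs.
spectral_permute <- function(data, fc, bins, ch_sel, perm) {
  d <- dim(data); n <- d[1L]; nt <- d[3L]
  x2 <- data
  tt <- seq_len(nt) - 1L
  for (b in bins) {
    scale <- if (b == 0L || (nt %% 2L == 0L && b == nt %/% 2L))
      1 / nt else 2 / nt
    basis <- exp(2i * pi * b * tt / nt) * scale       # [nt]
    dF <- fc[, b + 1L, ch_sel[perm], drop = FALSE] -
      fc[, b + 1L, ch_sel, drop = FALSE]              # [n, 1, |ch|]
    dF <- matrix(dF, nrow = n)                        # [n x |ch|]
    for (tr in seq_len(n)) {
      delta <- Re(outer(dF[tr, ], basis))             # [|ch| x nt]
      x2[tr, ch_sel, ] <- x2[tr, ch_sel, ] + delta
    }
  }
  x2
}

# per-channel DFT of all trials: complex array [n, n_times, n_channels]
trial_dfts <- function(data) {
  d <- dim(data)
  fc <- array(complex(real = 0), dim = c(d[1L], d[3L], d[2L]))
  for (tr in seq_len(d[1L]))
    fc[tr, , ] <- stats::mvfft(t(matrix(data[tr, , ], nrow = d[2L])))
  fc
}

#' Spectral permutation feature importance
#'
#' Each trial and channel is Fourier transformed over the full epoch (DFT
#' length = epoch length, no padding); for each frequency band, the
#' coefficients of all bins in the band are permuted across channels (one
#' random channel reordering per band and repetition, conjugate-symmetric
#' bins moved consistently so the inverse transform stays real), the trial
#' is inverse transformed, and the accuracy drop recorded.
#'
#' @inheritParams temporal_pfi
#' @param bands list of `c(lo, hi)` frequency intervals in Hz, or `NULL`
#'   (default) for one band per DFT bin from DC to Nyquist.
#' @param channels optional channel subset the permutation is restricted
#'   to (used by [spatiospectral_pfi()]).
#' @return A `meg_pfi` data.frame with `band_hz` (band centre), `rep`,
#'   `loss`.
#' @export
spectral_pfi <- function(model, epochs, idx, bands = NULL,
                         plan = pfi_plan(), channels = NULL) {
  d <- dim(epochs$data)
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  baseline <- model_accuracy(model, data, labels)
  bd <- resolve_bands(bands, d[3L], epochs$sfreq)
  ch_sel <- if (is.null(channels)) seq_len(d[2L]) else channels
  fc <- trial_dfts(data)
  rng <- local_rng(plan$seed)
  out <- vector("list", plan$n_permutations * length(bd$bins))
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (bi in seq_along(bd$bins)) {
      perm <- rng$sample(length(ch_sel))
      x2 <- spectral_permute(data, fc, bd$bins[[bi]], ch_sel, perm)
      r <- r + 1L
      out[[r]] <- data.frame(
        band_hz = bd$centers[bi], rep = rep_i,
        loss = baseline - model_accuracy(model, x2, labels))
    }
  }
  new_pfi_map(do.call(rbind, out), "spectral", baseline)
}

#' Spatio-spectral permutation feature importance
#'
#' Spectral PFI restricted to one site neighbourhood (site + 3 nearest
#' sites, 12 channels) at a time: the band's Fourier coefficients are
#' permuted only among those channels, mapping which sites carry the
#' band's discriminative content.
#'
#' @inheritParams spectral_pfi
#' @return A `meg_pfi` data.frame with `site`, `band_hz`, `rep`, `loss`.
#' @export
spatiospectral_pfi <- function(model, epochs, idx, bands = NULL,
                               plan = pfi_plan()) {
  layout <- epochs$layout
  if (is.null(layout)) stop("epochs carry no sensor layout")
  d <- dim(epochs$data)
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  baseline <- model_accuracy(model, data, labels)
  bd <- resolve_bands(bands, d[3L], epochs$sfreq)
  fc <- trial_dfts(data)
  rng <- local_rng(plan$seed)
  out <- vector("list",
                plan$n_permutations * layout$n_sites * length(bd$bins))
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (s in seq_len(layout$n_sites)) {
      ch <- neighborhood_channels(layout, s)
      for (bi in seq_along(bd$bins)) {
        perm <- rng$sample(length(ch))
        x2 <- spectral_permute(data, fc, bd$bins[[bi]], ch, perm)
        r <- r + 1L
        out[[r]] <- data.frame(
          site = s, band_hz = bd$centers[bi], rep = rep_i,
          loss = baseline - model_accuracy(model, x2, labels))
      }
    }
  }
  new_pfi_map(do.call(rbind, out), "spatiospectral", baseline)
}

# ---- STFT machinery ---------------------------------------------------

#' Short-time Fourier transform with maximal overlap
#'
#' Hamming-windowed STFT with a hop of 1 sample. [istft()] reconstructs
#' the signal by weighted overlap-add (synthesis window = analysis window,
#' normalised by the summed squared window), which is exact for any
#' positive window at hop 1.
#'
#' @param x numeric vector.
#' @param window_len window length in samples.
#' @return `stft()`: complex matrix `[n_frames x window_len]` (frame `f`
#'   starts at sample `f - 1`, 0-based start `f - 1`), with the window
#'   attached as attribute `window`.
#' @export
stft <- function(x, window_len) {
  n <- length(x)
  if (window_len > n) stop("window longer than signal")
  w <- as.numeric(signal::hamming(window_len))
  n_frames <- n - window_len + 1L
  frames <- vapply(seq_len(n_frames), function(f)
    x[f:(f + window_len - 1L)] * w, numeric(window_len))
  s <- t(stats::mvfft(frames))          # [n_frames x window_len]
  attr(s, "window") <- w
  attr(s, "n_times") <- n
  s
}

#' @rdname stft
#' @param s an `stft()` result (complex `[n_frames x window_len]`).
#' @return `istft()`: the reconstructed real signal.
#' @export
istft <- function(s) {
  w <- attr(s, "window")
  n <- attr(s, "n_times")
  L <- length(w)
  n_frames <- nrow(s)
  num <- numeric(n); den <- numeric(n)
  frames_t <- Re(stats::mvfft(t(s), inverse = TRUE)) / L  # [L x n_frames]
  for (f in seq_len(n_frames)) {
    sel <- f:(f + L - 1L)
    num[sel] <- num[sel] + w * frames_t[, f]
    den[sel] <- den[sel] + w^2
  }
  num / den
}

#' Temporo-spectral permutation feature importance
#'
#' Each channel's full epoch is short-time Fourier transformed (Hamming
#' window, hop 1 sample); for each (frequency band, time window) the
#' band's coefficients are permuted across channels in the window and its
#' immediate neighbours (frames `w - 1, w, w + 1`, clamped at the epoch
#' edges, which smooths the temporal profile), the epoch is inverse
#' transformed by weighted overlap-add, and the accuracy drop recorded.
#' With a 10-sample window at 100 Hz the band centres are
#' 0, 10, ..., 50 Hz; the 0 Hz band carries only the true within-window
#' mean.
#'
#' @inheritParams temporal_pfi
#' @param stft_len STFT window length in samples (default 100 ms worth).
#' @return A `meg_pfi` data.frame with `center_s`, `band_hz`, `rep`,
#'   `loss`.
#' @export
temporospectral_pfi <- function(model, epochs, idx,
                                stft_len = round(0.1 * epochs$sfreq),
                                plan = pfi_plan()) {
  d <- dim(epochs$data)
  nt <- d[3L]
  if (stft_len > nt) stop("STFT window longer than epoch")
  data <- epochs$data[idx, , , drop = FALSE]
  labels <- epochs$labels[idx]
  n <- dim(data)[1L]; nch <- d[2L]
  baseline <- model_accuracy(model, data, labels)

  w <- as.numeric(signal::hamming(stft_len))
  n_frames <- nt - stft_len + 1L
  # forward STFT of every trial/channel: complex [n, n_frames, stft_len, ch]
  S <- array(complex(real = 0), dim = c(n, n_frames, stft_len, nch))
  for (tr in seq_len(n)) for (c in seq_len(nch)) {
    st <- stft(data[tr, c, ], stft_len)
    S[tr, , , c] <- st
  }
  den <- numeric(nt)
  for (f in seq_len(n_frames)) {
    sel <- f:(f + stft_len - 1L)
    den[sel] <- den[sel] + w^2
  }

  nyq_bin <- stft_len %/% 2
  band_centers <- (0:nyq_bin) * epochs$sfreq / stft_len
  tt <- seq_len(stft_len) - 1L
  centers_s <- epochs$t0 + ((seq_len(n_frames) - 1L) + stft_len / 2) /
    epochs$sfreq
  rng <- local_rng(plan$seed)
  out <- vector("list", plan$n_permutations * n_frames * (nyq_bin + 1L))
  r <- 0L
  for (rep_i in seq_len(plan$n_permutations)) {
    for (b in 0:nyq_bin) {
      scale <- if (b == 0L || (stft_len %% 2L == 0L && b == nyq_bin))
        1 / stft_len else 2 / stft_len
      basis <- exp(2i * pi * b * tt / stft_len) * scale  # [stft_len]
      for (f in seq_len(n_frames)) {
        perm <- rng$sample(nch)
        frames_mod <- intersect((f - 1L):(f + 1L), seq_len(n_frames))
        x2 <- data
        for (fm in frames_mod) {
          sel <- fm:(fm + stft_len - 1L)
          for (tr in seq_len(n)) {
            dF <- S[tr, fm, b + 1L, perm] - S[tr, fm, b + 1L, ]  # [nch]
            delta <- Re(outer(basis, dF))                # [stft_len x nch]
            x2[tr, , sel] <- x2[tr, , sel] +
              t(delta * (w / den[sel]))
          }
        }
        r <- r + 1L
        out[[r]] <- data.frame(
          center_s = centers_s[f], band_hz = band_centers[b + 1L],
          rep = rep_i,
          loss = baseline - model_accuracy(model, x2, labels))
      }
    }
  }
  new_pfi_map(do.call(rbind, out), "temporospectral", baseline)
}
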