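# Interictal iEEG band-power pipeline: preprocessing, Welch spectra,
# relative band power, contact-to-ROI assignment, regional reduction.

#' Construct a multichannel recording
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_ids character vector of channel identifiers.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_ids = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop_config("recording contains missing samples")
  if (fs <= 0) stop_config("sampling rate must be positive")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data)) {
    stop_shape("channel_ids length does not match number of rows")
  }
  structure(list(data = data, fs = fs, channel_ids = channel_ids),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Downsample and re-reference a recording
#'
#' Anti-alias filters and resamples the recording to `target_rate`, then
#' applies a common average reference (the per-sample mean across retained
#' channels is subtracted from every channel). Upsampling is refused.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate target sampling rate in Hz (default 200).
#' @param car apply the common average reference (default TRUE).
#' @return A preprocessed `eeg_recording` at `target_rate`.
#' @export
preprocess_recording <- function(rec, target_rate = 200, car = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < target_rate) {
    stop_config("sampling rate ", rec$fs, " Hz below target ", target_rate,
                " Hz; upsampling is not supported")
  }
  x <- rec$data
  if (rec$fs > target_rate) {
    ratio <- rec$fs / target_rate
    if (abs(ratio - round(ratio)) < 1e-9) {
      # integer decimation: zero-phase Butterworth anti-alias filter
      # (flat passband) followed by subsampling
      bf <- signal::butter(8, 0.8 / ratio)
      x <- t(apply(x, 1, function(ch)
        signal::filtfilt(bf, ch)[seq(1, length(ch), by = round(ratio))]))
    } else {
      # rational resampling with polyphase anti-alias filtering
      frac <- .rat_approx(target_rate / rec$fs)
      x <- t(apply(x, 1, function(ch) signal::resample(ch, frac[1], frac[2])))
    }
  }
  if (car && nrow(x) >= 1) {
    x <- sweep(x, 2, colMeans(x))
  }
  eeg_recording(x, target_rate, rec$channel_ids)
}

.rat_approx <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop_config("cannot express resampling ratio ", r, " as a small rational")
}

#' Extract a contiguous analysis epoch
#'
#' Takes a contiguous segment of the recording (default 70 s). If seizure
#' times are supplied, the epoch must start at least `min_postseizure_s`
#' after the most recent seizure.
#'
#' @param rec an [eeg_recording()].
#' @param length_s epoch length in seconds (default 70).
#' @param offset_s start offset in seconds (default 0).
#' @param seizure_times_s optional numeric vector of seizure times (s,
#'   same clock as the recording start at 0).
#' @param min_postseizure_s minimum postseizure interval (default 7200 s).
#' @return An `eeg_recording` of the requested length.
#' @export
extract_epoch <- function(rec, length_s = 70, offset_s = 0,
                          seizure_times_s = NULL, min_postseizure_s = 7200) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  i0 <- round(offset_s * rec$fs) + 1L
  i1 <- i0 + round(length_s * rec$fs) - 1L
  if (length_s <= 0 || i0 < 1 || i1 > n) {
    stop_config("epoch [", offset_s, ", ", offset_s + length_s,
                "] s outside recording of ", n / rec$fs, " s")
  }
  if (!is.null(seizure_times_s)) {
    gap <- offset_s - seizure_times_s
    bad <- gap > 0 & gap < min_postseizure_s
    if (any(bad)) {
      stop_config("epoch starts ", round(min(gap[bad])), " s after a seizure; ",
                  "at least ", min_postseizure_s, " s required")
    }
  }
  eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$fs, rec$channel_ids)
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram PSD estimate: the signal is segmented into
#' `window_s`-second windows with `overlap_s` seconds of overlap, each
#' segment is mean-detrended and Hamming-tapered, and the one-sided
#' periodograms are averaged. With 2-s windows at 200 Hz the frequency
#' resolution is 0.5 Hz. The estimate is a density (units^2/Hz): summing
#' `psd * df` over all bins recovers the signal variance.
#'
#' @param rec an `eeg_recording` (typically an extracted epoch).
#' @param window_s segment length in seconds (default 2).
#' @param overlap_s segment overlap in seconds (default 1).
#' @return A list with `freq` (Hz) and `psd` (channels x frequencies).
#' @export
welch_psd <- function(rec, window_s = 2, overlap_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  nwin <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  if (step < 1 || nwin < 2) stop_config("invalid window/overlap settings")
  n <- ncol(rec$data)
  if (n < nwin) stop_config("epoch shorter than one Welch window")
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- signal::hamming(nwin)
  U <- sum(w^2)                      # window energy for density scaling
  nfreq <- nwin %/% 2 + 1L
  freq <- (seq_len(nfreq) - 1L) * fs / nwin
  psd <- matrix(0, nrow = nrow(rec$data), ncol = nfreq)
  for (s in starts) {
    seg <- rec$data[, s:(s + nwin - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    X <- t(apply(seg, 1, fft))[, seq_len(nfreq), drop = FALSE]
    if (nrow(rec$data) == 1L) X <- matrix(X, nrow = 1)
    P <- (Mod(X)^2) / (fs * U)
    # one-sided: double interior bins (not DC, not Nyquist)
    interior <- 2:(nfreq - if (nwin %% 2 == 0) 1L else 0L)
    P[, interior] <- 2 * P[, interior]
    psd <- psd + P
  }
  psd <- psd / length(starts)
  rownames(psd) <- rec$channel_ids
  list(freq = freq, psd = psd, fs = fs, df = fs / nwin)
}

#' Per-contact band powers
#'
#' Integrates a Welch PSD over the five canonical bands (half-open
#' intervals: a shared edge belongs to the upper band), normalizes each
#' contact's band powers to sum to one, and records log10 relative power
#' for normative z-scoring.
#'
#' @param spec output of [welch_psd()].
#' @param bands a band table as from [canonical_bands()].
#' @return A data.frame with columns `contact_id`, `band`, `rel_power`,
#'   `log_power` (log10 of relative power).
#' @export
band_powers <- function(spec, bands = canonical_bands()) {
  if (max(spec$freq) < max(bands$hi)) {
    stop_config("PSD covers up to ", max(spec$freq), " Hz; bands require ",
                max(bands$hi), " Hz")
  }
  abs_power <- sapply(seq_len(nrow(bands)), function(b) {
    sel <- spec$freq >= bands$lo[b] & spec$freq < bands$hi[b]
    rowSums(spec$psd[, sel, drop = FALSE]) * spec$df
  })
  if (is.null(dim(abs_power))) abs_power <- matrix(abs_power, nrow = 1)
  colnames(abs_power) <- bands$band
  tot <- rowSums(abs_power)
  if (any(tot <= 0)) stop_config("zero total band power in at least one contact")
  rel <- abs_power / tot
  data.frame(
    contact_id = rep(rownames(spec$psd), times = nrow(bands)),
    band = rep(bands$band, each = nrow(rel)),
    rel_power = as.vector(rel),
    log_power = as.vector(log10(rel)),
    stringsAsFactors = FALSE
  )
}

#' Assign electrode contacts to parcellation regions
#'
#' Each contact is assigned to the region with the nearest representative
#' point (Euclidean distance in mm). Contacts more than `max_dist_mm` from
#' every region are excluded; white-matter contacts more than
#' `wm_gm_max_mm` from the nearest gray matter are excluded; contacts
#' flagged as artifactual are excluded.
#'
#' @param contacts data.frame with columns `contact_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `tissue` (`"GM"`/`"WM"`), optional logical `artifact`.
#' @param geometry named list (by ROI id) of n x 3 matrices of
#'   representative GM points in mm, or a data.frame with columns
#'   `roi_id`, `x_mm`, `y_mm`, `z_mm`.
#' @param max_dist_mm exclusion radius for any region (default 5).
#' @param wm_gm_max_mm exclusion radius for WM contacts to GM (default 2).
#' @return data.frame: `contact_id`, `roi_id` (NA if excluded),
#'   `distance_mm`, `excluded_reason` in `none`, `far_from_any_region`,
#'   `wm_far_from_gm`, `artifact`.
#' @export
assign_contacts <- function(contacts, geometry, max_dist_mm = 5,
                            wm_gm_max_mm = 2) {
  if (is.data.frame(geometry)) {
    geometry <- split(as.matrix(geometry[, c("x_mm", "y_mm", "z_mm")]),
                      geometry$roi_id)
    geometry <- lapply(geometry, function(m) matrix(m, ncol = 3))
  }
  if (length(geometry) == 0) stop_config("empty parcellation geometry")
  rois <- names(geometry)
  pts <- as.matrix(contacts[, c("x_mm", "y_mm", "z_mm")])
  artifact <- contacts$artifact %||% rep(FALSE, nrow(contacts))

  dmin <- sapply(geometry, function(g) {
    # squared distances contact x roi-point, min over points
    d2 <- outer(rowSums(pts^2), rowSums(g^2), `+`) - 2 * pts %*% t(g)
    sqrt(pmax(apply(d2, 1, min), 0))
  })
  if (is.null(dim(dmin))) dmin <- matrix(dmin, nrow = nrow(pts))
  nearest <- apply(dmin, 1, which.min)
  dist <- dmin[cbind(seq_len(nrow(pts)), nearest)]

  reason <- rep("none", nrow(pts))
  reason[artifact] <- "artifact"
  reason[reason == "none" & dist > max_dist_mm] <- "far_from_any_region"
  is_wm <- contacts$tissue == "WM"
  reason[reason == "none" & is_wm & dist > wm_gm_max_mm] <- "wm_far_from_gm"

  data.frame(
    contact_id = contacts$contact_id,
    roi_id = ifelse(reason == "none", rois[nearest], NA_character_),
    distance_mm = dist,
    excluded_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Regional band power from assigned contacts
#'
#' Averages the log10 relative band power of a patient's retained contacts
#' within each region. Regions without any assigned contact are absent
#' from the output; coverage is handled downstream as missing, never as
#' zero abnormality.
#'
#' @param bp per-contact band powers from [band_powers()].
#' @param assignment contact assignment from [assign_contacts()].
#' @return data.frame: `roi_id`, `band`, `value` (mean log10 relative
#'   power), `n_contacts`.
#' @export
regional_band_power <- function(bp, assignment) {
  keep <- assignment[assignment$excluded_reason == "none", ]
  m <- merge(bp, keep[, c("contact_id", "roi_id")], by = "contact_id")
  if (nrow(m) == 0) {
    return(data.frame(roi_id = character(), band = character(),
                      value = numeric(), n_contacts = integer()))
  }
  agg <- aggregate(log_power ~ roi_id + band, data = m, FUN = mean)
  cnt <- aggregate(contact_id ~ roi_id + band, data = m, FUN = length)
  out <- merge(agg, cnt, by = c("roi_id", "band"))
  names(out)[names(out) == "log_power"] <- "value"
  names(out)[names(out) == "contact_id"] <- "n_contacts"
  out[order(out$roi_id, out$band), ]
}

#' Regional iEEG abnormality score
#'
#' Reduces per-band z-scores to one abnormality score per region: the
#' maximum absolute z across frequency bands, recording the achieving band
#' and its signed z.
#'
#' @param zmap a z-score map (data.frame with `roi_id`, `band`, `z`) for
#'   one patient's iEEG modality.
#' @return data.frame: `roi_id`, `score` (max |z|), `band`, `z_signed`.
#' @export
ieeg_abnormality <- function(zmap) {
  zmap <- zmap[!is.na(zmap$z), ]
  if (nrow(zmap) == 0) {
    return(data.frame(roi_id = character(), score = numeric(),
                      band = character(), z_signed = numeric()))
  }
  out <- do.call(rbind, lapply(split(zmap, zmap$roi_id), function(d) {
    i <- which.max(abs(d$z))
    data.frame(roi_id = d$roi_id[1], score = abs(d$z[i]),
               band = d$band[i], z_signed = d$z[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
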