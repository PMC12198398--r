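# Minimal EEG conditioning: zero-phase band-pass, mastoid-pair
# re-referencing, fixed-length epoching and peak-to-peak artifact rejection.

#' Construct an EEGRecording
#'
#' @param data channels x samples matrix, microvolts.
#' @param rate sampling rate, Hz.
#' @param subject subject id.
#' @param channels channel names (default Ch1..ChN).
#' @param markers data.frame (label, sample), 1-based sample indices.
#' @return an [EEGRecording-class].
#' @export
eegRecording <- function(data, rate, subject = "S001", channels = NULL,
                         markers = data.frame(label = character(0),
                                              sample = integer(0))) {
  if (is.null(channels)) channels <- sprintf("Ch%d", seq_len(nrow(data)))
  new("EEGRecording", subject = subject, rate = rate, data = data,
      channels = channels, markers = markers)
}

#' Band-pass filter and re-reference an EEG recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per channel, then subtracts the arithmetic mean of the two reference
#' channels from every channel.
#'
#' @param rec an [EEGRecording-class].
#' @param band (low, high) cutoff frequencies in Hz; default `c(0.5, 45)`.
#'   `NULL` skips filtering (re-reference only).
#' @param refChannels names or indices of the two reference channels;
#'   `NULL` skips re-referencing.
#' @param order Butterworth order (default 4).
#' @return the filtered recording.
#' @export
filterAndRereference <- function(rec, band = c(0.5, 45), refChannels = NULL,
                                 order = 4L) {
  stopifnot(is(rec, "EEGRecording"))
  out <- rec@data
  if (!is.null(band)) {
    nyq <- rec@rate / 2
    if (band[1] <= 0 || band[2] >= nyq)
      stop("band edges must lie strictly inside (0, rate/2)")
    bf <- signal::butter(order, band / nyq, type = "pass")
    for (ch in seq_len(nrow(out)))
      out[ch, ] <- signal::filtfilt(bf, out[ch, ])
  }
  if (!is.null(refChannels)) {
    idx <- if (is.character(refChannels)) match(refChannels, rec@channels)
           else as.integer(refChannels)
    if (anyNA(idx) || length(idx) != 2L)
      stop("refChannels must name two existing channels")
    ref <- colMeans(out[idx, , drop = FALSE])
    out <- sweep(out, 2L, ref)
  }
  rec@data <- out
  rec
}

#' Epoch an EEG recording and flag artifacts
#'
#' Segments the recording into consecutive non-overlapping epochs of
#' `epochLen` seconds starting `pre` seconds before the onset marker (a
#' trailing partial epoch is dropped). A channel is bad within an epoch when
#' its peak-to-peak amplitude (max minus min) exceeds `p2pLimit`; an epoch is
#' bad when more than `maxBadChannels` channels are bad; the subject is
#' excluded when the bad-epoch fraction exceeds `maxBadFraction`. All three
#' comparisons are strict.
#'
#' @param rec an [EEGRecording-class].
#' @param onsetMarker marker label of the video onset.
#' @param pre seconds before the onset at which epoching starts
#'   (default 2.5).
#' @param epochLen epoch length in seconds (default 1).
#' @param p2pLimit peak-to-peak rejection limit, microvolts (default 100).
#' @param maxBadChannels per-epoch tolerated bad channels (default 3).
#' @param maxBadFraction tolerated bad-epoch fraction per subject
#'   (default 0.30).
#' @return an [EpochSet-class].
#' @export
epochAndReject <- function(rec, onsetMarker = "video_onset", pre = 2.5,
                           epochLen = 1, p2pLimit = 100,
                           maxBadChannels = 3L, maxBadFraction = 0.30) {
  stopifnot(is(rec, "EEGRecording"))
  hit <- which(rec@markers$label == onsetMarker)
  if (length(hit) == 0L) stop("onset marker '", onsetMarker, "' not found")
  onset <- rec@markers$sample[hit[1]]
  len <- round(epochLen * rec@rate)
  start <- onset - round(pre * rec@rate)
  if (start < 1L) stop("not enough data before the onset marker")
  nAvail <- ncol(rec@data) - start + 1L
  nEpochs <- nAvail %/% len
  if (nEpochs < 1L) stop("not enough data for a single epoch")
  nch <- nrow(rec@data)
  epochs <- array(NA_real_, c(nEpochs, nch, len))
  badChannel <- matrix(FALSE, nEpochs, nch,
                       dimnames = list(NULL, rec@channels))
  for (e in seq_len(nEpochs)) {
    idx <- start + (e - 1L) * len + seq_len(len) - 1L
    seg <- rec@data[, idx, drop = FALSE]
    epochs[e, , ] <- seg
    p2p <- apply(seg, 1L, function(v) max(v) - min(v))
    badChannel[e, ] <- p2p > p2pLimit
  }
  badEpoch <- rowSums(badChannel) > maxBadChannels
  excluded <- mean(badEpoch) > maxBadFraction
  new("EpochSet", epochs = epochs, badChannel = badChannel,
      badEpoch = badEpoch, excluded = excluded, rate = rec@rate)
}
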