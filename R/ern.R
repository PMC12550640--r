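# Response-locked ERP averaging and ERN peak selection.  An epoch set is a
# list: data [channels x time x trials] in microvolts, time_ms (strictly
# increasing, relative to the button response), channels, condition per
# trial ("inc_error" / "inc_correct"), srate.

#' Construct an epoch set
#' @param data numeric array channels x time x trials (microvolts)
#' @param time_ms time axis in ms relative to the response
#' @param channels channel names
#' @param condition per-trial condition, `"inc_error"` or `"inc_correct"`
#' @param srate sampling rate in Hz
#' @export
epoch_set <- function(data, time_ms, channels, condition, srate) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(channels),
            dim(data)[2] == length(time_ms),
            dim(data)[3] == length(condition))
  if (any(diff(time_ms) <= 0)) stop("time axis must be strictly increasing")
  if (any(!is.finite(data))) stop("epoch amplitudes must be finite")
  if (!all(condition %in% c("inc_error", "inc_correct"))) {
    stop("conditions must be inc_error / inc_correct")
  }
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 condition = condition, srate = srate), class = "epoch_set")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over a time window.
#'
#' @param epochs an [epoch_set()]
#' @param window length-2 ms interval (typically pre-response)
#' @export
baseline_correct <- function(epochs, window) {
  sel <- epochs$time_ms >= window[1] & epochs$time_ms <= window[2]
  if (!any(sel)) stop("baseline window does not intersect the time axis")
  base <- apply(epochs$data[, sel, , drop = FALSE], c(1, 3), mean)
  nt <- length(epochs$time_ms)
  epochs$data <- epochs$data -
    aperm(array(base, c(dim(base), nt)), c(1, 3, 2))
  epochs
}

#' Condition-average ERP
#' @param epochs an [epoch_set()]
#' @param condition condition label to average
#' @return list: `amplitude` (channels x time), `condition`, `n_trials`
#' @export
average_erp <- function(epochs, condition) {
  sel <- epochs$condition == condition
  if (!any(sel)) stop("no trials of condition ", condition)
  amp <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(amp) <- list(epochs$channels, NULL)
  structure(list(amplitude = amp, condition = condition, n_trials = sum(sel),
                 time_ms = epochs$time_ms, channels = epochs$channels),
            class = "erp_wave")
}

#' Error-minus-correct difference wave
#' @param err,corr `erp_wave`s on identical channels and time axes
#' @return channels x time matrix of differences (microvolts)
#' @export
difference_wave <- function(err, corr) {
  if (!identical(err$channels, corr$channels) ||
      !isTRUE(all.equal(err$time_ms, corr$time_ms))) {
    stop("ERP channel/time axes do not match")
  }
  structure(list(amplitude = err$amplitude - corr$amplitude,
                 time_ms = err$time_ms, channels = err$channels,
                 n_error = err$n_trials, n_correct = corr$n_trials),
            class = "diff_wave")
}

#' Locate the ERN peak
#'
#' Returns the time at which the cluster-mean difference wave is maximal in
#' the ERN sense, i.e. most negative (greatest negative polarization),
#' within a post-response search window.  Exact amplitude ties resolve to
#' the earliest time point so the result is deterministic.  Set
#' `polarity = "absolute"` to search on |amplitude| instead.
#'
#' @param diff a difference wave from [difference_wave()]
#' @param cluster channel subset to average (frontocentral by convention)
#' @param window length-2 ms search interval
#' @param polarity `"negative"` (default) or `"absolute"`
#' @return list: `latency_ms`, `amplitude_uv` (cluster mean at the peak)
#' @export
find_ern_peak <- function(diff, cluster, window = c(0, 100),
                          polarity = c("negative", "absolute")) {
  polarity <- match.arg(polarity)
  missing_ch <- setdiff(cluster, diff$channels)
  if (length(missing_ch)) {
    stop("cluster channel(s) absent: ", paste(missing_ch, collapse = ", "))
  }
  if (!length(cluster)) stop("cluster must be non-empty")
  tsel <- which(diff$time_ms >= window[1] & diff$time_ms <= window[2])
  if (!length(tsel)) stop("search window contains no samples")
  cm <- colMeans(diff$amplitude[cluster, tsel, drop = FALSE])
  crit <- if (polarity == "negative") cm else -abs(cm)
  k <- which(crit == min(crit))[1]        # earliest on ties
  list(latency_ms = diff$time_ms[tsel[k]], amplitude_uv = cm[k])
}

#' Per-subject/wave ERN peak table
#'
#' @param epoch_list nested list `epochs[[subject]][[wave]]` of epoch sets
#' @param cluster,window,baseline passed through to the waveform chain
#' @return data.frame: subject, wave, latency_ms, amplitude_uv,
#'   n_error_trials, n_correct_trials
#' @export
ern_peak_table <- function(epoch_list, cluster, window = c(0, 100),
                           baseline = c(-200, 0)) {
  rows <- list()
  for (subj in names(epoch_list)) for (wave in names(epoch_list[[subj]])) {
    ep <- baseline_correct(epoch_list[[subj]][[wave]], baseline)
    dw <- difference_wave(average_erp(ep, "inc_error"),
                          average_erp(ep, "inc_correct"))
    pk <- find_ern_peak(dw, cluster, window)
    rows[[length(rows) + 1]] <- data.frame(
      subject = subj, wave = wave, latency_ms = pk$latency_ms,
      amplitude_uv = pk$amplitude_uv, n_error_trials = dw$n_error,
      n_correct_trials = dw$n_correct)
  }
  do.call(rbind, rows)
}
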