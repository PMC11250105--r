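#' Convert effluent concentration to per-islet secretion rate
#'
#' Converts a perifusion trace measured as insulin concentration in the
#' column effluent (pmol/mL) to a per-islet secretion rate
#' (pmol/islet/min): `rate(t) = concentration(t) * flow_rate / islet_count`.
#' Already-normalized traces are returned unchanged (logged no-op).
#'
#' @param trace a `perifusion_trace`.
#' @param flow_rate perifusate flow in mL/min (defaults to the trace's own).
#' @param islet_count islets loaded on the column (defaults to the trace's).
#' @return The trace in pmol/islet/min units.
#' @examples
#' p <- canonical_protocols()$F
#' tr <- perifusion_trace("d1", "F", 0:63, rep(130, 64), "pmol/mL", p, 65, 0.4)
#' normalize_secretion(tr)$values[1]  # 130 * 0.4 / 65 = 0.8
#' @export
normalize_secretion <- function(trace, flow_rate = trace$flow_rate,
                                islet_count = trace$islet_count) {
  stopifnot(inherits(trace, "perifusion_trace"))
  if (trace$unit == "pmol/islet/min") {
    message("trace already normalized; returning unchanged")
    return(trace)
  }
  if (!is.finite(flow_rate) || flow_rate <= 0)
    stop("flow_rate must be > 0", call. = FALSE)
  if (!is.finite(islet_count) || islet_count <= 0)
    stop("islet_count must be > 0", call. = FALSE)
  trace$values <- trace$values * flow_rate / islet_count
  trace$unit <- "pmol/islet/min"
  trace$flow_rate <- flow_rate
  trace$islet_count <- islet_count
  trace
}

baseline_rate <- function(trace) {
  base <- trace$protocol[trace$protocol$baseline, , drop = FALSE]
  sel <- trace$time_min >= base$start_min & trace$time_min < base$end_min
  mean(trace$values[sel])
}

trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Baseline-subtracted segment AUC
#'
#' Trapezoidal integral of the secretion rate minus the baseline rate over
#' one protocol segment, in pmol/islet. The baseline is the mean rate over
#' the protocol's designated basal segment (`baseline_mode = "pre"`), or 0
#' (`"none"`, total AUC). Suppression below baseline yields negative area
#' and is preserved.
#'
#' @param trace normalized `perifusion_trace` (pmol/islet/min).
#' @param segment segment name, or a one-row segment data.frame with
#'   `start_min`/`end_min`.
#' @param baseline_mode `"pre"` (default) or `"none"`.
#' @param window optional numeric length-2 sub-window (absolute minutes)
#'   intersected with the segment.
#' @return AUC in pmol/islet.
#' @export
segment_auc <- function(trace, segment, baseline_mode = c("pre", "none"),
                        window = NULL) {
  stopifnot(inherits(trace, "perifusion_trace"))
  if (trace$unit != "pmol/islet/min")
    stop("trace must be normalized to pmol/islet/min first", call. = FALSE)
  baseline_mode <- match.arg(baseline_mode)
  if (is.character(segment)) segment <- protocol_segment(trace$protocol, segment)
  lo <- segment$start_min; hi <- segment$end_min
  if (!is.null(window)) { lo <- max(lo, window[1]); hi <- min(hi, window[2]) }
  if (lo < min(trace$time_min) || hi > max(trace$time_min) + 1)
    stop("segment outside trace time range", call. = FALSE)
  sel <- trace$time_min >= lo & trace$time_min <= hi
  if (sum(sel) < 2L) stop("need >= 2 samples in segment", call. = FALSE)
  b <- if (baseline_mode == "pre") baseline_rate(trace) else 0
  trapz(trace$time_min[sel], trace$values[sel] - b)
}

#' First- and second-phase AUC of a biphasic stimulation segment
#'
#' Splits a (>= 15 min) stimulation segment into the first phase (first
#' 15 min from the solution change) and the second phase (the remainder),
#' returning baseline-subtracted AUCs whose sum equals the full segment AUC
#' exactly (the trapezoid partition shares the boundary sample).
#'
#' @inheritParams segment_auc
#' @return Named numeric: `first_phase_auc`, `second_phase_auc`.
#' @export
phase_decomposition <- function(trace, segment, baseline_mode = c("pre", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  if (is.character(segment)) segment <- protocol_segment(trace$protocol, segment)
  if (segment$end_min - segment$start_min < 15)
    stop("segment shorter than 15 min: use segment_auc() (total mode) instead",
         call. = FALSE)
  split_t <- segment$start_min + 15
  c(first_phase_auc = segment_auc(trace, segment, baseline_mode,
                                  window = c(segment$start_min, split_t)),
    second_phase_auc = segment_auc(trace, segment, baseline_mode,
                                   window = c(split_t, segment$end_min)))
}

#' Peak secretion and time-to-peak within the first 15 min of a segment
#'
#' The peak is the largest sampled rate within the first 15 minutes after
#' the solution change (even for longer segments); ties are broken by the
#' earliest time. Time-to-peak is the offset from segment start in minutes.
#'
#' @inheritParams segment_auc
#' @return Named numeric: `peak_rate` (pmol/islet/min), `time_to_peak` (min).
#' @export
time_to_peak <- function(trace, segment) {
  stopifnot(inherits(trace, "perifusion_trace"))
  if (trace$unit != "pmol/islet/min")
    stop("trace must be normalized to pmol/islet/min first", call. = FALSE)
  if (is.character(segment)) segment <- protocol_segment(trace$protocol, segment)
  sel <- trace$time_min >= segment$start_min &
    trace$time_min < segment$start_min + 15
  if (sum(sel) < 2L) stop("need >= 2 samples in the first 15 min", call. = FALSE)
  tt <- trace$time_min[sel]; vv <- trace$values[sel]
  i <- which.max(vv)  # which.max returns the earliest maximum
  c(peak_rate = vv[i], time_to_peak = tt[i] - segment$start_min)
}

#' Build the donor-by-segment secretion feature table
#'
#' Extracts, for every donor and every non-baseline protocol segment, the
#' baseline-subtracted AUC, first/second phase AUCs (segments >= 15 min),
#' peak rate, time-to-peak, and the donor's baseline rate. Traces in
#' concentration units are normalized first. Donors missing an arm get
#' explicit rows with `NA` values and `missing = TRUE` rather than being
#' dropped.
#'
#' @param traces list of `perifusion_trace` objects (one per donor-arm).
#' @param protocols named list of `stimulus_protocol`s (one per arm);
#'   default [canonical_protocols()].
#' @param baseline_mode passed to [segment_auc()].
#' @return data.frame with one row per donor x segment:
#'   `donor_id`, `arm`, `segment`, `stimulus`, `auc`, `first_phase_auc`,
#'   `second_phase_auc`, `peak_rate`, `time_to_peak`, `baseline_rate`,
#'   `missing`.
#' @export
build_feature_table <- function(traces, protocols = canonical_protocols(),
                                baseline_mode = c("pre", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  keys <- vapply(traces, function(tr) paste(tr$donor_id, tr$arm), character(1))
  if (anyDuplicated(keys))
    stop("duplicate donor-arm trace: ", keys[duplicated(keys)][1], call. = FALSE)
  donors <- unique(vapply(traces, function(tr) tr$donor_id, character(1)))
  rows <- list()
  for (d in donors) {
    for (arm in names(protocols)) {
      proto <- protocols[[arm]]
      segs <- proto[!proto$baseline & proto$stimulus != "basal", , drop = FALSE]
      hit <- which(keys == paste(d, arm))
      tr <- if (length(hit)) traces[[hit]] else NULL
      if (!is.null(tr) && tr$unit == "pmol/mL")
        tr <- normalize_secretion(tr)
      for (i in seq_len(nrow(segs))) {
        seg <- segs[i, , drop = FALSE]
        if (is.null(tr)) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor_id = d, arm = arm, segment = seg$name, stimulus = seg$stimulus,
            auc = NA_real_, first_phase_auc = NA_real_,
            second_phase_auc = NA_real_, peak_rate = NA_real_,
            time_to_peak = NA_real_, baseline_rate = NA_real_, missing = TRUE)
          next
        }
        auc <- segment_auc(tr, seg, baseline_mode)
        ph <- if (seg$end_min - seg$start_min >= 15)
          phase_decomposition(tr, seg, baseline_mode)
        else c(first_phase_auc = NA_real_, second_phase_auc = NA_real_)
        pk <- time_to_peak(tr, seg)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_id = d, arm = arm, segment = seg$name, stimulus = seg$stimulus,
          auc = auc, first_phase_auc = unname(ph["first_phase_auc"]),
          second_phase_auc = unname(ph["second_phase_auc"]),
          peak_rate = unname(pk["peak_rate"]),
          time_to_peak = unname(pk["time_to_peak"]),
          baseline_rate = baseline_rate(tr), missing = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
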