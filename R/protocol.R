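#' Stimulus protocols for three-arm islet perifusion
#'
#' A `stimulus_protocol` is an ordered table of non-overlapping stimulus
#' segments applied to one perifusion column: a pre-stimulus basal recording
#' followed by nutrient and depolarization challenges. Exactly one segment is
#' designated as the baseline used for baseline subtraction.
#'
#' @param segments data.frame with columns `name`, `stimulus`, `start_min`,
#'   `end_min` and logical `baseline`. Times are minutes from the start of
#'   recording (after column equilibration, which is not recorded).
#' @return A `stimulus_protocol` object (validated data.frame).
#' @examples
#' p <- canonical_protocols()$G
#' p
#' @export
stimulus_protocol <- function(segments) {
  req <- c("name", "stimulus", "start_min", "end_min", "baseline")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("protocol needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  segments <- segments[order(segments$start_min), , drop = FALSE]
  if (any(segments$end_min <= segments$start_min))
    stop("protocol segments must have end_min > start_min", call. = FALSE)
  if (nrow(segments) > 1L &&
      any(segments$start_min[-1L] < segments$end_min[-nrow(segments)]))
    stop("protocol segments overlap", call. = FALSE)
  if (sum(segments$baseline) != 1L)
    stop("exactly one baseline segment required", call. = FALSE)
  rownames(segments) <- NULL
  class(segments) <- c("stimulus_protocol", "data.frame")
  segments
}

protocol_segment <- function(protocol, name) {
  i <- match(name, protocol$name)
  if (is.na(i)) stop("no segment named '", name, "' in protocol", call. = FALSE)
  protocol[i, , drop = FALSE]
}

#' Canonical three-arm perifusion protocol set
#'
#' The fixture protocol used throughout the package: each donor's islets are
#' run on three parallel columns. Arm G carries the glucose dose-response and
#' a terminal KCl depolarization; arm L carries leucine at basal (3 mM)
#' glucose and then leucine on top of 6 mM glucose; arm F carries the
#' oleate/palmitate challenge at basal glucose. Each arm starts with a 24-min
#' basal (3 mM glucose) recording; the 15 mM glucose segment is 40 min so the
#' first 15 min / remaining 25 min phase split applies. Sampling is every
#' minute.
#'
#' @return Named list of three `stimulus_protocol` objects (`G`, `L`, `F`).
#' @export
canonical_protocols <- function() {
  seg <- function(name, stimulus, start, end, baseline = FALSE)
    data.frame(name = name, stimulus = stimulus, start_min = start,
               end_min = end, baseline = baseline)
  list(
    G = stimulus_protocol(rbind(
      seg("basal",     "basal",     0,  24, TRUE),
      seg("glucose15", "glucose15", 24, 64),
      seg("washout",   "basal",     64, 79),
      seg("glucose6",  "glucose6",  79, 104),
      seg("kcl",       "kcl",       104, 114))),
    L = stimulus_protocol(rbind(
      seg("basal",      "basal",      0,  24, TRUE),
      seg("leucine",    "leucine",    24, 64),
      seg("washout",    "basal",      64, 79),
      seg("leu_plus_g6", "leu_plus_g6", 79, 104))),
    F = stimulus_protocol(rbind(
      seg("basal", "basal", 0, 24, TRUE),
      seg("fat",   "fat",   24, 64)))
  )
}

#' Read / write a protocol set as YAML
#'
#' @param path file path.
#' @param protocols named list of `stimulus_protocol` objects.
#' @return `read_protocols` returns the named list; `write_protocols` the
#'   path, invisibly.
#' @export
write_protocols <- function(protocols, path) {
  out <- lapply(protocols, function(p) {
    lapply(seq_len(nrow(p)), function(i) as.list(p[i, , drop = FALSE]))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_protocols
#' @export
read_protocols <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(arm) {
    stimulus_protocol(do.call(rbind, lapply(arm, as.data.frame)))
  })
}
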