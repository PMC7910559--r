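#' Episodic voltage-clamp recording
#'
#' Container for a set of current sweeps sharing a sampling interval and a
#' voltage protocol. Currents are in pA, voltages in mV, time in ms (0-based
#' at sweep start).
#'
#' @param dt sampling interval (ms).
#' @param current numeric matrix, samples x sweeps (pA).
#' @param voltage numeric matrix of the command waveform, same shape (mV).
#' @param solutions an [hv_solutions()].
#' @param protocol optional [hv_protocol()] the sweeps were acquired with.
#' @param labels free-text channel/condition tags.
#' @param seed integer provenance seed (NA if not simulated).
#' @return an object of class `hv_recording`.
#' @export
hv_recording <- function(dt, current, voltage, solutions = hv_solutions(),
                         protocol = NULL, labels = character(), seed = NA_integer_) {
  current <- as.matrix(current)
  voltage <- as.matrix(voltage)
  if (dt <= 0) stop("dt must be positive")
  if (ncol(current) < 1 || nrow(current) < 1) stop("recording needs at least one sweep with samples")
  if (!identical(dim(current), dim(voltage)))
    stop("current and command voltage must have identical dimensions")
  stopifnot(inherits(solutions, "hv_solutions"))
  structure(list(dt = dt, time = (seq_len(nrow(current)) - 1) * dt,
                 current = current, voltage = voltage, solutions = solutions,
                 protocol = protocol, labels = labels, seed = seed),
            class = "hv_recording")
}

#' @export
print.hv_recording <- function(x, ...) {
  cat(sprintf("hv_recording: %d sweep(s) x %d samples, dt = %g ms%s\n",
              ncol(x$current), nrow(x$current), x$dt,
              if (length(x$labels)) paste0(" [", paste(x$labels, collapse = ", "), "]") else ""))
  print(x$solutions)
  invisible(x)
}

#' Number of sweeps in a recording
#' @param recording an [hv_recording()].
#' @return integer sweep count.
#' @export
n_sweeps <- function(recording) ncol(recording$current)

.serialize_protocol <- function(p) {
  segs <- vapply(p$segments, function(s)
    sprintf("%s:%.17g:%.17g:%.17g", s$kind, s$V_start, s$V_end, s$duration),
    character(1))
  paste(segs, collapse = "|")
}

.parse_protocol <- function(txt, n_sweeps, sweep_increment, sweep_epoch, dt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  segs <- lapply(strsplit(txt, "|", fixed = TRUE)[[1]], function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(f) != 4) stop("malformed protocol descriptor: ", s)
    protocol_epoch(f[1], as.numeric(f[2]), as.numeric(f[3]), as.numeric(f[4]))
  })
  hv_protocol(segs, n_sweeps = n_sweeps, sweep_increment = sweep_increment,
              sweep_epoch = sweep_epoch, dt = dt)
}

#' Write a recording to the plain-text episodic trace format
#'
#' The format is UTF-8 text: `#key=value` header lines followed by one row
#' per sample with whitespace-separated columns `sweep_index` (0-based),
#' `time_ms`, `voltage_mV`, `current_pA`, sweeps concatenated in order.
#' Numbers are written at full double precision so that write/read
#' round-trips are exact. Required header keys: `format_version`, `dt`,
#' `units_current` (pA), `units_voltage` (mV), `pH_i`, `pH_o`,
#' `temperature_K`, `n_sweeps`.
#'
#' @param recording an [hv_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "hv_recording"))
  nsw <- ncol(recording$current)
  hdr <- c(
    "#format_version=1",
    sprintf("#dt=%.17g", recording$dt),
    "#units_current=pA",
    "#units_voltage=mV",
    sprintf("#pH_i=%.17g", recording$solutions$pH_i),
    sprintf("#pH_o=%.17g", recording$solutions$pH_o),
    sprintf("#temperature_K=%.17g", recording$solutions$T),
    sprintf("#n_sweeps=%d", nsw))
  if (!is.null(recording$protocol)) {
    p <- recording$protocol
    hdr <- c(hdr,
             sprintf("#protocol=%s", .serialize_protocol(p)),
             sprintf("#sweep_increment=%.17g", p$sweep_increment))
    if (!is.na(p$sweep_epoch))
      hdr <- c(hdr, sprintf("#sweep_epoch=%d", p$sweep_epoch))
  }
  if (length(recording$labels))
    hdr <- c(hdr, sprintf("#labels=%s", paste(recording$labels, collapse = ";")))
  if (!is.na(recording$seed)) hdr <- c(hdr, sprintf("#seed=%d", recording$seed))
  n <- nrow(recording$current)
  rows <- sprintf("%d %.17g %.17g %.17g",
                  rep(0:(nsw - 1), each = n),
                  rep(recording$time, nsw),
                  as.numeric(recording$voltage),
                  as.numeric(recording$current))
  con <- file(path, open = "wb")       # fixed newline convention for byte-identity
  on.exit(close(con))
  writeLines(c(hdr, "#columns=sweep_index time_ms voltage_mV current_pA", rows),
             con, sep = "\n")
  invisible(path)
}

#' Read a recording from the episodic trace format
#'
#' Parses and validates a file written by [write_recording()] (or by hand in
#' the same format). Fails with an explicit error on missing required header
#' keys, wrong units, ragged sweeps, or non-monotone time within a sweep.
#'
#' @param path file path.
#' @return an [hv_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", hdr_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  req <- c("format_version", "dt", "units_current", "units_voltage",
           "pH_i", "pH_o", "temperature_K", "n_sweeps")
  missing_keys <- setdiff(req, keys)
  if (length(missing_keys))
    stop("missing required header key(s): ", paste0("#", missing_keys, collapse = ", "))
  if (vals[["units_current"]] != "pA" || vals[["units_voltage"]] != "mV")
    stop("unsupported units: expected pA and mV")
  dt <- as.numeric(vals[["dt"]])
  if (!is.finite(dt) || dt <= 0) stop("invalid #dt header")
  nsw <- as.integer(vals[["n_sweeps"]])

  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no sample rows in file")
  dat <- utils::read.table(text = data_lines, col.names =
    c("sweep_index", "time_ms", "voltage_mV", "current_pA"))
  sweeps <- split(seq_len(nrow(dat)), dat$sweep_index)
  if (length(sweeps) != nsw)
    stop("header declares ", nsw, " sweep(s) but file contains ", length(sweeps))
  lens <- lengths(sweeps)
  if (length(unique(lens)) != 1) stop("ragged sweeps: unequal sample counts")
  for (s in sweeps) {
    tt <- dat$time_ms[s]
    if (any(diff(tt) <= 0)) stop("non-monotone time within a sweep")
  }
  current <- vapply(sweeps, function(s) dat$current_pA[s], numeric(lens[[1]]))
  voltage <- vapply(sweeps, function(s) dat$voltage_mV[s], numeric(lens[[1]]))
  sol <- hv_solutions(as.numeric(vals[["pH_i"]]), as.numeric(vals[["pH_o"]]),
                      as.numeric(vals[["temperature_K"]]))
  prot <- .parse_protocol(
    if ("protocol" %in% keys) vals[["protocol"]] else NA_character_,
    n_sweeps = nsw,
    sweep_increment = if ("sweep_increment" %in% keys) as.numeric(vals[["sweep_increment"]]) else 0,
    sweep_epoch = if ("sweep_epoch" %in% keys) as.integer(vals[["sweep_epoch"]]) else NA_integer_,
    dt = dt)
  labels <- if ("labels" %in% keys) strsplit(vals[["labels"]], ";", fixed = TRUE)[[1]] else character()
  seed <- if ("seed" %in% keys) as.integer(vals[["seed"]]) else NA_integer_
  hv_recording(dt = dt, current = current, voltage = voltage, solutions = sol,
               protocol = prot, labels = labels, seed = seed)
}
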