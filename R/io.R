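#' Read epoched EEG from disk
#'
#' Reads the package's delimited-text epochs container, or cuts epochs from a
#' continuous EDF recording given a separate events table. The text layout is
#' one row per trial-channel: columns `trial`, `condition`, `channel`, then one
#' column per sample named `t<ms>`; metadata (`fs`, `subject_id`) in `#`-prefixed
#' header lines.
#'
#' @param path input file.
#' @param format one of `"tsv"` (epochs container) or `"edf"` (continuous
#'   recording; requires `events`). An HDF5 layout is not supported by this
#'   build and raises an error.
#' @param events for `format = "edf"`: path to a tab-separated events table
#'   with columns `sample_index` and `condition`, or a data.frame.
#' @param window,baseline for `format = "edf"`: epoch window and baseline
#'   window in ms, passed to [epoch_recording()].
#' @param validate_conditions check trial labels against `CON`/`SEM`/`SEM+SYN`.
#' @return an [eeg_epochs] object.
#' @seealso [write_epochs()], [epoch_recording()]
#' @export
read_epochs <- function(path, format = c("tsv", "edf", "hdf5"), events = NULL,
                        window = c(-200, 1000), baseline = c(-200, 0),
                        validate_conditions = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "hdf5")
    stop("the HDF5 epochs layout is not supported by this build; ",
         "use the delimited-text container (format = \"tsv\")", call. = FALSE)
  x <- switch(format,
    tsv = read_epochs_tsv(path),
    edf = {
      if (is.null(events))
        stop("EDF input requires an events table", call. = FALSE)
      if (is.character(events))
        events <- read.delim(events, stringsAsFactors = FALSE)
      rec <- read_edf(path)
      rec$events <- as.data.frame(events)
      epoch_recording(rec, window = window, baseline = baseline)
    })
  if (validate_conditions) {
    bad <- setdiff(unique(x$conditions), CONDITIONS)
    if (length(bad))
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  x
}

read_epochs_tsv <- function(path) {
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$fs))
    stop("malformed epochs file: missing `fs` header line", call. = FALSE)
  fs <- as.numeric(meta$fs)
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("trial", "condition", "channel")
  for (f in need) if (!f %in% names(tab))
    stop("malformed epochs file: missing column `", f, "`", call. = FALSE)
  tcols <- grep("^t-?[0-9]", names(tab))
  if (!length(tcols))
    stop("malformed epochs file: no time-sample columns (t<ms>)", call. = FALSE)
  times <- as.numeric(sub("^t", "", names(tab)[tcols]))
  trials <- sort(unique(tab$trial))
  montage <- unique(tab$channel[tab$trial == trials[1]])
  nt <- length(trials); nc <- length(montage); ns <- length(tcols)
  if (nrow(tab) != nt * nc)
    stop("malformed epochs file: expected ", nt * nc,
         " trial-channel rows, found ", nrow(tab), call. = FALSE)
  data <- array(NA_real_, c(nt, nc, ns))
  conds <- character(nt)
  ord <- order(match(tab$trial, trials), match(tab$channel, montage))
  tab <- tab[ord, ]
  vals <- as.matrix(tab[, tcols])
  for (i in seq_len(nt)) {
    rows <- ((i - 1L) * nc + 1L):(i * nc)
    if (!all(tab$channel[rows] == montage))
      stop("malformed epochs file: inconsistent channel set in trial ",
           trials[i], call. = FALSE)
    data[i, , ] <- vals[rows, ]
    conds[i] <- tab$condition[rows[1]]
  }
  eeg_epochs(data, times, conds, fs,
             subject_id = meta$subject_id %||% "S01", montage = montage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write epoched EEG to the delimited-text container
#'
#' @param x an [eeg_epochs] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  nt <- dim(x$data)[1]; nc <- dim(x$data)[2]
  flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = nt * nc)
  tab <- data.frame(
    trial = rep(seq_len(nt), each = nc),
    condition = rep(x$conditions, each = nc),
    channel = rep(x$montage, nt),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(flat))
  names(tab)[-(1:3)] <- paste0("t", format(x$times, trim = TRUE,
                                           scientific = FALSE))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# erpride epochs v1",
               paste0("# fs: ", format(x$fs)),
               paste0("# subject_id: ", x$subject_id)), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal EDF adapter ---------------------------------------------------
# EDF (16-bit, fixed-layout header) reader for continuous recordings; no R
# package in this stack reads EDF. Handles plain EDF with equal sampling
# rate across signals, which is all the pipeline accepts.

edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1L):(off + len)]))
}

#' Read a continuous EDF recording
#'
#' Minimal reader for plain (non-EDF+) 16-bit EDF files with a common
#' sampling rate across signals. Digital values are rescaled to physical
#' units using the per-signal calibration fields.
#'
#' @param path EDF file.
#' @return an [eeg_recording] with an empty events table (supply events
#'   separately, e.g. via [read_epochs()]).
#' @export
read_edf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256L) stop("not an EDF file (truncated header)", call. = FALSE)
  hdr_bytes <- as.integer(edf_field(raw, 184, 8))
  n_records <- as.integer(edf_field(raw, 236, 8))
  rec_dur <- as.numeric(edf_field(raw, 244, 8))
  ns <- as.integer(edf_field(raw, 252, 4))
  if (is.na(ns) || ns < 1L) stop("not an EDF file (bad signal count)", call. = FALSE)
  sig_field <- function(off0, len) {
    vapply(seq_len(ns) - 1L,
           function(i) edf_field(raw, 256L + off0 * ns + i * len, len), "")
  }
  labels <- sig_field(0L, 16L)
  phys_min <- as.numeric(sig_field(16L + 80L + 8L, 8L))
  phys_max <- as.numeric(sig_field(16L + 80L + 8L + 8L, 8L))
  dig_min <- as.numeric(sig_field(16L + 80L + 8L + 16L, 8L))
  dig_max <- as.numeric(sig_field(16L + 80L + 8L + 24L, 8L))
  spr <- as.integer(sig_field(16L + 80L + 8L + 32L + 80L, 8L))
  if (length(unique(spr)) != 1L)
    stop("EDF adapter supports a single sampling rate across signals",
         call. = FALSE)
  spr <- spr[1]
  fs <- spr / rec_dur
  dat <- readBin(raw[-seq_len(hdr_bytes)], "integer", size = 2L,
                 n = n_records * ns * spr, endian = "little", signed = TRUE)
  if (length(dat) < n_records * ns * spr)
    stop("EDF data shorter than header declares", call. = FALSE)
  # records x (signal-major blocks of spr samples)
  arr <- array(dat, c(spr, ns, n_records))
  samples <- matrix(0, ns, spr * n_records)
  for (s in seq_len(ns)) samples[s, ] <- as.numeric(arr[, s, ])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- sweep(sweep(samples, 1, dig_min), 1, gain, `*`) + phys_min
  eeg_recording(samples, fs, labels,
                data.frame(sample_index = integer(), condition = character()))
}

# Internal EDF writer, used to build synthetic EDF fixtures at test time
# (EDF is binary, so fixtures are generated, not shipped). Record length 1 s;
# the recording is zero-padded to a whole number of records.
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs; ns <- nrow(rec$samples)
  spr <- as.integer(fs)
  n_records <- ceiling(ncol(rec$samples) / spr)
  pad <- n_records * spr - ncol(rec$samples)
  x <- cbind(rec$samples, matrix(0, ns, pad))
  pmin_ <- floor(min(x, -1)); pmax_ <- ceiling(max(x, 1))
  dmin <- -32768; dmax <- 32767
  pad_field <- function(v, len)
    vapply(v, function(s) formatC(substr(s, 1, len), width = -len), "")
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("erpride", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(as.character(256L * (1L + ns)), 8), pad_field("", 44),
    pad_field(as.character(n_records), 8), pad_field("1", 8),
    pad_field(as.character(ns), 4),
    paste(pad_field(rec$channel_labels, 16), collapse = ""),
    paste(pad_field(rep("", ns), 80), collapse = ""),
    paste(pad_field(rep("uV", ns), 8), collapse = ""),
    paste(pad_field(rep(as.character(pmin_), ns), 8), collapse = ""),
    paste(pad_field(rep(as.character(pmax_), ns), 8), collapse = ""),
    paste(pad_field(rep(as.character(dmin), ns), 8), collapse = ""),
    paste(pad_field(rep(as.character(dmax), ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 80), collapse = ""),
    paste(pad_field(rep(as.character(spr), ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 32), collapse = ""))
  dig <- round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  out <- integer(n_records * ns * spr)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(dig[, cols, drop = FALSE])        # spr x ns, signal-major
    out[((r - 1L) * ns * spr + 1L):(r * ns * spr)] <- as.integer(block)
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}
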