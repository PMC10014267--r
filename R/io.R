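#' Construct an EEG recording
#'
#' The basic container for multichannel scalp EEG: a channels x samples
#' amplitude matrix in microvolts, a sampling rate, ordered channel labels,
#' optional 3-D electrode positions on the unit sphere, and the referencing
#' state.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels, one per
#'   data row. Defaults to `rownames(data)`.
#' @param montage optional data.frame with columns `name`, `x`, `y`, `z`
#'   giving electrode positions; positions are normalized to unit radius.
#'   Head frame: x toward the nose, y toward the left ear, z up. Must cover
#'   every channel if present.
#' @param reference referencing state, `"raw"` or `"common_average"`.
#' @param eog optional numeric vector, a bipolar electro-oculogram sampled
#'   at `rate`; consumed only by ICA component screening, never by the
#'   source model.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names = rownames(data),
                          montage = NULL, reference = c("raw", "common_average"),
                          eog = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names))
    stopf("channel_names required (no rownames on data)")
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stopf("duplicate channel names: %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (nrow(data) != length(channel_names))
    stopf("data has %d rows but %d channel names", nrow(data), length(channel_names))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stopf("rate must be a single positive number")
  if (!is.null(montage)) montage <- normalize_montage(montage, channel_names)
  if (!is.null(eog)) {
    eog <- as.numeric(eog)
    if (length(eog) != ncol(data))
      stopf("eog length %d != %d samples", length(eog), ncol(data))
  }
  rownames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 montage = montage, reference = reference, eog = eog),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s%s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference,
              if (is.null(x$montage)) ", no montage" else ""))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

normalize_montage <- function(montage, channel_names) {
  montage <- as.data.frame(montage)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(montage)))
    stopf("montage must have columns name,x,y,z")
  montage$name <- as.character(montage$name)
  missing <- setdiff(channel_names, montage$name)
  if (length(missing))
    stopf("montage is missing channel(s): %s", paste(missing, collapse = ", "))
  montage <- montage[match(channel_names, montage$name), , drop = FALSE]
  r <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(r < 1e-12)) stopf("montage position at origin for channel %s",
                            montage$name[which(r < 1e-12)[1]])
  montage$x <- montage$x / r; montage$y <- montage$y / r; montage$z <- montage$z / r
  rownames(montage) <- NULL
  montage
}

#' Idealized 10-20 electrode montage for the 19-channel set
#'
#' Unit-sphere positions (head frame: x nose, y left ear, z vertex) for
#' Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4, T5, P3, Pz, P4, T6,
#' O1, O2 -- the standard 10-20 layout shipped as a package fixture, since
#' clinical recordings of this kind carry no individual digitization.
#'
#' @return data.frame with columns name, x, y, z (unit radius).
#' @export
montage_1020 <- function() {
  path <- system.file("extdata", "montage_1020_19ch.csv", package = "gaitsource")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  normalize_montage(m, m$name)
}

#' Montage positions as a channels x 3 matrix
#' @param rec an `eeg_recording` with a montage.
#' @return numeric matrix, rownames = channel names.
#' @export
montage_matrix <- function(rec) {
  if (is.null(rec$montage)) stopf("recording has no montage")
  m <- as.matrix(rec$montage[, c("x", "y", "z")])
  rownames(m) <- rec$montage$name
  m
}

# ---------------------------------------------------------------------------
# EDF (16-bit European Data Format) -- minimal continuous reader/writer.
# One signal per EEG channel, one data record per second; amplitudes are
# scaled into the 16-bit digital range per channel, so a write/read round
# trip agrees to within the format's quantization step.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

#' Write a recording to disk
#'
#' `format = "edf"` writes a minimal continuous EDF file (16-bit,
#' 1-second data records, zero-padded final record with the true sample
#' count recorded in the reserved header field). `format = "txt"` writes
#' the package's plain-array dialect: a TSV with `# rate=<Hz>` on the first
#' line, channel names on the second, then one row per sample.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param format `"edf"` or `"txt"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "txt"
  format <- match.arg(format, c("edf", "txt"))
  if (format == "txt") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# rate=%.10g", rec$rate), con)
    writeLines(paste(rec$channel_names, collapse = "\t"), con)
    utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  ns <- n_channels(rec); nt <- n_samples(rec)
  spr <- as.integer(round(rec$rate))          # samples per 1-s record
  if (abs(spr - rec$rate) > 1e-9)
    stopf("EDF writer requires an integer sampling rate, got %g", rec$rate)
  nrec <- as.integer(ceiling(nt / spr))
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- (pmax - pmin) < 1e-9
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("gaitsource synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),
    edf_pad(sprintf("nsamp=%d", nt), 44),     # true sample count (reserved)
    edf_pad(nrec, 8),
    edf_pad(1, 8),                            # record duration, seconds
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste(vapply(vals, edf_pad, "", n = w),
                                             collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.8g", pmin), 8)
  field(sprintf("%.8g", pmax), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("none", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  padded <- cbind(rec$data, matrix(0, ns, nrec * spr - nt))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((padded[, idx, drop = FALSE] - pmin) / gain) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (ver != "0") stopf("not an EDF file (version field '%s'): %s", ver, path)
  nbytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16); fields(80); fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)); fields(32)
  if (length(unique(spr)) != 1)
    stopf("EDF reader supports a single sampling rate across signals")
  if (dur <= 0) stopf("non-positive record duration in EDF header")
  rate <- spr[1] / dur
  total <- nrec * spr[1]
  data <- matrix(0, ns, total)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      data[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[s]) * gain + pmin[s]
    }
  }
  nsamp <- if (grepl("^nsamp=", reserved))
    as.integer(sub("^nsamp=", "", reserved)) else total
  list(data = data[, seq_len(nsamp), drop = FALSE], rate = rate,
       labels = labels)
}

read_txt_eeg <- function(path) {
  first <- readLines(path, n = 2)
  if (!grepl("^# rate=", first[1]))
    stopf("plain-array EEG file must start with '# rate=<Hz>': %s", path)
  rate <- as.numeric(sub("^# rate=", "", first[1]))
  labels <- strsplit(first[2], "\t", fixed = TRUE)[[1]]
  raw <- utils::read.table(path, sep = "\t", skip = 2)
  list(data = t(as.matrix(raw)), rate = rate, labels = labels)
}

#' Read an EEG recording from EDF or the plain-array dialect
#'
#' @param path EDF file or plain-array TSV (see [write_eeg()]).
#' @param montage_path optional CSV of electrode positions (columns
#'   name,x,y,z); every channel in the file must appear in it. When `NULL`
#'   the recording carries no montage.
#' @return an `eeg_recording` with `reference = "raw"`, channels in file
#'   order, montage positions normalized to unit radius.
#' @export
read_eeg <- function(path, montage_path = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  is_edf <- tryCatch({
    con <- file(path, "rb"); on.exit(close(con))
    identical(trimws(readChar(con, 8, useBytes = TRUE)), "0")
  }, error = function(e) FALSE)
  raw <- if (is_edf) read_edf(path) else read_txt_eeg(path)
  montage <- NULL
  labels <- raw$labels
  eog <- NULL
  if ("EOG" %in% labels) {
    eog <- raw$data[which(labels == "EOG"), ]
    keep <- labels != "EOG"
    raw$data <- raw$data[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (!is.null(montage_path))
    montage <- utils::read.csv(montage_path, stringsAsFactors = FALSE)
  eeg_recording(raw$data, raw$rate, labels, montage = montage,
                reference = "raw", eog = eog)
}

# ---------------------------------------------------------------------------
# Heel-strike event streams

#' Construct a heel-strike event stream
#'
#' @param time_s numeric event times in seconds, strictly increasing after
#'   sorting.
#' @param label character, `"RHS"` (right heel strike) or `"LHS"` (left).
#' @param source free-text provenance (e.g. "inertial-sensor trigger").
#' @return object of class `event_stream` (a data.frame).
#' @export
event_stream <- function(time_s, label, source = "unknown") {
  label <- as.character(label)
  bad <- setdiff(unique(label), c("RHS", "LHS"))
  if (length(bad)) stopf("unknown event label(s): %s", paste(bad, collapse = ", "))
  time_s <- as.numeric(time_s)
  if (length(time_s) != length(label)) stopf("times and labels differ in length")
  if (is.unsorted(time_s, strictly = FALSE)) {
    warnf("event times not sorted; sorting")
    o <- order(time_s)
    time_s <- time_s[o]; label <- label[o]
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stopf("event times must be strictly increasing (duplicate or decreasing time)")
  structure(data.frame(time_s = time_s, label = label,
                       stringsAsFactors = FALSE),
            source = source, class = c("event_stream", "data.frame"))
}

#' Read a heel-strike event stream from TSV
#'
#' @param path TSV with columns `time_s`, `label` (RHS/LHS). Rows out of
#'   order are sorted with a warning; duplicate times and unknown labels
#'   are hard errors.
#' @return an `event_stream`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(event_stream(numeric(0), character(0),
                                          source = path))
  if (!all(c("time_s", "label") %in% names(raw)))
    stopf("event file needs columns time_s, label: %s", path)
  event_stream(raw$time_s, raw$label, source = path)
}

#' Write an event stream to TSV
#' @param events an `event_stream`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("time_s", "label")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Clinical outcomes

CLINICAL_MEASURES <- c("FGA", "UPDRS", "BBS", "FES", "TENMWT", "TUG", "GQI")
CLINICAL_GROUPS <- c("NMT", "nonNMT")
CLINICAL_TIMEPOINTS <- c("TPRE", "TPOST")

#' Construct a clinical outcomes table
#'
#' Long format: one row per (subject, group, timepoint, measure, value).
#' Groups are the neurologic-music-therapy (NMT) and control (nonNMT)
#' training arms; timepoints are pre/post training.
#'
#' @param df data.frame with columns subject_id, group, timepoint, measure,
#'   value.
#' @return object of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject_id", "group", "timepoint", "measure", "value")
  if (!all(need %in% names(df)))
    stopf("clinical table needs columns %s", paste(need, collapse = ", "))
  df <- df[, need]
  df$subject_id <- as.character(df$subject_id)
  for (col in c("group", "timepoint", "measure")) df[[col]] <- as.character(df[[col]])
  bad <- setdiff(unique(df$group), CLINICAL_GROUPS)
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$timepoint), CLINICAL_TIMEPOINTS)
  if (length(bad)) stopf("unknown timepoint(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$measure), CLINICAL_MEASURES)
  if (length(bad)) stopf("unknown measure(s): %s", paste(bad, collapse = ", "))
  key <- paste(df$subject_id, df$timepoint, df$measure)
  if (anyDuplicated(key))
    stopf("duplicate (subject,timepoint,measure): %s", key[duplicated(key)][1])
  grp <- unique(df[, c("subject_id", "group")])
  if (anyDuplicated(grp$subject_id))
    stopf("subject(s) assigned to both groups: %s",
          grp$subject_id[duplicated(grp$subject_id)][1])
  df$value <- as.numeric(df$value)
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Read a clinical outcomes table from CSV
#'
#' Accepts the long format (columns subject_id, group, timepoint, measure,
#' value) or a wide layout with one column per measure, which is melted to
#' long automatically.
#'
#' @param path CSV file.
#' @return a `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("measure", "value") %in% names(raw))) return(clinical_table(raw))
  meas <- intersect(CLINICAL_MEASURES, names(raw))
  if (!length(meas))
    stopf("clinical CSV is neither long format nor wide with measure columns")
  id <- c("subject_id", "group", "timepoint")
  if (!all(id %in% names(raw)))
    stopf("wide clinical CSV needs id columns %s", paste(id, collapse = ", "))
  long <- do.call(rbind, lapply(meas, function(m) {
    data.frame(raw[id], measure = m, value = raw[[m]],
               stringsAsFactors = FALSE)
  }))
  clinical_table(long)
}
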