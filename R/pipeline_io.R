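#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer: mono, 16-bit signed PCM. The signal is scaled to
#' \code{peak} of full scale before quantization.
#'
#' @param x Numeric vector in arbitrary units.
#' @param path Output path.
#' @param fs Sampling rate in samples/s.
#' @param peak Peak level relative to full scale (default 0.95).
#' @export
write_wav <- function(x, path, fs, peak = 0.95) {
  stopifnot(length(x) > 0, fs > 0)
  if (max(abs(x)) > 0) x <- x / max(abs(x)) * peak
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return List with \code{x} (numeric in [-1, 1]) and \code{fs}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fs <- NULL; bits <- NULL; channels <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("not PCM: ", path, call. = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      x <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                   endian = "little") / 32768
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(x)) stop("no data chunk in ", path, call. = FALSE)
  if (channels != 1) stop("stereo WAV not supported: ", path, call. = FALSE)
  list(x = x, fs = fs)
}

#' Write the GAW tracks of a recording as CSV
#'
#' Columns: \code{time_s}, \code{gaw_total}, \code{gaw_left},
#' \code{gaw_right}, with a uniform time step of \code{1/fs_gaw}.
#'
#' @param rec A \code{gaw_recording}.
#' @param path Output CSV path.
#' @export
write_gaw_csv <- function(rec, path) {
  n <- length(rec$gaw_total)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs_gaw,
                   gaw_total = rec$gaw_total,
                   gaw_left = rec$gaw_left,
                   gaw_right = rec$gaw_right)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one recording from its manifest row
#'
#' Loads the acoustic WAV and the GAW CSV, validates formats (mono PCM WAV;
#' the four declared GAW columns; uniform time step; no missing values) and
#' infers sampling rates from the files.
#'
#' @param wav_path Path to the mono PCM acoustic WAV.
#' @param gaw_csv_path Path to the GAW CSV.
#' @param subject_id,group Identifiers attached to the recording.
#' @return A \code{gaw_recording}.
#' @export
read_recording <- function(wav_path, gaw_csv_path, subject_id = NA_character_,
                           group = NA_character_) {
  wav <- read_wav(wav_path)
  gaw <- utils::read.csv(gaw_csv_path)
  need <- c("time_s", "gaw_total", "gaw_left", "gaw_right")
  missing_cols <- setdiff(need, names(gaw))
  if (length(missing_cols))
    stop("format error in ", gaw_csv_path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(gaw[need]))
    stop("format error in ", gaw_csv_path, ": NA values", call. = FALSE)
  dt <- diff(gaw$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]) || dt[1] <= 0)
    stop("format error in ", gaw_csv_path, ": non-uniform time column",
         call. = FALSE)
  structure(list(gaw_total = gaw$gaw_total, gaw_left = gaw$gaw_left,
                 gaw_right = gaw$gaw_right, acoustic = wav$x,
                 fs_gaw = round(1 / dt[1]), fs_acoustic = wav$fs,
                 subject_id = subject_id, group = group),
            class = "gaw_recording")
}

#' Write a simulated cohort to disk
#'
#' Emits, per subject: the acoustic track as 16-bit PCM WAV, the GAW tracks
#' as CSV, and collects a cohort manifest (subject_id, group, wav_path,
#' gaw_csv_path) plus a ground-truth CSV.
#'
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest data frame (also written to
#'   \code{manifest.csv} in \code{out_dir}).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(el) {
    rec <- el$recording
    wav <- file.path(out_dir, paste0(rec$subject_id, ".wav"))
    csv <- file.path(out_dir, paste0(rec$subject_id, "_gaw.csv"))
    write_wav(rec$acoustic, wav, rec$fs_acoustic)
    write_gaw_csv(rec, csv)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               wav_path = wav, gaw_csv_path = csv)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- do.call(rbind, lapply(cohort, function(el) {
    tr <- el$truth
    data.frame(subject_id = el$recording$subject_id,
               mean_period_s = tr$mean_period_s, mjit_ms = tr$mjit_ms,
               jit_pct = tr$jit_pct, shim_db = tr$shim_db,
               gap_rel = tr$gap_rel,
               lr_phase_delay_rel = tr$lr_phase_delay_rel,
               lr_amp_ratio = tr$lr_amp_ratio,
               acoustic_snr_db = tr$acoustic_snr_db)
  }))
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path Path to a manifest CSV (subject_id, group, wav_path,
#'   gaw_csv_path); relative file paths are resolved against the manifest's
#'   directory when not found as given.
#' @return List of \code{gaw_recording}s.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  if (anyDuplicated(man$subject_id))
    stop("manifest has duplicate subject_ids", call. = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i) {
    read_recording(resolve(man$wav_path[i]), resolve(man$gaw_csv_path[i]),
                   subject_id = man$subject_id[i], group = man$group[i])
  })
}
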