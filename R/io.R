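# Minimal RIFF/WAVE reader and writer.
# Sessions are exported one channel per file as 32-bit IEEE float WAV
# (format code 3); reading also accepts 16-bit integer PCM (format code 1,
# normalized to [-1, 1)). No R WAV package is declared as a dependency on
# purpose: the subset of the format needed here is tiny and fully tested.

#' Write samples to a 32-bit float WAV file
#'
#' @param x numeric sample vector.
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs) {
  check_scalar_number(fs, "fs", min = 0, strict_min = TRUE)
  n <- length(x)
  data_bytes <- 4L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(4 + 26 + 12 + 8 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(18L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(3L, con, size = 2, endian = "little")           # IEEE float
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs)) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")           # block align
  writeBin(32L, con, size = 2, endian = "little")          # bits per sample
  writeBin(0L, con, size = 2, endian = "little")           # cbSize
  writeChar("fact", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file (float32 or 16-bit PCM)
#'
#' @param path WAV file path.
#' @return numeric sample vector with attribute `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop_invalid("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop_invalid("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_invalid("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      code <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      n_chan <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16L))
      if (n_chan != 1L) stop_invalid("only mono WAV files are supported")
      fmt <- list(code = code, fs = fs, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop_invalid("data chunk before fmt chunk")
      if (fmt$code == 3L && fmt$bits == 32L) {
        x <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        x <- readBin(con, integer(), n = sz %/% 2L, size = 2, endian = "little") / 32768
      } else {
        stop_invalid(sprintf("unsupported WAV encoding (format %d, %d bits)",
                             fmt$code, fmt$bits))
      }
      return(structure(x, fs = fmt$fs))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2L))
    }
  }
}

#' Write a cohort to disk as WAV + CSV files with a manifest
#'
#' Exports each session as one float32 WAV file per channel and one motion
#' CSV (`time_s`, `angle_deg`), and writes a `sessions.csv` manifest with one
#' row per channel recording (subject, visit, group label, channel, file
#' paths, sampling rates).
#'
#' @param cohort a `jae_cohort` tibble.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ses <- cohort[i, ]
    stem <- paste0(ses$subject_id, "_", ses$visit)
    motion_path <- file.path(dir, paste0(stem, "_motion.csv"))
    readr::write_csv(tibble::as_tibble(ses$motion[[1]]), motion_path, progress = FALSE)
    purrr::imap_dfr(ses$audio[[1]], function(x, ch) {
      audio_path <- file.path(dir, paste0(stem, "_", ch, ".wav"))
      write_wav(as.numeric(x), audio_path, ses$fs_audio)
      tibble::tibble(
        subject_id = ses$subject_id, visit = ses$visit,
        group_label = ses$group_label, channel = ch,
        audio_path = basename(audio_path), motion_path = basename(motion_path),
        fs_audio = ses$fs_audio, fs_motion = ses$fs_motion
      )
    })
  })
  manifest_path <- file.path(dir, "sessions.csv")
  readr::write_csv(manifest, manifest_path, progress = FALSE)
  invisible(manifest_path)
}

#' Read a cohort back from a sessions manifest
#'
#' Reconstructs a cohort tibble from the files written by [write_cohort()].
#' Ground-truth cycle boundaries are not part of the on-disk format (real
#' recordings have none); segmentation of a re-read cohort relies on the
#' motion trace alone.
#'
#' @param manifest_path path to `sessions.csv`.
#' @return a `jae_cohort` tibble.
#' @export
read_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  sessions <- dplyr::distinct(manifest, .data$subject_id, .data$visit,
                              .data$group_label, .data$motion_path,
                              .data$fs_audio, .data$fs_motion)
  rows <- purrr::map(seq_len(nrow(sessions)), function(i) {
    ses <- sessions[i, ]
    chan_rows <- dplyr::filter(manifest, .data$subject_id == ses$subject_id,
                               .data$visit == ses$visit)
    audio <- lapply(setNames(chan_rows$audio_path, chan_rows$channel), function(p) {
      read_wav(file.path(dir, p))
    })
    mot <- readr::read_csv(file.path(dir, ses$motion_path),
                           show_col_types = FALSE, progress = FALSE)
    motion <- structure(mot, fs = ses$fs_motion, cycle_starts = NA_integer_,
                        class = c("jae_motion", class(mot)))
    tibble::tibble(
      subject_id = ses$subject_id, visit = ses$visit, group_label = ses$group_label,
      fs_audio = ses$fs_audio, fs_motion = ses$fs_motion,
      audio = list(audio), motion = list(motion),
      cycle_starts = list(NA_integer_)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("jae_cohort", class(out))
  out
}
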