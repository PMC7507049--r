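#' EEG epoch container
#'
#' A stimulus-locked channels x samples x trials tensor with its sampling
#' metadata.  At the defaults used throughout the package (250 Hz, epoch span
#' -800...+2000 ms) an epoch has 700 samples; after channel exclusions the
#' scalp montage has 28 channels.
#'
#' @param data numeric array, channels x samples x trials.
#' @param fs sampling rate (Hz).
#' @param t0_ms time of the first sample relative to stimulus onset (ms).
#' @param channel_names character vector, one label per channel.
#' @param condition named character vector or list describing (group,
#'   intensity, stim_type); free-form.
#' @return an object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs = 250, t0_ms = -800,
                        channel_names = NULL, condition = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[1]))
  }
  stopifnot(length(channel_names) == dim(data)[1])
  structure(
    list(data = data, fs = fs, t0_ms = t0_ms,
         channel_names = channel_names, condition = condition),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g...%g ms\n", x$t0_ms, x$t0_ms + (d[2] - 1) * 1000 / x$fs))
  if (!is.null(x$condition)) {
    cat("  condition:", paste(names(x$condition), unlist(x$condition),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Time axis of an epoch array (ms)
#' @param x an `epoch_array` (or any object with `fs`, `t0_ms` and a sample
#'   dimension).
#' @param n_samples number of samples; inferred from `x` when omitted.
#' @return numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(x, n_samples = dim(x$data)[2]) {
  x$t0_ms + (seq_len(n_samples) - 1) * 1000 / x$fs
}

#' Read / write epoch arrays in HDF5
#'
#' Layout: dataset `data` (channels x samples x trials, float64) with root
#' attributes `fs_hz`, `t0_ms`, `channel_names` and `condition` (JSON string).
#'
#' @param x an `epoch_array`.
#' @param path HDF5 file path (overwritten by the writer).
#' @return `path` invisibly (writer); an `epoch_array` (reader).
#' @export
write_epochs_h5 <- function(x, path) {
  stopifnot(inherits(x, "epoch_array"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(x$data, path, "data")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(x$fs, fid, "fs_hz")
  rhdf5::h5writeAttribute(x$t0_ms, fid, "t0_ms")
  rhdf5::h5writeAttribute(x$channel_names, fid, "channel_names")
  cond <- if (is.null(x$condition)) "" else
    as.character(jsonlite::toJSON(as.list(x$condition), auto_unbox = TRUE))
  rhdf5::h5writeAttribute(cond, fid, "condition")
  invisible(path)
}

#' @rdname write_epochs_h5
#' @export
read_epochs_h5 <- function(path) {
  dat <- rhdf5::h5read(path, "data")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  fs <- as.numeric(rhdf5::h5readAttributes(fid, "/")$fs_hz)
  t0 <- as.numeric(rhdf5::h5readAttributes(fid, "/")$t0_ms)
  ch <- as.character(rhdf5::h5readAttributes(fid, "/")$channel_names)
  cond_json <- as.character(rhdf5::h5readAttributes(fid, "/")$condition)
  cond <- if (nzchar(cond_json)) jsonlite::fromJSON(cond_json) else NULL
  epoch_array(dat, fs = fs, t0_ms = t0, channel_names = ch, condition = cond)
}

#' Standard 28-channel scalp montage used after channel exclusions
#' @return character vector of 28 10/20-system labels.
#' @export
scalp_channels_28 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "Oz",
    "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6")
}
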