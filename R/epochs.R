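#' Movement- or stimulus-aligned multichannel epochs
#'
#' Container for real-valued epoched signals: an array `channels x samples x
#' trials` with a uniformly spaced time axis in seconds relative to the
#' alignment event (movement or stimulus onset, time 0).
#'
#' @param data numeric array, channels x samples x trials.
#' @param fs sampling rate, Hz.
#' @param time numeric vector of sample times, seconds, strictly increasing
#'   with step `1/fs`.
#' @param channel_labels character vector, one per channel.
#' @param channel_pos optional channels x 2 matrix of 2-D positions.
#' @param alignment `"movement"` or `"stimulus"`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time, channel_labels = NULL, channel_pos = NULL,
                      alignment = c("movement", "stimulus")) {
  alignment <- match.arg(alignment)
  if (length(dim(data)) != 3) stop("data must be a 3-d array (channels x samples x trials)")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[1]))
  es <- structure(
    list(
      data = data, fs = fs, time = time, channel_labels = channel_labels,
      channel_pos = channel_pos, alignment = alignment
    ),
    class = "epoch_set"
  )
  validate_epoch_set(es)
}

#' @rdname epoch_set
#' @param es a candidate `epoch_set`.
#' @export
validate_epoch_set <- function(es) {
  d <- dim(es$data)
  if (length(es$time) != d[2]) stop("time axis length does not match sample dimension")
  if (length(es$channel_labels) != d[1]) stop("channel_labels length does not match channel dimension")
  if (es$fs <= 0) stop("fs must be positive")
  dt <- diff(es$time)
  if (any(dt <= 0) || max(abs(dt - 1 / es$fs)) > 1e-9) {
    stop("time axis must be strictly increasing with step 1/fs")
  }
  if (!is.null(es$channel_pos) && nrow(es$channel_pos) != d[1]) {
    stop("channel_pos rows do not match channel dimension")
  }
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d channel(s) x %d sample(s) x %d trial(s), fs = %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  cat(sprintf(
    "  %s-aligned, window [%.4g, %.4g] s\n", x$alignment,
    x$time[1], x$time[length(x$time)]
  ))
  invisible(x)
}

# layout of the HDF5 container: datasets /data (channels x samples x trials),
# /time, /channel_labels, optional /channel_pos; root attributes fs, alignment
#' Read / write epochs as an HDF5 container
#'
#' Lossless round trip: `write_epochs()` then `read_epochs()` reproduces the
#' signal array bit-exactly and all metadata exactly.
#'
#' @param path file path (overwritten by `write_epochs`).
#' @return `read_epochs` returns an [epoch_set()]; `write_epochs` returns
#'   `path` invisibly.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)$name
  for (ds in c("data", "time", "channel_labels")) {
    if (!(ds %in% contents)) stop("epoch container is missing dataset '", ds, "'")
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (a in c("fs", "alignment")) {
    if (is.null(attrs[[a]])) stop("epoch container is missing attribute '", a, "'")
  }
  data <- rhdf5::h5read(path, "data")
  time <- as.numeric(rhdf5::h5read(path, "time"))
  labels <- as.character(rhdf5::h5read(path, "channel_labels"))
  pos <- if ("channel_pos" %in% contents) rhdf5::h5read(path, "channel_pos") else NULL
  epoch_set(data, as.numeric(attrs$fs), time, labels, pos, as.character(attrs$alignment))
}

#' @rdname read_epochs
#' @param es an [epoch_set()].
#' @export
write_epochs <- function(es, path) {
  es <- validate_epoch_set(es)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(es$data, path, "data")
  rhdf5::h5write(es$time, path, "time")
  rhdf5::h5write(es$channel_labels, path, "channel_labels")
  if (!is.null(es$channel_pos)) rhdf5::h5write(es$channel_pos, path, "channel_pos")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(es$fs, fid, "fs")
  rhdf5::h5writeAttribute(es$alignment, fid, "alignment")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read / write analytic (complex) epochs as an HDF5 container
#'
#' Same layout as [write_epochs()] but with `/real` and `/imag` datasets for
#' the complex analytic signal, plus attributes `fs_out`, `center_freq`,
#' `band_lo`, `band_hi`.
#'
#' @param path file path.
#' @return `read_analytic_epochs` returns an [analytic_epochs()] object.
#' @export
read_analytic_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)$name
  for (ds in c("real", "imag", "time")) {
    if (!(ds %in% contents)) stop("analytic container is missing dataset '", ds, "'")
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (a in c("fs_out", "center_freq", "band_lo", "band_hi")) {
    if (is.null(attrs[[a]])) stop("analytic container is missing attribute '", a, "'")
  }
  values <- rhdf5::h5read(path, "real") + 1i * rhdf5::h5read(path, "imag")
  labels <- as.character(rhdf5::h5read(path, "channel_labels"))
  analytic_epochs(
    values, as.numeric(attrs$fs_out), as.numeric(rhdf5::h5read(path, "time")),
    as.numeric(attrs$center_freq), c(as.numeric(attrs$band_lo), as.numeric(attrs$band_hi)),
    labels
  )
}

#' @rdname read_analytic_epochs
#' @param ae an [analytic_epochs()] object.
#' @export
write_analytic_epochs <- function(ae, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(ae$values), path, "real")
  rhdf5::h5write(Im(ae$values), path, "imag")
  rhdf5::h5write(ae$time, path, "time")
  rhdf5::h5write(ae$channel_labels, path, "channel_labels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(ae$fs_out, fid, "fs_out")
  rhdf5::h5writeAttribute(ae$center_freq, fid, "center_freq")
  rhdf5::h5writeAttribute(ae$band[1], fid, "band_lo")
  rhdf5::h5writeAttribute(ae$band[2], fid, "band_hi")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
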