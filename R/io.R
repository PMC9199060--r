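# Plain-text array container: line 1 is a JSON header (field names
# documented below), remaining lines are tab-separated matrix rows.
# Used in place of a binary hierarchical container so that every artifact
# is diffable and portable.
#
# ChannelData header fields: type="channel_data", t0, fs, n_elements,
#   n_samples, tx_meta (incl. per-element delays), geom (pitch, f0, c).
# Field/image header fields: type="field"|"image", kind, x_axis, z_axis.

write_text_container <- function(header, mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  utils::write.table(mat, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_text_container <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  mat <- as.matrix(utils::read.table(con, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  list(header = header, mat = mat)
}

#' Persist channel data / fields as text containers
#'
#' One file per array: a one-line JSON header (acquisition metadata,
#' grid axes, transmit event) followed by tab-separated matrix rows.
#'
#' @param data a `fus_channel_data`.
#' @param path output file path.
#' @export
write_channel_data <- function(data, path) {
  stopifnot(inherits(data, "fus_channel_data"))
  header <- list(type = "channel_data", t0 = data$t0, fs = data$fs,
                 n_elements = nrow(data$rf), n_samples = ncol(data$rf),
                 tx_meta = data$tx_meta,
                 geom = list(n_elements = data$geom$n_elements,
                             pitch = data$geom$pitch, f0 = data$geom$f0,
                             fs = data$geom$fs, c = data$geom$c,
                             element_width = data$geom$element_width))
  write_text_container(header, data$rf, path)
}

#' @rdname write_channel_data
#' @export
read_channel_data <- function(path) {
  tc <- read_text_container(path)
  h <- tc$header
  if (!identical(h$type, "channel_data")) stop("not a channel_data container")
  g <- h$geom
  geom <- array_geometry(g$n_elements, g$pitch, g$f0, g$fs, g$c,
                         g$element_width %||% g$pitch)
  structure(list(rf = tc$mat, t0 = h$t0, fs = h$fs,
                 tx_meta = h$tx_meta, geom = geom),
            class = "fus_channel_data")
}

#' @rdname write_channel_data
#' @param field a `fus_field` or `fus_image`.
#' @export
write_field <- function(field, path) {
  header <- list(type = if (inherits(field, "fus_image")) "image" else "field",
                 kind = field$kind, x_axis = field$grid$x_axis,
                 z_axis = field$grid$z_axis)
  write_text_container(header, field$values, path)
}

#' @rdname write_channel_data
#' @export
read_field <- function(path) {
  tc <- read_text_container(path)
  h <- tc$header
  grid <- image_grid(h$x_axis, h$z_axis)
  if (identical(h$type, "image")) {
    new_image(tc$mat, grid, kind = h$kind)
  } else {
    new_field(tc$mat, grid, kind = h$kind)
  }
}
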