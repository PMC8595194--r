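# File interfaces: channel-separated ImageJ-style TIFF stacks with a JSON
# sidecar recording intensity scaling and voxel size, protocol and
# trajectory CSV tables, and JSON ground-truth sidecars.

#' Write a VoxelStack as channel-separated TIFF
#'
#' One multi-page (z) 32-bit float TIFF per channel, plus a JSON sidecar
#' with voxel size, channel names and the intensity scale used to map data
#' into the unit range TIFF expects.
#'
#' @param stack a [VoxelStack-class].
#' @param prefix output path prefix; files are
#'   \code{<prefix>_<channel>.tif} and \code{<prefix>_meta.json}.
#' @return invisibly, the written file paths.
#' @export
writeVoxelStackTIFF <- function(stack, prefix) {
  maxv <- max(stack@data, 1e-12)
  paths <- character(0)
  for (ch in channelNames(stack)) {
    arr <- channelData(stack, ch) / maxv
    pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
    p <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(channels = channelNames(stack),
         voxel_size_um = as.list(voxelSize(stack)),
         intensity_scale = maxv,
         axis_order = "y,x,z"),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' Read a channel-separated TIFF VoxelStack
#'
#' @param prefix path prefix used by [writeVoxelStackTIFF()].
#' @return A [VoxelStack-class].
#' @export
readVoxelStackTIFF <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  chans <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
    arr * meta$intensity_scale
  })
  VoxelStack(chans, voxelSize = unlist(meta$voxel_size_um),
             channels = meta$channels)
}

#' Read / write a stimulus protocol CSV
#'
#' Columns: \code{label}, \code{onset_frame}, \code{duration_s},
#' \code{repeat_index}.
#'
#' @param path CSV path.
#' @return [StimulusProtocol()] table.
#' @export
readProtocolCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  StimulusProtocol(df$label, df$onset_frame, df$duration_s, df$repeat_index)
}

#' @rdname readProtocolCSV
#' @param protocol protocol table to write.
#' @export
writeProtocolCSV <- function(protocol, path) {
  write.csv(protocol, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trajectory CSV (t_s, x_mm, y_mm) with geometry JSON
#'
#' @param path CSV path; the geometry JSON sits next to it as
#'   \code{<path>.geometry.json} unless given explicitly.
#' @param geometryPath optional geometry JSON path.
#' @return A [Trajectory-class].
#' @export
readTrajectoryCSV <- function(path, geometryPath = NULL) {
  df <- read.csv(path)
  gp <- geometryPath %||% paste0(path, ".geometry.json")
  g <- jsonlite::read_json(gp, simplifyVector = TRUE)
  geometry <- lapply(g, function(p) {
    m <- as.matrix(as.data.frame(p))
    colnames(m) <- c("x", "y")
    m
  })
  Trajectory(df[, c("t_s", "x_mm", "y_mm")], geometry)
}

#' @rdname readTrajectoryCSV
#' @param trajectory trajectory to write.
#' @export
writeTrajectoryCSV <- function(trajectory, path, geometryPath = NULL) {
  write.csv(trajectorySamples(trajectory), path, row.names = FALSE)
  gp <- geometryPath %||% paste0(path, ".geometry.json")
  g <- lapply(trajectoryGeometry(trajectory), function(m)
    list(x = m[, 1], y = m[, 2]))
  jsonlite::write_json(g, gp, digits = NA)
  invisible(c(path, gp))
}
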