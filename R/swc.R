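# Standard 7-column SWC reading and writing. Columns: id, structure type,
# x, y, z, radius, parent; coordinates in micrometers; the root (soma) has
# parent -1. Lines starting with '#' are comments.

#' Read an SWC reconstruction
#'
#' @param path SWC file path.
#' @param scale optional factor applied to x, y, z and radius, for
#'   reconstructions stored in voxel indices rather than micrometers.
#' @return A [NeuronTree-class].
#' @export
readSWC <- function(path, scale = 1) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no SWC records in ", path)
  fields <- do.call(rbind, strsplit(lines, "[[:space:]]+"))
  if (ncol(fields) != 7L) stop("SWC must have 7 columns")
  nodes <- data.frame(
    id = as.integer(fields[, 1L]),
    type = as.integer(fields[, 2L]),
    x = as.numeric(fields[, 3L]) * scale,
    y = as.numeric(fields[, 4L]) * scale,
    z = as.numeric(fields[, 5L]) * scale,
    radius = as.numeric(fields[, 6L]) * scale,
    parent = as.integer(fields[, 7L]))
  NeuronTree(nodes)
}

#' Write an SWC reconstruction
#'
#' Serializes with fixed \code{%.4f} numeric formatting, so a tree written
#' twice produces byte-identical files.
#'
#' @param tree a [NeuronTree-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSWC <- function(tree, path) {
  nd <- treeNodes(tree)
  lines <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                   nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# SWC generated by bulbmorph", lines), path)
  invisible(path)
}
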