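# Plain-text I/O: square matrices as CSV with region-name headers,
# networks as edge lists, volumes as NIfTI (via RNifti, when installed).

#' Write a square named matrix as CSV
#'
#' Region names are written as both the header row and the first column,
#' so region order survives a round trip.
#'
#' @param m square matrix with dimnames.
#' @param path output file path.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a network as an edge-list text file
#'
#' One line per upper-triangle edge: `node_a,node_b[,weight]`. Binary
#' networks list present edges only; weighted networks list every
#' nonzero weight.
#'
#' @param net a `binary_network` or `weighted_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  m <- if (inherits(net, "binary_network")) net$a else net$w
  nm <- rownames(m)
  ij <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  df <- data.frame(
    node_a = nm[ij[, 1]], node_b = nm[ij[, 2]],
    stringsAsFactors = FALSE
  )
  if (inherits(net, "weighted_network")) df$weight <- m[ij]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an edge list back into a network
#'
#' @param path edge-list CSV from [write_edge_list()].
#' @param region_names full ordered node label vector (needed because
#'   isolated nodes carry no edges).
#' @return a `weighted_network` if the file has a `weight` column,
#'   otherwise a `binary_network`.
#' @export
read_edge_list <- function(path, region_names) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  n <- length(region_names)
  i <- match(df$node_a, region_names)
  j <- match(df$node_b, region_names)
  if (anyNA(i) || anyNA(j)) {
    stop_invalid("edge list refers to nodes outside region_names")
  }
  m <- matrix(0, n, n, dimnames = list(region_names, region_names))
  vals <- if ("weight" %in% names(df)) df$weight else 1
  m[cbind(i, j)] <- vals
  m[cbind(j, i)] <- vals
  if ("weight" %in% names(df)) {
    weighted_network(m, region_names)
  } else {
    binary_network(m, region_names)
  }
}

#' Write a 3-D or 4-D array as a NIfTI volume
#'
#' Thin wrapper over `RNifti::writeNifti()` for exporting label
#' probability maps, FA volumes or 4-D functional series.
#'
#' @param x numeric array (3-D or 4-D).
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_dims voxel sizes in mm (length 3, default 1).
#' @export
write_volume <- function(x, path, voxel_dims = c(1, 1, 1)) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_invalid("the RNifti package is required for NIfTI output")
  }
  img <- RNifti::asNifti(x, pixdim = c(voxel_dims, rep(1, length(dim(x)) - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return numeric array.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_invalid("the RNifti package is required for NIfTI input")
  }
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}
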