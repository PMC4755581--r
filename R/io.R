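# File interfaces: multi-page TIFF stacks, OBJ meshes, truth JSON, and CSV
# tables.

#' Read a multi-page TIFF into a 3D array
#'
#' @param path TIFF file; pages become z slices.
#' @return Numeric 3D array (x, y, z) with intensities as stored.
#' @export
readStackTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF returns row-major matrices [row = y, col = x]; transpose to
  # the package's [x, y] convention
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  arr
}

#' Write a 3D array as a multi-page TIFF
#'
#' @param arr numeric array (x, y, z); values are clipped into [0, 1].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStackTIFF <- function(arr, path) {
  pages <- lapply(seq_len(dim(arr)[3]), function(z)
    t(pmin(pmax(arr[, , z], 0), 1)))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Write a synthetic stack to disk
#'
#' Two multi-page TIFFs (cell and nucleus channels) plus a JSON ground
#' truth file.
#'
#' @param stack a \linkS4class{SyntheticStack}.
#' @param prefix output path prefix; files are
#'   \code{<prefix>_cell.tif}, \code{<prefix>_nucleus.tif},
#'   \code{<prefix>_truth.json}.
#' @return The three paths, invisibly.
#' @export
writeSyntheticStack <- function(stack, prefix) {
  stopifnot(is(stack, "SyntheticStack"))
  pc <- paste0(prefix, "_cell.tif")
  pn <- paste0(prefix, "_nucleus.tif")
  pt <- paste0(prefix, "_truth.json")
  mx <- max(stack@cellChannel, stack@nucleusChannel, 1)
  writeStackTIFF(stack@cellChannel / mx, pc)
  writeStackTIFF(stack@nucleusChannel / mx, pn)
  truth <- lapply(stack@truth, function(tr) {
    tr$contours <- lapply(tr$contours, function(P) unname(as.matrix(P)))
    tr
  })
  jsonlite::write_json(list(seed = stack@seed, spacing = stack@spacing,
                            cells = truth),
                       pt, auto_unbox = TRUE, digits = NA)
  invisible(c(pc, pn, pt))
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f))
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ triangle mesh
#'
#' @param path OBJ file with v/f records (triangular faces).
#' @return A \linkS4class{TriangleMesh}.
#' @export
readOBJ <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  TriangleMesh(v, f)
}

#' Write cell morphometry records as CSV
#'
#' One row per cell: id, slice span, L, W, T, slenderness, beta, alpha and
#' flags.
#'
#' @param records list of \linkS4class{CellRecord} objects.
#' @param path output path.
#' @return The written data.frame, invisibly.
#' @export
writeMorphometryCSV <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    zspan <- if (any(r@volume@voxels)) {
      zs <- which(apply(r@volume@voxels, 3, any))
      sprintf("%d-%d", min(zs), max(zs))
    } else ""
    cbind(data.frame(id = r@id, slices = zspan), r@morphometry,
          data.frame(flags = paste(r@flags, collapse = "; ")))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
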