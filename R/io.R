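# NIfTI + JSON-sidecar I/O for phantoms and dose grids.

#' Write / read a voxel grid as NIfTI with a JSON sidecar
#'
#' The array is stored as NIfTI; grid spacing, origin and an md5 checksum
#' of the voxel data live in a JSON sidecar next to it, which
#' [readVoxelGrid()] verifies (silent file edits are detected via the
#' checksum, geometry mismatches via spacing/shape).
#'
#' @param x numeric or logical 3D array.
#' @param path output path (".nii.gz" appended if no extension).
#' @param spacing numeric(3) mm.
#' @param origin numeric(3) mm.
#' @return [writeVoxelGrid()]: the path, invisibly. [readVoxelGrid()]:
#'   list(data, spacing, origin).
#' @export
writeVoxelGrid <- function(x, path, spacing, origin = c(0, 0, 0)) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  arr <- if (is.logical(x)) array(as.integer(x), dim = dim(x)) else x
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(spacing = spacing, origin = origin, shape = dim(arr),
         logical = is.logical(x), md5 = .hash_obj(as.numeric(arr))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVoxelGrid
#' @export
readVoxelGrid <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) .stopf("missing sidecar '%s'", sidecar)
  sc <- jsonlite::fromJSON(sidecar)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (!identical(dim(arr), as.integer(sc$shape))) {
    .stopf("shape mismatch between '%s' and its sidecar", path)
  }
  pd <- attr(img, "pixdim")
  if (!is.null(pd) && any(abs(pd[1:3] - sc$spacing) > 1e-4)) {
    .stopf("spacing mismatch between '%s' and its sidecar", path)
  }
  if (!identical(unname(.hash_obj(as.numeric(arr))), unname(sc$md5))) {
    .stopf("checksum mismatch: '%s' was modified after writing", path)
  }
  if (isTRUE(sc$logical)) arr <- array(arr != 0, dim = dim(arr))
  list(data = arr, spacing = as.numeric(sc$spacing),
       origin = as.numeric(sc$origin))
}

#' Write / read a phantom as a directory of NIfTI volumes
#'
#' One NIfTI per mask plus the stopping-power map, and a phantom.json
#' sidecar (spacing, origin, structure names, seed, config echo).
#' Round-trips losslessly.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param dir output directory (created).
#' @return [writePhantom()]: dir, invisibly. [readPhantom()]: the
#'   [VoxelPhantom-class].
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom@spacing; o <- phantom@origin
  writeVoxelGrid(phantom@rsp, file.path(dir, "rsp"), sp, o)
  writeVoxelGrid(phantom@body, file.path(dir, "body"), sp, o)
  for (nm in names(phantom@structures)) {
    writeVoxelGrid(phantom@structures[[nm]], file.path(dir, paste0("mask_", nm)), sp, o)
  }
  jsonlite::write_json(
    list(grid = phantom@grid, spacing = sp, origin = o,
         structures = names(phantom@structures), seed = phantom@seed,
         meta = phantom@meta),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir) {
  info <- jsonlite::fromJSON(file.path(dir, "phantom.json"),
                             simplifyVector = TRUE)
  rsp <- readVoxelGrid(file.path(dir, "rsp"))
  body <- readVoxelGrid(file.path(dir, "body"))
  if (any(abs(rsp$spacing - body$spacing) > 1e-9)) {
    .stopf("spacing mismatch between rsp and body volumes")
  }
  structures <- list()
  for (nm in info$structures) {
    m <- readVoxelGrid(file.path(dir, paste0("mask_", nm)))
    if (!identical(dim(m$data), dim(rsp$data))) {
      .stopf("shape mismatch between rsp and mask '%s'", nm)
    }
    structures[[nm]] <- m$data
  }
  new("VoxelPhantom",
      grid = as.integer(info$grid), spacing = as.numeric(info$spacing),
      origin = as.numeric(info$origin), rsp = rsp$data, body = body$data,
      structures = structures, seed = as.integer(info$seed),
      meta = if (is.null(info$meta)) list() else info$meta)
}

#' Write a spot catalog as CSV
#'
#' @param spots a [SpotSet-class].
#' @param path CSV path.
#' @return path, invisibly.
#' @export
writeSpots <- function(spots, path) {
  utils::write.csv(spots@spots, path, row.names = FALSE)
  invisible(path)
}

#' Write a plan solution as JSON
#'
#' @param plan a [PlanSolution-class].
#' @param path JSON path.
#' @return path, invisibly.
#' @export
writePlan <- function(plan, path) {
  # the solver log (which carries wall-clock timings) is intentionally not
  # serialized so that re-runs of the same configuration are byte-identical
  jsonlite::write_json(
    list(weights = plan@weights,
         active = plan@active,
         achieved = plan@achieved,
         tb_fraction = plan@tb_fraction,
         meta = plan@meta["frozen_bounds"]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
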