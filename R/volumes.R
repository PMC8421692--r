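#' Construct a volume stack
#'
#' A volume stack bundles co-registered participant volumes (grey-matter
#' volume or FDG metabolism maps on one spatially normalized grid) with the
#' shared voxel-to-world affine, the binary analysis mask and the participant
#' index aligned to the first array dimension.
#'
#' @param data 4-D numeric array, participants x i x j x k.
#' @param mask 3-D logical (or 0/1) array matching the per-participant grid;
#'   non-logical input is binarized at `> 0`.
#' @param ids character vector of participant ids, one per volume.
#' @param affine 4x4 voxel-to-world transform (default identity).
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, mask, ids, affine = diag(4)) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4-D array", call. = FALSE)
  mask <- array(as.logical(mask > 0), dim = dim(mask))
  if (!identical(dim(mask), dim(data)[2:4])) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ", paste(dim(data)[2:4], collapse = "x"),
         call. = FALSE)
  }
  ids <- as.character(ids)
  if (length(ids) != dim(data)[1L]) {
    stop("length(ids) must equal the number of volumes", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate participant ids in stack", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  structure(list(data = data, mask = mask, ids = ids, affine = affine),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat("<volume_stack> ", length(x$ids), " volumes, grid ",
      paste(dim(x$data)[2:4], collapse = "x"), ", ",
      sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Number of in-mask voxels
#' @param stack a `volume_stack` or 3-D logical mask.
#' @return integer voxel count.
#' @export
mask_size <- function(stack) {
  if (inherits(stack, "volume_stack")) sum(stack$mask) else sum(stack > 0)
}

#' Read NIfTI volumes into a stack
#'
#' All volumes and the mask must share one grid; affines must agree entrywise
#' within `affine_tol` (normalized maps written by one pipeline can differ in
#' float representation without being mis-registered).
#'
#' @param paths character vector of NIfTI-1 (.nii/.nii.gz) file paths.
#' @param mask_path path to the binary analysis mask (binarized at `> 0`).
#' @param ids participant ids, one per path; defaults to file basenames
#'   without extension.
#' @param affine_tol absolute per-entry affine tolerance.
#' @return A [volume_stack()].
#' @export
read_volume_stack <- function(paths, mask_path, ids = NULL, affine_tol = 1e-4) {
  if (length(paths) < 1L) stop("no volume paths given", call. = FALSE)
  mask_img <- read_nifti_checked(mask_path)
  mask_dim <- dim(mask_img)
  ref_affine <- nifti_affine(mask_img)
  if (is.null(ids)) {
    ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  }
  data <- array(NA_real_, dim = c(length(paths), mask_dim))
  for (i in seq_along(paths)) {
    img <- read_nifti_checked(paths[i])
    if (!identical(dim(img), mask_dim)) {
      stop("grid mismatch for '", paths[i], "': ",
           paste(dim(img), collapse = "x"), " vs mask ",
           paste(mask_dim, collapse = "x"), call. = FALSE)
    }
    aff <- nifti_affine(img)
    if (max(abs(aff - ref_affine)) > affine_tol) {
      stop("affine mismatch for '", paths[i],
           "' exceeds tolerance ", affine_tol, call. = FALSE)
    }
    data[i, , , ] <- as.array(img)
  }
  volume_stack(data, as.array(mask_img) > 0, ids, ref_affine)
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) != 3L) {
    stop("'", path, "' is not a 3-D volume", call. = FALSE)
  }
  img
}

nifti_affine <- function(img) {
  aff <- try(structure(RNifti::xform(img), imagedim = NULL, code = NULL),
             silent = TRUE)
  if (inherits(aff, "try-error") || is.null(aff)) aff <- diag(4)
  m <- matrix(as.numeric(aff), 4, 4)
  m
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D numeric/integer/logical array.
#' @param path output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world transform.
#' @export
write_volume <- function(vol, path, affine = diag(4)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cluster report to TSV (+ label map as NIfTI)
#'
#' Writes one row per cluster with columns `cluster_id`, `n_voxels`, `peak_t`,
#' `peak_x`, `peak_y`, `peak_z` (world mm, via the stack affine) and `status`
#' (`significant` or `trend`), and the integer cluster label map as a NIfTI-1
#' volume alongside (same path with extension `_labels.nii.gz`).
#'
#' @param report a `cluster_report` from [threshold_and_cluster()].
#' @param path output TSV path.
#' @param write_labels write the label map next to the TSV?
#' @return invisibly, the TSV path.
#' @export
write_cluster_report <- function(report, path, write_labels = TRUE) {
  stopifnot(inherits(report, "cluster_report"))
  tab <- report$clusters
  out <- data.frame(
    cluster_id = tab$cluster_id,
    n_voxels = tab$n_voxels,
    peak_t = tab$peak_t,
    peak_x = tab$peak_x,
    peak_y = tab$peak_y,
    peak_z = tab$peak_z,
    status = tab$status
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop("cannot write cluster report to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (write_labels && ok) {
    lab_path <- sub("\\.tsv$", "", path)
    lab_path <- paste0(lab_path, "_labels.nii.gz")
    write_volume(report$labels, lab_path, report$affine)
  }
  invisible(path)
}

# voxel (i,j,k) -> world mm via affine; NIfTI convention is 0-based voxel
# indices, R arrays are 1-based.
voxel_to_world <- function(ijk, affine) {
  v <- c(as.numeric(ijk) - 1, 1)
  as.numeric(affine %*% v)[1:3]
}
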