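# Volume and manifest I/O: NIfTI for rank-4 volumes, CSV for manifests.

#' Write a volume to NIfTI
#'
#' @param v An `octa_raw_volume`, `octa_volume` or rank-4 array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(v, path) {
  RNifti::writeNifti(RNifti::asNifti(vol_data(v)), path)
  invisible(path)
}

#' Read a rank-4 volume from NIfTI
#'
#' @param path Path written by [write_volume_nifti()].
#' @param acquisition Optional acquisition tag to attach.
#' @return An `octa_volume` when `acquisition` is given, else a rank-4 array.
#' @export
read_volume_nifti <- function(path, acquisition = NULL) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)
  stopifnot(length(dim(a)) == 4)
  if (is.null(acquisition)) return(a)
  structure(list(data = a, acquisition = acquisition, d_target = dim(a)[2]),
            class = "octa_volume")
}

write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
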