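# File interchange: NIfTI masks/label maps, TSV matrices.

#' Read and write masks and label maps as NIfTI
#'
#' Masks are stored as 0/1 volumes, label maps as integer volumes. An
#' existing NIfTI header/affine on the object is carried through unchanged.
#'
#' @param mask 3D logical array.
#' @param labels 3D integer array from [grow_parcels()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path (writers, invisibly); a logical or integer 3D array
#'   (readers).
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img) > 0
  dim(arr) <- dim(img)[1:3]
  arr
}

#' @rdname nifti_io
#' @export
write_labels_nifti <- function(labels, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim(labels)),
                         datatype = "int32")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(as.array(img)), dim(img)[1:3])
  structure(arr, n_nodes = max(arr))
}

#' Read and write square matrices as TSV
#'
#' Connectivity and weight matrices are exchanged as tab-separated tables
#' with node ids as the header row.
#'
#' @param m Square numeric matrix.
#' @param path File path.
#' @return The path (writer, invisibly) or the matrix (reader).
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  cn <- colnames(m) %||% paste0("n", seq_len(ncol(m)))
  utils::write.table(matrix(m, nrow(m), dimnames = list(NULL, cn)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}
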