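#' Read a NIfTI-1 volume
#'
#' Reads a 3-D or 4-D magnitude volume and returns the data array together
#' with the [volume_grid()] reconstructed from the header. Physical units of
#' derived maps are taken from the pipeline configuration, not from the
#' header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with elements `data` (numeric array) and `grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e), ")"))
  data <- array(as.vector(img), dim(img))
  if (all(is.na(data))) stop("volume contains no finite data: ", path)
  d <- dim(data)
  if (!length(d) %in% c(3L, 4L)) stop("expected 3-D or 4-D volume, got ",
                                      length(d), "-D")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- volume_grid(d[seq_len(3)],
                      voxel_size = sqrt(colSums(aff[seq_len(3),
                                                    seq_len(3)]^2)),
                      affine = aff)
  list(data = data, grid = grid)
}

#' Write a volume or parameter map as NIfTI-1
#'
#' @param x A [parameter_map()] or a numeric 3-D/4-D array.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param grid Required [volume_grid()] when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "parameter_map")) {
    grid <- x$grid
    data <- x$values
  } else {
    if (is.null(grid)) stop("grid is required when writing a bare array")
    data <- as.array(x)
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$voxel_size      # before sform: sform wins
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON file naming file roles, per-subject physiology and
#' constant overrides.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Restrict a parameter map to a mask
#'
#' Validity becomes `validity AND mask`; the stored values are untouched, so
#' masking is idempotent and order-independent.
#'
#' @param map A [parameter_map()].
#' @param mask Logical array on the same grid.
#' @return The masked [parameter_map()].
#' @export
apply_mask <- function(map, mask) {
  mask <- as.array(mask)
  if (!identical(dim(mask), as.integer(map$grid$shape))) {
    stop("mask shape does not match map grid")
  }
  map$validity <- map$validity & mask
  map
}

log_stage <- function(stage, subject = NA, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  extra <- list(...)
  kv <- if (length(extra)) {
    paste(names(extra), unlist(extra), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[%s] subject=%s %s", stage, subject, kv))
  invisible(NULL)
}
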