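#' Read an image + mask pair into a `roi_image`
#'
#' Supported image formats: PNG (8/16-bit, values rescaled to the stored
#' integer range), TIFF, NIfTI (`.nii`/`.nii.gz`; a slice of a 3-D volume is
#' selected with `slice`), and plain-text CSV matrices. Masks use the same
#' readers; any nonzero pixel is in-ROI. Intensities are used as stored; no
#' rescaling is applied beyond what the format itself mandates.
#'
#' @param image_path,mask_path Paths to the image and the mask.
#' @param slice Slice index used when a NIfTI file holds a 3-D volume.
#' @param subject_id,label,replicate Passed through to [roi_image()].
#' @return A `roi_image`.
#' @export
read_roi <- function(image_path, mask_path, slice = 1L,
                     subject_id = NULL, label = NULL, replicate = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(image_path))
  img <- read_gray(image_path, slice)
  msk <- read_gray(mask_path, slice)
  if (!identical(dim(img), dim(msk)))
    stop("image and mask dimensions differ for subject ", subject_id,
         call. = FALSE)
  roi_image(img, msk != 0, subject_id = subject_id, label = label,
            replicate = replicate)
}

read_gray <- function(path, slice = 1L) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    bd <- attr(a, "info")$bit.depth
    if (is.null(bd)) bd <- 16L
    if (length(dim(a)) == 3L) a <- a[, , 1L]   # first channel of color PNGs
    return(a * (2^bd - 1))
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    return(a * 65535)
  }
  if (ext == "nii") {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) >= 3L) a <- a[, , slice]
    return(matrix(as.numeric(a), nrow = dim(a)[1]))
  }
  if (ext %in% c("csv", "txt"))
    return(as.matrix(utils::read.csv(path, header = FALSE)))
  stop("unsupported image format: .", ext,
       " (supported: png, tiff, nii[.gz], csv)", call. = FALSE)
}

#' Feature tables
#'
#' A feature table is a data frame with identifier columns `subject_id`,
#' `label`, `cohort` followed by one numeric column per feature (233 under
#' the default configuration). All rows share the same feature set.
#'
#' @param df Data frame with the columns described above.
#' @return The validated table, classed `feature_table`.
#' @export
feature_table <- function(df) {
  need <- c("subject_id", "label", "cohort")
  if (!all(need %in% names(df)))
    stop("feature table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  feat <- setdiff(names(df), need)
  if (!length(feat)) stop("feature table has no feature columns", call. = FALSE)
  for (f in feat) {
    if (!is.numeric(df[[f]]))
      stop("feature column ", f, " is not numeric", call. = FALSE)
    if (any(!is.finite(df[[f]])))
      stop("feature column ", f, " contains non-finite values", call. = FALSE)
  }
  df <- df[, c(need, feat)]
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (cohorts: %s)\n",
              nrow(x), ncol(x) - 3L,
              paste(unique(x$cohort), collapse = "/")))
  invisible(x)
}

#' Columns of a feature table that hold features
#' @param table A `feature_table`.
#' @return Character vector of feature names.
#' @export
feature_columns <- function(table)
  setdiff(names(table), c("subject_id", "label", "cohort"))

#' Write / read a feature table as CSV
#'
#' Values are written with 15 significant digits so a write-read round trip
#' reproduces them to better than 12 significant digits.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(as.data.frame(table))
  out <- as.data.frame(table)
  for (f in feature_columns(table))
    out[[f]] <- sprintf("%.15g", out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = NA, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df$label <- as.character(df$label)
  df$cohort <- as.character(df$cohort)
  feature_table(df)
}

#' Read a cohort manifest
#'
#' CSV with columns `subject_id,image,mask,label,cohort,replicate`
#' (`replicate` may be empty). Paths are interpreted relative to the manifest
#' unless absolute.
#'
#' @param path Manifest CSV path.
#' @return Data frame of per-subject records.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image", "mask", "label", "cohort")
  if (!all(need %in% names(m)))
    stop("manifest needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!"replicate" %in% names(m)) m$replicate <- NA_character_
  m$replicate[m$replicate %in% c("", NA)] <- NA_character_
  key <- paste(m$subject_id, ifelse(is.na(m$replicate), "", m$replicate))
  if (anyDuplicated(key))
    stop("duplicate subject_id/replicate pairs in manifest", call. = FALSE)
  root <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", m$image)
  m$image[rel] <- file.path(root, m$image[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", m$mask)
  m$mask[rel] <- file.path(root, m$mask[rel])
  m
}
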