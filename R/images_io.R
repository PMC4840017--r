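#' Write / read contrast images (NIfTI-1 and GIfTI)
#'
#' Grid-space images are written as 2D NIfTI-1 volumes (`.nii`), with
#' the pixel size (mm) in the header and masked pixels stored as NaN.
#' Mesh-space images are written as ASCII GIfTI functional files
#' (`.gii`), one value per vertex, paired with a GIfTI surface written
#' by [write_gifti_surface()]. Reading inverts writing exactly on
#' values, mask and geometry metadata.
#'
#' @param img A [contrast_image()].
#' @param path Output path: `.nii` for grid images, `.gii` for mesh
#'   images.
#' @return `write_image()` returns the path invisibly; `read_image()`
#'   returns a [contrast_image()].
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "contrast_image"))
  if (img$space == "grid2d") {
    if (!grepl("\\.nii$", path))
      stop("grid2d images are written as NIfTI-1; use a .nii path",
           call. = FALSE)
    n <- img$geometry$n
    ps <- img$geometry$pixel_size
    arr <- matrix(img$values, n, n)
    ref <- RNifti::niftiHeader(list(
      dim = c(2L, n, n, 1L, 1L, 1L, 1L, 1L),
      pixdim = c(1, ps, ps, 1, 0, 0, 0, 0),
      datatype = 64L))
    RNifti::writeNifti(RNifti::asNifti(arr, reference = ref), path)
  } else {
    if (!grepl("\\.gii$", path))
      stop("mesh3d images are written as GIfTI; use a .gii path",
           call. = FALSE)
    write_gifti_func(img$values, path)
  }
  invisible(path)
}

#' @rdname write_image
#' @param geometry For mesh images, the [make_canonical_mesh()] the
#'   values refer to (vertex count is checked); for grid images the grid
#'   is reconstructed from the NIfTI header if not supplied.
#' @param subject_id Subject label attached to the returned image.
#' @export
read_image <- function(path, geometry = NULL, subject_id = NA_character_) {
  if (grepl("\\.nii$", path)) {
    v <- RNifti::readNifti(path)
    n <- dim(v)[1]
    ps <- RNifti::pixdim(v)[1]
    if (is.null(geometry))
      geometry <- scalp_grid2d(n, extent = ps * (n - 1) / 2)
    vals <- as.vector(v)
    vals[is.nan(vals)] <- NA_real_
    return(contrast_image("grid2d", vals, !is.na(vals), geometry,
                          subject_id))
  }
  if (grepl("\\.gii$", path)) {
    vals <- read_gifti_func(path)
    if (!is.null(geometry) && length(vals) != nrow(geometry$vertices))
      stop("value count does not match mesh vertex count", call. = FALSE)
    vals[is.nan(vals)] <- NA_real_
    return(contrast_image("mesh3d", vals, !is.na(vals), geometry,
                          subject_id))
  }
  stop("unsupported image extension: ", path, call. = FALSE)
}

gifti_data_array <- function(doc, intent, dtype, dims, text) {
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent, DataType = dtype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII", Endian = "LittleEndian",
                            ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1), as.character(dims[i]))
  xml2::xml_add_child(da, "Data", text)
  da
}

#' Write a scalp mesh as a GIfTI surface
#'
#' ASCII-encoded GIfTI with a POINTSET array (vertex coordinates scaled
#' to the scalp radius, mm) and a TRIANGLE array (0-based indices).
#'
#' @param mesh A [make_canonical_mesh()].
#' @param path Output `.gii` path.
#' @export
write_gifti_surface <- function(mesh, path) {
  v <- mesh$vertices * mesh$radius
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   dim(v),
                   paste(apply(v, 1, paste, collapse = " "),
                         collapse = "\n"))
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   dim(mesh$faces),
                   paste(apply(mesh$faces - 1L, 1, paste, collapse = " "),
                         collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gifti_surface
#' @return `read_gifti_surface()` returns a `scalp_mesh` (radius taken
#'   as the mean vertex norm; stored vertices are unit-normalized).
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(das, "Intent")
  parse_da <- function(da) {
    dims <- as.integer(c(xml2::xml_attr(da, "Dim0"),
                         xml2::xml_attr(da, "Dim1")))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  }
  v <- parse_da(das[[which(intents == "NIFTI_INTENT_POINTSET")]])
  f <- parse_da(das[[which(intents == "NIFTI_INTENT_TRIANGLE")]]) + 1L
  radius <- mean(sqrt(rowSums(v^2)))
  structure(list(vertices = v / sqrt(rowSums(v^2)),
                 faces = matrix(as.integer(f), nrow(f), 3),
                 radius = radius),
            class = "scalp_mesh")
}

write_gifti_func <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  txt <- ifelse(is.na(values), "NaN", format(values, digits = 17))
  gifti_data_array(doc, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                   length(values), paste(txt, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti_func <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
       quiet = TRUE, na.strings = "NaN")
}
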