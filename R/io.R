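#' Read a NIfTI volume as a ScalarField or LabelVolume
#'
#' The affine is taken from the NIfTI header (xform); voxel indices are
#' 0-based so the header affine applies directly.
#'
#' @param path .nii or .nii.gz file.
#' @param as "scalar" or "labels".
#' @param legend named integer vector for a label volume.
#' @return A \linkS4class{ScalarField} or \linkS4class{LabelVolume}.
#' @export
readVolume <- function(path, as = c("scalar", "labels"), legend = integer()) {
  as <- match.arg(as)
  if (!file.exists(path))
    stop(errorCondition(paste("missing input file:", path),
                        class = c("seegplan_missing_input", "error")))
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL, code = NULL)
  vals <- array(as.vector(img), dim = dim(img))
  if (as == "scalar")
    scalarField(vals, affine, name = sub("\\.nii(\\.gz)?$", "", basename(path)))
  else
    labelVolume(round(vals), affine, legend = legend)
}

#' Write a ScalarField or LabelVolume to NIfTI
#' @param x field or label volume.
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  vals <- fieldValues(x)
  img <- RNifti::asNifti(array(as.numeric(vals), dim = dim(vals)))
  img <- RNifti::`sform<-`(img, structure(fieldAffine(x), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a triangulated surface from ASCII STL or PLY
#'
#' STL facets are merged on exactly coincident vertices. A watertight check
#' runs at load; a warning is issued when the surface is open.
#'
#' @param path .stl or .ply file (ASCII).
#' @return A \linkS4class{SurfaceMesh}.
#' @export
readMesh <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste("missing input file:", path),
                        class = c("seegplan_missing_input", "error")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") .readSTL(path) else if (ext == "ply") .readPLY(path)
  else stop("unsupported mesh format: ", ext)
}

.readSTL <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("not an ASCII STL file: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(x) as.numeric(x[2:4])))
  key <- apply(nums, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  vid <- match(key, key[uniq])
  verts <- nums[uniq, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  surfaceMesh(verts, faces)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", lines, value = TRUE)[1]))
  hdr <- grep("end_header", lines)[1]
  vdat <- do.call(rbind, lapply(strsplit(trimws(lines[(hdr + 1):(hdr + nv)]),
                                         "\\s+"), as.numeric))
  fdat <- do.call(rbind, lapply(strsplit(trimws(lines[(hdr + nv + 1):(hdr + nv + nf)]),
                                         "\\s+"), as.numeric))
  surfaceMesh(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L)
}

#' Write a SurfaceMesh to ASCII PLY
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output .ply path.
#' @return `path`, invisibly.
#' @export
writeMeshPLY <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(v, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
  writeLines(apply(f, 1, function(r) paste(c(3, r), collapse = " ")), con)
  invisible(path)
}

#' Read an electrode strategy file (YAML or JSON)
#'
#' A strategy lists the electrodes to implant: an id, the deep ROI label
#' the electrode must reach, an optional superficial ROI label it must
#' traverse, and the spatial-prior choice ("roi_centreline" or
#' "medial_surface").
#'
#' @param path .yaml/.yml or .json file.
#' @return data.frame with columns id, deep_roi_label,
#'   superficial_roi_label (NA if absent), prior.
#' @export
readStrategy <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste("missing input file:", path),
                        class = c("seegplan_missing_input", "error")))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$electrodes)) raw <- raw$electrodes
  df <- do.call(rbind, lapply(raw, function(e) {
    data.frame(id = as.character(e$id),
               deep_roi_label = as.integer(e$deep_roi_label),
               superficial_roi_label =
                 if (is.null(e$superficial_roi_label)) NA_integer_
                 else as.integer(e$superficial_roi_label),
               prior = match.arg(e$prior, c("roi_centreline", "medial_surface")),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Write an electrode strategy file as YAML
#' @param strategy data.frame as returned by [readStrategy()].
#' @param path output .yaml path.
#' @return `path`, invisibly.
#' @export
writeStrategy <- function(strategy, path) {
  lst <- lapply(seq_len(nrow(strategy)), function(i) {
    e <- list(id = strategy$id[i],
              deep_roi_label = strategy$deep_roi_label[i],
              prior = strategy$prior[i])
    if (!is.na(strategy$superficial_roi_label[i]))
      e$superficial_roi_label <- strategy$superficial_roi_label[i]
    e
  })
  yaml::write_yaml(list(electrodes = lst), path)
  invisible(path)
}
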