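#' Label volumes
#'
#' A `label_volume` is a 3D integer array of voxel labels in which 0 is
#' background and positive values are segment IDs (or, after
#' [remap_volume()], group labels), plus voxel spacing and origin in
#' micrometres. This is the bridge between the combinatorial tree and the
#' image domain: per-segment attributions are mapped back onto the voxels of
#' the original segmentation.
#'
#' @param data integer array (3D; a 2D matrix is promoted to a single-slice
#'   volume)
#' @param spacing_um voxel spacing, length 3
#' @param origin_um volume origin, length 3
#' @return object of class `label_volume`
#' @export
label_volume <- function(data, spacing_um = c(1, 1, 1), origin_um = c(0, 0, 0)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing_um) == 3L, length(origin_um) == 3L)
  if (any(data < 0, na.rm = TRUE)) stop("voxel labels must be >= 0")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(x$spacing_um, collapse = ", "),
      ") um; ", sum(x$data != 0L), " foreground voxels, ",
      length(setdiff(unique(as.vector(x$data)), 0L)), " labels\n", sep = "")
  invisible(x)
}

#' Check a label volume against its companion tree
#'
#' @param volume a `label_volume` whose labels are segment IDs
#' @param tree the companion [vessel_tree()]
#' @return integer vector of orphaned labels (non-zero voxel values with no
#'   corresponding tree segment); empty when the volume is consistent
#' @export
orphan_labels <- function(volume, tree) {
  ids <- require_ids(tree)
  sort(setdiff(unique(as.vector(volume$data)), c(0L, ids)))
}

#' Remap segment IDs in a label volume to group labels
#'
#' Replaces every non-background voxel value by the group label of its
#' segment, e.g. to render a classification in the original image geometry.
#' Background (0) voxels are untouched, so the background voxel count is
#' preserved exactly.
#'
#' @param volume a `label_volume` keyed by segment ID
#' @param labels a `scheme_labels` object or named integer vector
#'   (names = segment IDs)
#' @param missing_policy what to do with voxel values absent from `labels`:
#'   `"error"` (default) or `"background"` (set to 0; the count of cleared
#'   voxels is attached as attribute `n_missing_voxels`)
#' @return the remapped `label_volume`
#' @export
remap_volume <- function(volume, labels, missing_policy = c("error", "background")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(volume, "label_volume"))
  ids <- as.integer(names(labels))
  if (anyNA(ids)) stop("labels must be named by integer segment IDs")
  vals <- setdiff(unique(as.vector(volume$data)), 0L)
  missing <- setdiff(vals, ids)
  n_missing_voxels <- 0L
  if (length(missing)) {
    if (missing_policy == "error") {
      stop("volume contains segment ID(s) absent from labels: ",
           paste(utils::head(sort(missing), 5), collapse = ", "))
    }
    n_missing_voxels <- sum(volume$data %in% missing)
  }
  lut <- c(0L, as.integer(labels), 0L)            # background, labels, missing
  idx <- match(volume$data, c(0L, ids))
  idx[is.na(idx)] <- length(lut)
  out <- volume
  out$data <- array(lut[idx], dim = dim(volume$data))
  attr(out, "n_missing_voxels") <- n_missing_voxels
  out
}

#' Read / write NRRD label volumes
#'
#' Minimal NRRD (Nearly Raw Raster Data) support for 3D integer label
#' volumes: `ascii` and `raw` encodings, integer sample types (the integer
#' type is preserved on write), `spacings` and `space origin` fields.
#'
#' @param path NRRD file path
#' @return `read_nrrd()`: a [label_volume()]; `write_nrrd()`: `path`,
#'   invisibly
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "[ ]+")[[1]])
  ndim <- as.integer(fields[["dimension"]])
  stopifnot(length(sizes) == ndim)
  encoding <- tolower(fields[["encoding"]])
  type <- tolower(fields[["type"]])
  n <- prod(sizes)
  if (encoding == "ascii" || encoding == "text" || encoding == "txt") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (encoding == "raw") {
    size_bytes <- nrrd_type_bytes(type)
    endian <- if (!is.null(fields[["endian"]]) &&
                  grepl("big", fields[["endian"]])) "big" else "little"
    unsigned <- grepl("^u", type) || grepl("unsigned", type)
    # readBin only honours signed = FALSE for 1- and 2-byte sizes
    vals <- readBin(con, what = "integer", n = n, size = size_bytes,
                    signed = if (size_bytes < 4L) !unsigned else TRUE,
                    endian = endian)
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  if (length(vals) != n) stop("truncated NRRD data: ", path)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "[ ]+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  }
  if (ndim == 2L) { sizes <- c(sizes, 1L); spacing <- c(spacing, 1); origin <- c(origin, 0) }
  vol <- label_volume(array(as.integer(vals), dim = sizes),
                      spacing_um = spacing, origin_um = origin)
  attr(vol, "nrrd_type") <- type
  vol
}

nrrd_type_bytes <- function(type) {
  switch(type,
         "int8" = , "uint8" = , "uchar" = , "signed char" = , "unsigned char" = 1L,
         "int16" = , "uint16" = , "short" = , "unsigned short" = 2L,
         "int32" = , "uint32" = , "int" = , "unsigned int" = 4L,
         stop("unsupported NRRD sample type: ", type))
}

#' @rdname read_nrrd
#' @param volume a [label_volume()]
#' @param encoding `"ascii"` (default; plain-text payload) or `"raw"`
#' @param type NRRD sample type (default `"int32"`, or the type the volume
#'   was read with)
#' @export
write_nrrd <- function(volume, path, encoding = c("ascii", "raw"),
                       type = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(type)) type <- attr(volume, "nrrd_type")
  if (is.null(type)) type <- "int32"
  header <- c("NRRD0004",
              "# label volume written by vesselrank",
              paste0("type: ", type),
              "dimension: 3",
              paste0("sizes: ", paste(dim(volume$data), collapse = " ")),
              paste0("spacings: ", paste(volume$spacing_um, collapse = " ")),
              paste0("encoding: ", encoding))
  if (encoding == "raw") header <- c(header, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, ""), con)
  if (encoding == "ascii") {
    writeLines(paste(as.vector(volume$data), collapse = " "), con)
  } else {
    writeBin(as.vector(volume$data), con, size = nrrd_type_bytes(type),
             endian = "little")
  }
  invisible(path)
}
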