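## Reading and writing images, masks and dataset manifests.

#' Read / write a grayscale intensity image
#'
#' Images are stored as 16-bit grayscale TIFF or PNG. Reading returns an
#' integer intensity matrix; multi-channel files are reduced to their first
#' channel.
#'
#' @param path file path (.tif/.tiff or .png).
#' @param img integer intensity matrix.
#' @param bitDepth pixel bit depth (default 16).
#' @return `readPlaqueImage` an integer matrix; `writePlaqueImage` the path,
#'   invisibly.
#' @export
readPlaqueImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    a <- round(a * 65535)
  } else stop("unsupported image format: ", ext)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a)), nrow(a), ncol(a))
}

#' @rdname readPlaqueImage
#' @export
writePlaqueImage <- function(img, path, bitDepth = 16L) {
  maxv <- 2^bitDepth - 1
  tiff::writeTIFF(pmin(pmax(img, 0), maxv) / maxv, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `readMask` a logical matrix; `writeMask` the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write a phantom dataset to disk
#'
#' Writes each record's image (16-bit TIFF), truth mask (8-bit PNG) and a
#' CSV manifest with columns id, path, mask_path, label.
#'
#' @param records list of [PlaqueRecord-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    ip <- file.path(dir, paste0(recordId(r), ".tif"))
    writePlaqueImage(plaqueImage(r), ip, bitDepth(r))
    mp <- ""
    if (!is.null(truthMask(r))) {
      mp <- file.path(dir, paste0(recordId(r), "_mask.png"))
      writeMask(truthMask(r), mp)
    }
    data.frame(id = recordId(r), path = ip, mask_path = mp,
               label = ifelse(is.na(stageLabel(r)), "", stageLabel(r)))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a dataset from a manifest CSV
#'
#' The manifest must have columns id and path; mask_path and label are
#' optional. Rows whose image file cannot be read are skipped with a
#' warning.
#'
#' @param manifest path to the manifest CSV.
#' @return list of [PlaqueRecord-class].
#' @export
readDataset <- function(manifest) {
  df <- read.csv(manifest, colClasses = "character")
  if (!all(c("id", "path") %in% colnames(df)))
    stop("manifest must have 'id' and 'path' columns")
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  recs <- list()
  for (i in seq_len(nrow(df))) {
    ip <- resolve(df$path[i])
    img <- tryCatch(readPlaqueImage(ip), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image for id ", df$id[i])
      next
    }
    msk <- NULL
    if ("mask_path" %in% colnames(df) && nzchar(df$mask_path[i])) {
      mp <- resolve(df$mask_path[i])
      msk <- tryCatch(readMask(mp), error = function(e) NULL)
    }
    lab <- if ("label" %in% colnames(df) && nzchar(df$label[i]))
      df$label[i] else NA_character_
    recs[[length(recs) + 1L]] <- PlaqueRecord(df$id[i], img, msk, lab)
  }
  recs
}
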