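# ---------------------------------------------------------------------------
# Image-folder datasets: class-per-subdirectory layout, manifest CSVs,
# loading into training arrays.
# ---------------------------------------------------------------------------

#' Read an RGB image into an (H, W, 3) array in [0, 1]
#'
#' Grayscale images are replicated across channels; alpha channels are
#' dropped.
#'
#' @param path PNG file path.
#' @return Numeric array of dim `(H, W, 3)`.
#' @export
read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  if (is.na(dim(img)[3])) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  ch <- dim(img)[3]
  if (ch == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3L))
  else if (ch >= 3) img <- img[, , 1:3, drop = FALSE]
  else stop("unsupported channel count: ", ch)
  img
}

#' Scan a class-per-subdirectory image folder into a manifest
#'
#' Each subdirectory of `root` is one identity; every PNG/JPEG below it is
#' one item.
#'
#' @param root Dataset root directory.
#' @return Manifest data.frame: `path` (relative), `identity`.
#' @export
scan_image_folder <- function(root) {
  if (!dir.exists(root)) stop("no such dataset directory: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  rows <- lapply(dirs, function(d) {
    files <- sort(list.files(d, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE))
    if (!length(files)) return(NULL)
    data.frame(path = file.path(basename(d), files),
               identity = basename(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("empty dataset: no images found under ", root)
  out
}

#' Write / read a dataset manifest CSV
#'
#' Column layout `path,identity,split[,rot,...]`.
#'
#' @param manifest Manifest data.frame.
#' @param path CSV file path.
#' @return `path` invisibly (writer); the manifest (reader).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load manifest images into a training array
#'
#' Reads every referenced image, applies the manifest's lossless `rot`
#' rotation if present, resizes to `side` by bilinear interpolation, and
#' stacks into an `(side, side, 3, N)` array. Identity labels are mapped to
#' integers by sorted unique value.
#'
#' @param manifest Manifest data.frame with `path` and `identity`.
#' @param root Directory the manifest paths are relative to.
#' @param side Output image side in pixels.
#' @param levels Optional fixed label ordering (character).
#' @return List: `x` (array), `y` (integer labels), `levels` (label names).
#' @export
load_manifest_images <- function(manifest, root, side, levels = NULL) {
  n <- nrow(manifest)
  if (n == 0) stop("empty manifest")
  if (is.null(levels)) levels <- sort(unique(as.character(manifest$identity)))
  y <- match(as.character(manifest$identity), levels)
  if (anyNA(y)) stop("identity outside the provided label set")
  x <- array(0, c(side, side, 3L, n))
  rots <- if ("rot" %in% names(manifest)) manifest$rot else rep(0, n)
  for (i in seq_len(n)) {
    img <- read_image_rgb(file.path(root, manifest$path[i]))
    if (rots[i] != 0) img <- rotate_rgb(img, rots[i])
    if (dim(img)[1] != side || dim(img)[2] != side)
      img <- EBImage::resize(img, w = side, h = side)
    x[, , , i] <- img
  }
  list(x = x, y = y, levels = levels)
}
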