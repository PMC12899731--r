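#' @title YOLO-format dataset I/O
#' @description
#' Plain-text YOLO label files (one `class cx cy w h` row per object, all
#' box fields normalized to `[0, 1]`), PNG images, and the
#' `images/ labels/ data.yaml` directory layout.
#' @name yolo-io
NULL

#' Write / read an image
#'
#' Images are `(H, W, 3)` arrays; on disk they are 8-bit PNG. `read_image`
#' returns values in 0..255.
#'
#' @param img `(H, W, 3)` array, 0..255 (or already in 0..1).
#' @param path file path.
#' @export
write_image <- function(img, path) {
  if (max(img) > 1) img <- img / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write / read YOLO label files
#'
#' @param labels numeric matrix with columns `class, cx, cy, w, h`
#'   (normalized); zero rows write an empty file.
#' @param path file path (`.txt`).
#' @export
write_yolo_labels <- function(labels, path) {
  if (is.null(labels) || nrow(labels) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  stopifnot(ncol(labels) == 5L,
            all(labels[, 2:5] >= 0), all(labels[, 2:5] <= 1),
            all(labels[, 4:5] > 0))
  lines <- apply(labels, 1L, function(r)
    paste(c(format(as.integer(r[1L])),
            formatC(r[2:5], format = "f", digits = 6)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- if (length(lines) == 0L) matrix(numeric(), 0L, 5L)
  else do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                             function(f) as.numeric(f[1:5])))
  colnames(out) <- c("class", "cx", "cy", "w", "h")
  out
}

#' Read a YOLO-layout dataset split into image samples
#'
#' @param dir dataset root (containing `images/`, `labels/`, `data.yaml`).
#' @param split `"train"` or `"val"`.
#' @return list of `image_sample` objects.
#' @export
read_dataset <- function(dir, split = c("train", "val")) {
  split <- match.arg(split)
  imgs <- sort(list.files(file.path(dir, "images", split),
                          pattern = "\\.png$", full.names = TRUE))
  lapply(imgs, function(ip) {
    lp <- file.path(dir, "labels", split,
                    sub("\\.png$", ".txt", basename(ip)))
    structure(list(image = read_image(ip),
                   labels = if (file.exists(lp)) read_yolo_labels(lp)
                   else matrix(numeric(), 0L, 5L)),
              class = "image_sample")
  })
}
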