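# Synthetic digit bitmaps standing in for a reduced handwritten-digit set
# (10 variants per class), plus a reader/writer for the standard IDX container
# so real MNIST files can be dropped in unchanged.

# Stroke templates: each digit as a set of segments (x1, y1, x2, y2) in the
# unit square, x rightward, y downward. Seven-segment layout with diagonals
# for 1, 4 and 7 to keep classes well separated.
digit_segments <- list(
  `0` = rbind(c(.2, .1, .8, .1), c(.2, .9, .8, .9), c(.2, .1, .2, .9),
              c(.8, .1, .8, .9)),
  `1` = rbind(c(.5, .1, .5, .9), c(.3, .25, .5, .1)),
  `2` = rbind(c(.2, .1, .8, .1), c(.8, .1, .8, .5), c(.2, .5, .8, .5),
              c(.2, .5, .2, .9), c(.2, .9, .8, .9)),
  `3` = rbind(c(.2, .1, .8, .1), c(.2, .5, .8, .5), c(.2, .9, .8, .9),
              c(.8, .1, .8, .9)),
  `4` = rbind(c(.2, .1, .2, .5), c(.2, .5, .8, .5), c(.7, .1, .7, .9)),
  `5` = rbind(c(.2, .1, .8, .1), c(.2, .1, .2, .5), c(.2, .5, .8, .5),
              c(.8, .5, .8, .9), c(.2, .9, .8, .9)),
  `6` = rbind(c(.2, .1, .8, .1), c(.2, .1, .2, .9), c(.2, .5, .8, .5),
              c(.8, .5, .8, .9), c(.2, .9, .8, .9)),
  `7` = rbind(c(.2, .1, .8, .1), c(.8, .1, .4, .9)),
  `8` = rbind(c(.2, .1, .8, .1), c(.2, .5, .8, .5), c(.2, .9, .8, .9),
              c(.2, .1, .2, .9), c(.8, .1, .8, .9)),
  `9` = rbind(c(.2, .1, .8, .1), c(.2, .1, .2, .5), c(.2, .5, .8, .5),
              c(.8, .1, .8, .9), c(.2, .9, .8, .9)))

render_glyph <- function(class, shape, shift = c(0, 0), scale = 1) {
  segs <- digit_segments[[as.character(class)]]
  if (is.null(segs)) stop("no template for digit class ", class)
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(0, nr, nc)
  thick <- max(1, round(min(shape) / 12))
  for (k in seq_len(nrow(segs))) {
    p <- segs[k, ]
    # centre, scale, then map to pixel coordinates
    x <- (c(p[1], p[3]) - 0.5) * scale + 0.5
    y <- (c(p[2], p[4]) - 0.5) * scale + 0.5
    n_pts <- 2 * max(nr, nc)
    xs <- round(seq(x[1], x[2], length.out = n_pts) * (nc - 1)) + 1 + shift[2]
    ys <- round(seq(y[1], y[2], length.out = n_pts) * (nr - 1)) + 1 + shift[1]
    for (i in seq_len(n_pts)) {
      rr <- ys[i] + seq(0, thick - 1); cc <- xs[i] + seq(0, thick - 1)
      rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
      img[rr, cc] <- 1
    }
  }
  img
}

#' Generate a synthetic digit bank
#'
#' Renders deterministic stroke-template glyphs for each class and perturbs
#' each variant by a small affine jitter (isotropic rescaling about the
#' glyph center) and by flipping a `noise_level` fraction of pixels. Classes
#' are linearly separable at the default noise; bitmaps stay essentially
#' binary.
#'
#' @param classes Integer digit classes (subset of 0..9).
#' @param variants_per_class Number of variants per class per split
#'   (default 10).
#' @param shape Bitmap shape `c(rows, cols)`; `c(22, 22)` and `c(20, 15)` are
#'   the task defaults.
#' @param noise_level Fraction of pixels flipped per variant.
#' @param seed Integer seed; the bank is a pure function of its arguments.
#' @param split Tag, `"train"` or `"test"`.
#' @return An object of class `digit_bank`: per-class lists of bitmaps in
#'   `[0, 1]`.
#' @export
synth_digit_bank <- function(classes = 0:9, variants_per_class = 10,
                             shape = c(22, 22), noise_level = 0.05,
                             seed = 1, split = "train") {
  if (variants_per_class < 1) stop("need at least one variant per class")
  set.seed(seed + if (split == "test") 10000L else 0L)
  images <- lapply(classes, function(cl) {
    lapply(seq_len(variants_per_class), function(v) {
      scale <- runif(1, 0.95, 1.05)
      img <- render_glyph(cl, shape, scale = scale)
      if (noise_level > 0) {
        flip <- which(runif(length(img)) < noise_level)
        img[flip] <- 1 - img[flip]
      }
      img
    })
  })
  names(images) <- as.character(classes)
  structure(list(images = images, classes = classes, shape = shape,
                 variants_per_class = variants_per_class, split = split),
            class = "digit_bank")
}

#' Draw one bitmap of a class from a bank
#'
#' @param bank A [synth_digit_bank()] (or a bank read from IDX files).
#' @param class Digit class label.
#' @return A bitmap matrix with attribute `class_label`.
#' @export
digit_sample <- function(bank, class) {
  imgs <- bank$images[[as.character(class)]]
  if (is.null(imgs)) stop("digit class ", class, " missing from the bank")
  img <- imgs[[sample.int(length(imgs), 1)]]
  attr(img, "class_label") <- class
  img
}

#' Symmetric center crop of an image
#'
#' Crops equally from all four sides; on an odd difference the extra pixel is
#' removed from the leading (top/left) side.
#'
#' @param image Matrix.
#' @param shape Target `c(rows, cols)`, each no larger than the source.
#' @return The cropped matrix.
#' @export
crop_center <- function(image, shape) {
  nr <- nrow(image); nc <- ncol(image)
  if (shape[1] > nr || shape[2] > nc) stop("target exceeds the source image")
  dr <- nr - shape[1]; dc <- nc - shape[2]
  r0 <- ceiling(dr / 2); c0 <- ceiling(dc / 2)
  image[(r0 + 1):(r0 + shape[1]), (c0 + 1):(c0 + shape[2]), drop = FALSE]
}

#' Read an IDX (MNIST-style) file
#'
#' Accepts the standard unsigned-byte IDX containers: magic 2051 for image
#' cubes, 2049 for label vectors. Pixel values are scaled to `[0, 1]`.
#'
#' @param path Path to the file.
#' @return For images, an array `n x rows x cols`; for labels, an integer
#'   vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2051L) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    n_px <- prod(dims)
    raw <- readBin(con, "integer", n_px, size = 1, signed = FALSE)
    if (length(raw) < n_px) stop("truncated IDX image file")
    aperm(array(raw / 255, dim = rev(dims)), 3:1)
  } else if (magic == 2049L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    lab <- readBin(con, "integer", n, size = 1, signed = FALSE)
    if (length(lab) < n) stop("truncated IDX label file")
    lab
  } else stop("not an IDX image or label file (bad magic number)")
}

#' Write images or labels to an IDX file
#'
#' @param x For images, an array `n x rows x cols` with values in `[0, 1]`;
#'   for labels, an integer vector.
#' @param path Output path.
#' @param type `"images"` or `"labels"`.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, type = c("images", "labels")) {
  type <- match.arg(type)
  con <- file(path, "wb"); on.exit(close(con))
  if (type == "images") {
    stopifnot(length(dim(x)) == 3)
    writeBin(2051L, con, size = 4, endian = "big")
    writeBin(as.integer(dim(x)), con, size = 4, endian = "big")
    writeBin(as.integer(round(255 * aperm(x, 3:1))), con, size = 1)
  } else {
    writeBin(2049L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.integer(x), con, size = 1)
  }
  invisible(path)
}

#' Assemble a digit bank from IDX image and label files
#'
#' @param image_path,label_path IDX files (e.g. real MNIST).
#' @param classes Classes to keep.
#' @param variants_per_class Images kept per class (first occurrences).
#' @param shape Optional center-crop target.
#' @return A `digit_bank`.
#' @export
idx_digit_bank <- function(image_path, label_path, classes = 0:9,
                           variants_per_class = 10, shape = NULL) {
  imgs <- read_idx(image_path)
  labs <- read_idx(label_path)
  if (dim(imgs)[1] != length(labs)) stop("image/label count mismatch")
  images <- lapply(classes, function(cl) {
    idx <- which(labs == cl)[seq_len(variants_per_class)]
    if (anyNA(idx)) stop("not enough images of class ", cl)
    lapply(idx, function(i) {
      im <- imgs[i, , ]
      if (!is.null(shape)) im <- crop_center(im, shape) else im
    })
  })
  names(images) <- as.character(classes)
  out_shape <- if (is.null(shape)) dim(imgs)[2:3] else shape
  structure(list(images = images, classes = classes, shape = out_shape,
                 variants_per_class = variants_per_class, split = "idx"),
            class = "digit_bank")
}
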