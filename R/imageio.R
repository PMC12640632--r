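#' Read a pressure image from PNG or PGM
#'
#' Reads an 8-bit single-channel image bit-exactly. Multi-channel PNG inputs
#' (common for pseudo-colored exports in the wild) are accepted and converted
#' by luminance with a warning. Inputs deeper than 8 bits are rejected.
#'
#' @param path path to a PNG or PGM (P5 binary or P2 ASCII) file.
#' @param pressureScale kPa per intensity unit (default 1).
#' @return a \linkS4class{PressureImage}.
#' @export
readPressureImage <- function(path, pressureScale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 8)
  if (length(magic) >= 2 && magic[1] == as.raw(0x89) &&
      rawToChar(magic[2:4]) == "PNG") {
    pix <- .readPng8(path)
  } else if (length(magic) >= 2 && rawToChar(magic[1:2]) %in% c("P5", "P2")) {
    pix <- .readPgm(path)
  } else {
    stop("unsupported image format (expected PNG or PGM): ", path,
      call. = FALSE)
  }
  PressureImage(pix, pressureScale = pressureScale)
}

.readPng8 <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  depth <- as.integer(hdr[25]) # IHDR bit-depth byte
  if (depth != 8)
    stop(sprintf("unsupported PNG bit depth: %d-bit (8-bit required)", depth),
      call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    if (nch >= 3) {
      warning("multi-channel PNG converted to intensity by luminance")
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else { # grey + alpha
      warning("grey+alpha PNG: alpha channel dropped")
      a <- a[, , 1]
    }
  }
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

.readPgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens: magic, width, height, maxval ('#' comments allowed)
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      word <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || grepl("[[:space:]]", ch)) break
        word <- paste0(word, ch)
      }
      tok <- c(tok, word)
    }
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  if (maxval > 255)
    stop(sprintf("unsupported PGM bit depth: 16-bit (maxval %d; 8-bit required)",
      maxval), call. = FALSE)
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    v <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(v) != w * h) stop("truncated PGM pixel data")
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a pressure image to PNG or PGM
#'
#' The output is 8-bit single-channel; a write/read round trip is bit-exact.
#' The format follows the file extension (.png, .pgm).
#'
#' @param img a \linkS4class{PressureImage}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePressureImage <- function(img, path) {
  .assertImage(img)
  ext <- tolower(tools::file_ext(path))
  p <- pixels(img)
  if (ext == "png") {
    png::writePNG(p / 255, target = path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(p), nrow(p)), con,
      eos = NULL, useBytes = TRUE)
    writeBin(as.raw(t(p)), con)
  } else {
    stop("unsupported output extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Render a pseudo-color visualization
#'
#' Maps intensity monotonically through a 256-entry blue-to-red (jet-style)
#' palette — the rendering pressure scanners display — and writes an RGB
#' PNG, optionally with an embedded vertical colorbar spanning 0 to
#' \code{255 * pressureScale(img)} kPa (255 at the top). All 256 palette
#' entries are distinct, so the mapping is injective.
#'
#' @param img a \linkS4class{PressureImage}.
#' @param path output PNG path.
#' @param legend embed the colorbar strip at the right edge.
#' @return the path, invisibly.
#' @export
writePseudocolor <- function(img, path, legend = FALSE) {
  .assertImage(img)
  pal <- .jetPalette()
  p <- pixels(img)
  h <- nrow(p); w <- ncol(p)
  idx <- p + 1L
  rgb <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[ch, idx], h, w)
  if (legend) {
    barIdx <- rev(round(seq(1, 256, length.out = h)))
    bar <- array(1, dim = c(h, 24, 3)) # 4 px white gap + 20 px bar
    for (ch in 1:3) bar[, 5:24, ch] <- matrix(pal[ch, barIdx], h, 20)
    out <- array(0, dim = c(h, w + 24, 3))
    out[, seq_len(w), ] <- rgb
    out[, w + 1:24, ] <- bar
    rgb <- out
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

# 256-entry jet palette (blue -> cyan -> green -> yellow -> red) as a
# 3 x 256 matrix in [0, 1]; piecewise-linear channels change by 4/255 per
# step in their active range, so every entry is distinct after 8-bit
# quantization
.jetPalette <- function() {
  x <- (0:255) / 255
  ch <- function(centre) pmin(pmax(1.5 - abs(4 * x - centre), 0), 1)
  pal <- rbind(ch(3), ch(2), ch(1))
  round(pal * 255) / 255
}

# class-id map for YOLO annotations: side-major, region-minor
.gtClassMap <- function() {
  data.frame(
    classId = 0:7,
    side = rep(c("left", "right"), each = 4),
    label = rep(regionLabels(), 2),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth class-id map
#'
#' The declared mapping between YOLO class ids and (side, region) pairs:
#' ids 0-3 are the left foot's outerForefoot, innerForefoot, midfoot and
#' heel; ids 4-7 the right foot's, same order.
#' @return data.frame with columns classId, side, label.
#' @export
gtClassMap <- function() .gtClassMap()

#' Read ground-truth region boxes
#'
#' Accepts YOLO-style text (one \code{class_id cx cy w h} line per box,
#' normalized center coordinates) or the package's JSON dialect
#' \code{\{image, boxes: [\{side, label, x, y, w, h\}]\}}. Boxes are returned
#' as absolute half-open pixel rectangles.
#'
#' @param path annotation file (.txt = YOLO, .json = JSON).
#' @param imgWidth,imgHeight image dimensions in pixels.
#' @return data.frame with columns side, label, x, y, w, h (0 rows when the
#'   file is empty).
#' @export
readGroundTruth <- function(path, imgWidth, imgHeight) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    boxes <- obj$boxes
    if (is.null(boxes) || NROW(boxes) == 0) return(.emptyGt())
    df <- data.frame(side = boxes$side, label = boxes$label,
      x = boxes$x, y = boxes$y, w = boxes$w, h = boxes$h,
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(.emptyGt())
    parts <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"),
      as.numeric))
    map <- .gtClassMap()
    bad <- !(parts[, 1] %in% map$classId)
    if (any(bad))
      stop("unknown YOLO class id(s): ",
        paste(unique(parts[bad, 1]), collapse = ", "), call. = FALSE)
    m <- match(parts[, 1], map$classId)
    w <- round(parts[, 4] * imgWidth)
    h <- round(parts[, 5] * imgHeight)
    df <- data.frame(
      side = map$side[m], label = map$label[m],
      x = round(parts[, 2] * imgWidth - w / 2),
      y = round(parts[, 3] * imgHeight - h / 2),
      w = w, h = h, stringsAsFactors = FALSE)
  }
  bad <- !(df$label %in% regionLabels())
  if (any(bad))
    stop("unknown region label(s): ",
      paste(unique(df$label[bad]), collapse = ", "), call. = FALSE)
  oob <- df$x < 0 | df$y < 0 | df$x + df$w > imgWidth | df$y + df$h > imgHeight
  if (any(oob))
    stop("box exceeding image bounds: ",
      paste(sprintf("(%s %s: %g,%g,%g,%g)", df$side[oob], df$label[oob],
        df$x[oob], df$y[oob], df$w[oob], df$h[oob]), collapse = " "),
      call. = FALSE)
  df
}

.emptyGt <- function() {
  data.frame(side = character(0), label = character(0), x = numeric(0),
    y = numeric(0), w = numeric(0), h = numeric(0), stringsAsFactors = FALSE)
}

#' Write ground-truth region boxes
#'
#' Inverse of \code{\link{readGroundTruth}}; YOLO normalized coordinates are
#' quantized at 6 decimals so integer-pixel boxes round-trip exactly.
#'
#' @param boxes data.frame with columns side, label, x, y, w, h.
#' @param path output file (.txt = YOLO, .json = JSON).
#' @param imgWidth,imgHeight image dimensions in pixels.
#' @param image image file name recorded in the JSON dialect.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(boxes, path, imgWidth, imgHeight,
                             image = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(image = image,
      boxes = boxes[, c("side", "label", "x", "y", "w", "h")])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    map <- .gtClassMap()
    id <- map$classId[match(paste(boxes$side, boxes$label),
      paste(map$side, map$label))]
    if (anyNA(id)) stop("box with side/label outside the declared class map")
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", id,
      (boxes$x + boxes$w / 2) / imgWidth, (boxes$y + boxes$h / 2) / imgHeight,
      boxes$w / imgWidth, boxes$h / imgHeight)
    writeLines(lines, path)
  }
  invisible(path)
}
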