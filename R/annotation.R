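# Polygon annotations and parsing maps. Annotation practice for this task is
# LabelMe-style: a handful of landmarks clicked along the cytoplasm and
# nucleus boundaries, joined in order into closed polygons, rasterized to a
# three-class map (nucleus blue, cytoplasm red, background black). This
# module reads that dialect, rasterizes polygons with an even-odd pixel-centre
# rule, and converts between one-hot maps and the colour legend.

.palette <- rbind(nucleus = c(0, 0, 255), cytoplasm = c(255, 0, 0),
                  background = c(0, 0, 0)) / 255

#' Read a LabelMe-style polygon annotation
#'
#' Parses a LabelMe-dialect JSON document (keys `shapes[].label`,
#' `shapes[].points`, `imageHeight`, `imageWidth`). Labels are matched
#' case-insensitively against `nucleus` and `cytoplasm`; anything else is a
#' format error naming the offending shape, as are polygons with fewer than
#' three vertices or vertices outside the image bounds.
#'
#' @param json a file path to a JSON document, or a JSON string.
#' @examples
#' f <- system.file("extdata", "synthetic_cell_labelme.json",
#'                  package = "leukosr")
#' ann <- read_labelme(f)
#' map <- rasterize_annotation(ann)
#' @return object of class `leuko_annotation`: list with `image_size`
#'   (`c(height, width)`) and `polygons`, each polygon a list with `label`
#'   and an `n x 2` vertex matrix of (x, y) pixel coordinates (x = column,
#'   y = row, 0-based, origin top-left). Polygons are closed implicitly.
#' @export
read_labelme <- function(json) {
  doc <- if (length(json) == 1L && !grepl("[{\\[]", json) && file.exists(json))
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  else jsonlite::fromJSON(paste(json, collapse = "\n"), simplifyVector = FALSE)
  h <- doc$imageHeight; w <- doc$imageWidth
  if (is.null(h) || is.null(w))
    stop("annotation is missing imageHeight/imageWidth")
  h <- as.integer(h); w <- as.integer(w)
  shapes <- doc$shapes
  if (is.null(shapes)) shapes <- list()
  polys <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    lab <- tolower(trimws(as.character(sh$label)))
    if (!lab %in% c("nucleus", "cytoplasm"))
      stop(sprintf("shape %d has unknown label '%s' (expected nucleus or cytoplasm)",
                   i, as.character(sh$label)))
    pts <- sh$points
    if (is.null(pts) || length(pts) < 3L)
      stop(sprintf("shape %d ('%s') has fewer than 3 vertices", i, lab))
    v <- t(vapply(pts, function(p) as.numeric(unlist(p))[1:2], numeric(2)))
    if (anyNA(v)) stop(sprintf("shape %d ('%s') has malformed points", i, lab))
    if (any(v[, 1] < 0) || any(v[, 1] > w) || any(v[, 2] < 0) || any(v[, 2] > h))
      stop(sprintf("shape %d ('%s') has vertices outside the %dx%d image",
                   i, lab, h, w))
    colnames(v) <- c("x", "y")
    polys[[i]] <- list(label = lab, vertices = v)
  }
  new_annotation(c(h, w), polys)
}

#' Construct a polygon annotation programmatically
#'
#' @param image_size integer `c(height, width)` in pixels.
#' @param polygons list of polygons, each a list with `label` ("nucleus" or
#'   "cytoplasm") and `vertices`, an `n x 2` matrix of (x, y) coordinates.
#' @return a `leuko_annotation`, as returned by [read_labelme()].
#' @export
new_annotation <- function(image_size, polygons) {
  structure(list(image_size = as.integer(image_size), polygons = polygons),
            class = "leuko_annotation")
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Pixel (row r, col c), 0-based, is tested at its centre (c + 0.5, r + 0.5),
# so integer-coordinate vertices never sit exactly on a tested point.
points_in_polygon <- function(px, py, verts) {
  nv <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon annotation into a parsing map
#'
#' Fills each closed polygon with the even-odd rule, sampling at pixel
#' centres (a pixel belongs to the polygon iff its centre is inside).
#' Multiple polygons of one class are unioned; where nucleus and cytoplasm
#' overlap, nucleus wins; uncovered pixels are background. The result is a
#' one-hot map, channels ordered (nucleus, cytoplasm, background).
#'
#' @param annotation a `leuko_annotation` from [read_labelme()] or
#'   [new_annotation()].
#' @return `height x width x 3` one-hot array.
#' @export
rasterize_annotation <- function(annotation) {
  if (!inherits(annotation, "leuko_annotation"))
    stop("annotation must be a leuko_annotation")
  h <- annotation$image_size[1]; w <- annotation$image_size[2]
  px <- rep(seq_len(w) - 0.5, each = h)    # centre x of pixel (r, c)
  py <- rep(seq_len(h) - 0.5, times = w)   # centre y
  cyto <- rep(FALSE, h * w); nuc <- rep(FALSE, h * w)
  for (poly in annotation$polygons) {
    inside <- points_in_polygon(px, py, poly$vertices)
    if (poly$label == "nucleus") nuc <- nuc | inside else cyto <- cyto | inside
  }
  mask <- matrix(0L, h, w)
  mask[matrix(cyto, h, w)] <- 1L
  mask[matrix(nuc, h, w)] <- 2L            # nucleus > cytoplasm precedence
  mask_to_onehot(mask)
}

check_onehot <- function(map, tol = 0) {
  d <- dim(map)
  if (length(d) != 3L || d[3] != 3L) stop("parsing map must be H x W x 3")
  m <- map; dim(m) <- c(d[1] * d[2], 3L)
  ok_vals <- all(m %in% c(0, 1))
  ok_sum <- all(abs(rowSums(m) - 1) <= tol)
  if (!ok_vals || !ok_sum)
    stop("parsing map is not one-hot (each pixel must have exactly one channel = 1)")
  invisible(map)
}

#' Convert a parsing map to and from its colour legend
#'
#' The visual convention for ground-truth maps is blue nucleus
#' `(0, 0, 255)`, red cytoplasm `(255, 0, 0)`, black background `(0, 0, 0)`.
#' `map_to_color()` requires a strictly one-hot map; `color_to_map()`
#' requires every pixel to be exactly one of the three palette colours, so
#' the pair is a bijection on one-hot maps.
#'
#' @param map `H x W x 3` one-hot parsing map (nucleus, cytoplasm,
#'   background).
#' @param img `H x W x 3` RGB image in `[0, 1]` using the exact palette.
#' @return `map_to_color()`: an RGB array; `color_to_map()`: a one-hot map.
#' @export
map_to_color <- function(map) {
  check_onehot(map)
  d <- dim(map)
  img <- array(0, d)
  for (ch in 1:3)
    img[, , ch] <- map[, , 1] * .palette["nucleus", ch] +
      map[, , 2] * .palette["cytoplasm", ch] +
      map[, , 3] * .palette["background", ch]
  img
}

#' @rdname map_to_color
#' @export
color_to_map <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 array")
  m <- img; dim(m) <- c(d[1] * d[2], 3L)
  key <- paste(m[, 1], m[, 2], m[, 3])
  pal_key <- paste(.palette[, 1], .palette[, 2], .palette[, 3])
  idx <- match(key, pal_key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("pixel %d has colour (%g, %g, %g), not an exact palette colour",
                 bad, m[bad, 1] * 255, m[bad, 2] * 255, m[bad, 3] * 255))
  }
  mask <- matrix(c(2L, 1L, 0L)[idx], d[1], d[2])
  mask_to_onehot(mask)
}

#' Read and write images and parsing maps as PNG
#'
#' `write_image_png()`/`read_image_png()` persist RGB images (values are
#' quantised to 8 bits on write, file I/O being the only place the pipeline
#' leaves floating point). `write_map_png()`/`read_map_png()` persist parsing
#' maps as 8-bit grayscale PNG with class codes 0 = background,
#' 1 = cytoplasm, 2 = nucleus.
#'
#' @param img RGB array in `[0, 1]`.
#' @param map one-hot parsing map.
#' @param path file path.
#' @name leuko_png
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname leuko_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' @rdname leuko_png
#' @export
write_map_png <- function(map, path) {
  check_onehot(map)
  mask <- onehot_to_mask(map)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname leuko_png
#' @export
read_map_png <- function(path) {
  mask <- round(png::readPNG(path) * 255)
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  if (!all(mask %in% 0:2)) stop("not a class-coded parsing map PNG")
  mask_to_onehot(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}
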