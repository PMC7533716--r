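# On-disk dataset layout used by the command-line tools: PNG images under
# images/, class-coded parsing-map PNGs under maps/, and a JSON manifest
# recording ids, classes and split assignment.

#' Write and read datasets as PNG files plus a JSON manifest
#'
#' `write_dataset()` stores every sample's RGB image (`images/<id>.png`),
#' its parsing map (`maps/<id>.png`, class-coded 0/1/2) and a
#' `manifest.json` with classes and train/val/test assignment.
#' `read_dataset()` loads the directory back into a `leuko_dataset`. Images
#' are quantised to 8 bits on disk; parsing maps round-trip exactly.
#'
#' @param dataset a `leuko_dataset`.
#' @param dir target/source directory.
#' @return `write_dataset()`: `dir`, invisibly; `read_dataset()`: a
#'   `leuko_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "leuko_dataset")) stop("expected a leuko_dataset")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(dataset$samples, `[[`, character(1), "sample_id")
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    write_image_png(s$image, file.path(dir, "images", paste0(ids[i], ".png")))
    write_map_png(s$parsing_map, file.path(dir, "maps", paste0(ids[i], ".png")))
  }
  manifest <- list(
    image_size = dim(dataset$samples[[1]]$image)[1],
    palette = c(background = 0L, cytoplasm = 1L, nucleus = 2L),
    samples = data.frame(id = ids, class = dataset$classes,
                         split = as.character(dataset$split)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  info <- mf$samples
  samples <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    samples[[i]] <- structure(list(
      image = read_image_png(file.path(dir, "images", paste0(info$id[i], ".png"))),
      parsing_map = read_map_png(file.path(dir, "maps", paste0(info$id[i], ".png"))),
      cell_class = info$class[i],
      sample_id = info$id[i]), class = "leuko_sample")
  }
  structure(list(samples = samples,
                 split = factor(info$split, levels = c("train", "val", "test")),
                 classes = info$class),
            class = "leuko_dataset")
}
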