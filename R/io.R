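#' Write a fruit image as PNG
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output file.
#' @export
write_fruit_png <- function(image, path) png::writePNG(image, path)

#' Read a fruit image from PNG
#' @param path PNG file.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_fruit_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a region label image as PNG plus JSON label map
#'
#' The label image (0 = background, 1..8 = regions) is stored as a
#' single-channel PNG with the label value in the 8-bit sample, alongside a
#' JSON file mapping codes to region names.
#'
#' @param labels integer label matrix.
#' @param path output PNG path; the label map is written next to it with a
#'   `.json` extension.
#' @export
write_labels_png <- function(labels, path) {
  png::writePNG(labels / 255, path)
  map <- c(list(background = 0L), as.list(REGION_LABELS))
  jsonlite::write_json(map, sub("\\.png$", ".json", path), auto_unbox = TRUE)
}

#' Read a region label image written by [write_labels_png()]
#' @param path PNG path.
#' @return integer label matrix.
#' @export
read_labels_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a simulated dataset to a directory
#'
#' Images as `images/<fruit_id>.png`, label masks as
#' `masks/<fruit_id>.png` (+ shared JSON label map), ground-truth features
#' as `truth.csv`, and phenotypes as `phenotypes.csv` with columns
#' fruit_id, genotype, year, trait, continuous, ordinal, binary.
#'
#' @param population a `fruit_population` from [sample_population()].
#' @param phenotypes data.frame from [generate_traits()] (possibly several
#'   traits row-bound).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fruit_dataset <- function(population, phenotypes, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  if (!is.null(population$images)) {
    for (i in seq_along(population$images)) {
      id <- population$meta$fruit_id[i]
      write_fruit_png(population$images[[i]],
                      file.path(dir, "images", paste0(id, ".png")))
      write_labels_png(labels_from_masks(population$masks[[i]]),
                       file.path(dir, "masks", paste0(id, ".png")))
    }
  }
  truth <- data.frame(population$meta, population$truth, check.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
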