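# Serialization: YOLO segmentation label files and per-instance mask datasets.

#' Write / read YOLO segmentation label files
#'
#' One line per instance: the class index followed by the normalized polygon
#' coordinates, space separated, printed to 6 decimal places. The read/write
#' round trip is the identity to 1e-6.
#'
#' @param records List of [yolo_seg_record()] objects.
#' @param path Output text file path.
#' @return `write_yolo_file` returns `path` invisibly; `read_yolo_file`
#'   returns a list of records.
#' @export
write_yolo_file <- function(records, path) {
  lines <- vapply(records, function(rec) {
    paste(c(rec$class_index, sprintf("%.6f", rec$coords)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_file
#' @export
read_yolo_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || length(parts) < 7 || (length(parts) - 1) %% 2 != 0 ||
        vals[1] != round(vals[1]) || vals[1] < 0 ||
        any(vals[-1] < -1e-9) || any(vals[-1] > 1 + 1e-9))
      stop("malformed YOLO segmentation record at line ", i, " of ", path)
    yolo_seg_record(as.integer(vals[1]), vals[-1])
  })
}

#' Write / read a per-instance mask dataset
#'
#' The directory layout consumed by MaskRCNN-style trainers: one binary PNG
#' per instance plus an `annotations.json` index recording the image size and,
#' per instance, class, bounding box, instance id and mask file. The round
#' trip is bitwise lossless. If `image` is supplied it is stored as
#' `image.png`.
#'
#' @param annotations List of [instance_annotation()] objects (or a
#'   `synthetic_scene`, whose image is written too).
#' @param dir Dataset directory (created if needed).
#' @param image Optional RGB array to store alongside the annotations.
#' @return `write_mask_dataset` returns `dir` invisibly; `read_mask_dataset`
#'   returns `list(annotations, image)`.
#' @export
write_mask_dataset <- function(annotations, dir, image = NULL) {
  if (inherits(annotations, "synthetic_scene")) {
    image <- annotations$image
    annotations <- annotations$annotations
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(
    image_size = as.integer(annotations[[1]]$image_size),
    instances = lapply(seq_along(annotations), function(i) {
      ann <- annotations[[i]]
      file <- sprintf("instance_%03d.png", i)
      png::writePNG(ann$mask * 1, file.path(dir, file))
      list(file = file, class = ann$class, class_index = ann$class_index,
           bbox = as.integer(ann$bbox), instance_id = ann$instance_id)
    })
  )
  if (!is.null(image)) {
    png::writePNG(image, file.path(dir, "image.png"))
    index$image_file <- "image.png"
  }
  jsonlite::write_json(index, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_mask_dataset
#' @export
read_mask_dataset <- function(dir) {
  index_path <- file.path(dir, "annotations.json")
  if (!file.exists(index_path)) stop("missing annotations.json index in ", dir)
  index <- tryCatch(jsonlite::read_json(index_path),
                    error = function(e) stop("corrupt annotations.json in ", dir, ": ",
                                             conditionMessage(e)))
  anns <- lapply(index$instances, function(inst) {
    f <- file.path(dir, inst$file)
    if (!file.exists(f)) stop("index references a missing mask file: ", inst$file)
    mask <- png::readPNG(f)
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
    id <- inst$instance_id
    ann <- instance_annotation(inst$class, mask > 0.5,
                               instance_id = if (is.null(id)) NA_integer_ else id)
    ann
  })
  image <- NULL
  if (!is.null(index$image_file)) image <- png::readPNG(file.path(dir, index$image_file))
  list(annotations = anns, image = image)
}

#' Convert between mask-dataset and YOLO annotation formats
#'
#' @param in_dir Mask dataset directory or directory of YOLO `.txt` files.
#' @param out_dir Output directory.
#' @param from,to Either `"masks"` or `"yolo"`.
#' @param image_size Required when `from = "yolo"` (width, height).
#' @return Output directory, invisibly.
#' @export
convert_annotations <- function(in_dir, out_dir, from = c("masks", "yolo"),
                                to = c("yolo", "masks"), image_size = NULL) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) stop("'from' and 'to' formats must differ")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (from == "masks") {
    ds <- read_mask_dataset(in_dir)
    records <- lapply(ds$annotations, mask_to_polygon)
    write_yolo_file(records, file.path(out_dir, "annotations.txt"))
  } else {
    if (is.null(image_size)) stop("image_size is required when converting from YOLO")
    files <- list.files(in_dir, pattern = "\\.txt$", full.names = TRUE)
    if (!length(files)) stop("no .txt label files found in ", in_dir)
    for (f in files) {
      records <- read_yolo_file(f)
      anns <- lapply(records, polygon_to_mask, image_size = image_size)
      write_mask_dataset(anns, file.path(out_dir, tools::file_path_sans_ext(basename(f))))
    }
  }
  invisible(out_dir)
}
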