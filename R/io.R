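#' Write a synthetic CLE dataset to disk
#'
#' Writes one directory per sequence (`seq_0001/frame_000.png`, zero-based
#' frame indices), a `manifest.csv` with columns `sequence_id`, `case_id`,
#' `roi_id`, `label`, `n_frames`, `path`, and a `ground_truth.json` holding
#' the per-frame annotations. Intensities are quantized to the requested bit
#' depth before writing, so a written dataset re-read with
#' [read_cle_dataset()] round-trips exactly, and writing the same dataset
#' twice produces byte-identical files.
#'
#' @param dataset A `cle_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` (8-bit, default) or `"tiff"` (16-bit; needs the
#'   tiff package).
#' @return `dir`, invisibly.
#' @export
write_cle_dataset <- function(dataset, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "cle_dataset"))
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for 16-bit TIFF output", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset$manifest
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sequence_id[i]
    sq <- dataset$sequences[[sid]]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (t in seq_along(sq$frames)) {
      fr <- clamp01(sq$frames[[t]])
      if (format == "png") {
        png::writePNG(round(fr * 255) / 255,
                      file.path(sdir, sprintf("frame_%03d.png", t - 1L)))
      } else {
        tiff::writeTIFF(round(fr * 65535) / 65535,
                        file.path(sdir, sprintf("frame_%03d.tiff", t - 1L)),
                        bits.per.sample = 16L)
      }
    }
    paths[i] <- sid
  }
  manifest$path <- paths
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- lapply(dataset$annotations, annotation_to_list)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

annotation_to_list <- function(ann) {
  list(
    label = ann$label,
    artifact = as.logical(ann$artifact),
    velocity = as.numeric(ann$velocity),
    cluster = if (is.null(ann$cluster)) NULL else
      list(center = as.numeric(ann$cluster$center),
           radius = ann$cluster$radius),
    frames = lapply(ann$frames, function(fr) {
      list(cells = as.list(fr$cells), rbc = as.list(fr$rbc))
    })
  )
}

#' Read a CLE dataset from disk
#'
#' Loads `manifest.csv`, all referenced frame images (PNG or TIFF), and, when
#' present, `ground_truth.json`.
#'
#' @param dir Directory written by [write_cle_dataset()] (or arranged in the
#'   same layout for real data: per-sequence frame directories plus a
#'   manifest).
#' @return A `cle_dataset`; `annotations` is `NULL` when no ground truth file
#'   exists.
#' @export
read_cle_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  assert_that(file.exists(mf_path), paste("no manifest.csv under", dir))
  manifest <- tibble::as_tibble(utils::read.csv(mf_path, stringsAsFactors = FALSE))
  sequences <- list()
  for (i in seq_len(nrow(manifest))) {
    sdir <- file.path(dir, manifest$path[i])
    files <- sort(list.files(sdir, pattern = "^frame_\\d+\\.(png|tiff?)$",
                             full.names = TRUE))
    assert_that(length(files) > 0, paste("no frames under", sdir))
    frames <- lapply(files, read_frame_file)
    sequences[[manifest$sequence_id[i]]] <- new_cle_sequence(
      frames = frames,
      sequence_id = manifest$sequence_id[i], case_id = manifest$case_id[i],
      roi_id = manifest$roi_id[i], label = manifest$label[i],
      frame_interval_s = NA_real_
    )
  }
  gt_path <- file.path(dir, "ground_truth.json")
  annotations <- NULL
  if (file.exists(gt_path)) {
    annotations <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  structure(list(sequences = sequences, annotations = annotations,
                 manifest = manifest[, setdiff(names(manifest), "path")]),
            class = "cle_dataset")
}

read_frame_file <- function(path) {
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF frames", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1] # grayscale stored as RGB
  img
}
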