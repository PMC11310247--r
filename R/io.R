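#' Read a single- or multi-page grayscale TIFF
#'
#' Integer-sample images are returned on their native a.u. scale
#' (`0 .. 2^bits - 1`); float-sample images are returned as stored.
#'
#' @param path TIFF file path.
#' @return An `image_stack` array `(H, W, T)`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  rescale <- function(p) {
    info <- attributes(p)
    bits <- info$bits.per.sample
    fmt <- info$sample.format
    # 8/16-bit samples are integers stored on [0,1]; 32-bit samples are
    # float and come back as written
    if (!is.null(bits) && bits %in% c(8, 16) &&
        (is.null(fmt) || fmt == "uint")) {
      p * (2^bits - 1)
    } else p
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    rescale(p)
  })
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  image_stack(arr)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' With integer `bits` (8 or 16) values are rounded and clipped to the
#' sample range, giving bit-exact round-trips for integer-valued data;
#' `bits = 32` stores float32 samples and requires values in \[0, 1\].
#'
#' @param stack `image_stack`, matrix, or list of matrices.
#' @param path Output path.
#' @param bits 8, 16 (integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16) {
  if (!bits %in% c(8, 16, 32)) {
    abort(paste0("Unsupported bit depth ", bits, " for file ", path,
                 " (use 8, 16 or 32)."))
  }
  frames <- if (is.list(stack)) stack
    else if (is.matrix(stack)) list(stack)
    else purrr::map(seq_len(dim(stack)[3]), function(t) stack_frame(stack, t))
  if (bits == 32) {
    rng <- range(unlist(lapply(frames, range)))
    if (rng[1] < 0 || rng[2] > 1) {
      abort(paste0("Float TIFF requires values in [0, 1]; file ", path,
                   " has range [", signif(rng[1], 4), ", ",
                   signif(rng[2], 4), "]."))
    }
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  } else {
    top <- 2^bits - 1
    frames <- lapply(frames, function(f) pmin(pmax(round(f), 0), top) / top)
    tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  df
}

#' Read / write detection and track tables (CSV)
#'
#' CSV interchange with a header row; coordinates are 0-based, pixel
#' center, x = column. Numeric values round-trip to at least 6 decimals.
#'
#' @param path CSV path.
#' @return A tibble with the documented columns.
#' @export
read_detections <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  check_columns(df, c("frame", "x", "y", "amplitude"), "Detections CSV")
}

#' @rdname read_detections
#' @param detections Tibble from [detect_movie()].
#' @export
write_detections <- function(detections, path) {
  hdr <- "# detections: frame 0-based; x,y 0-based pixel-center, x = column"
  writeLines(hdr, path)
  readr::write_csv(detections, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname read_detections
#' @export
read_tracks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  df <- check_columns(df, c("track_id", "frame", "x", "y"), "Tracks CSV")
  structure(df, class = c("vt_tracks", class(df)))
}

#' @rdname read_detections
#' @param tracks Tibble from [link_tracks()].
#' @export
write_tracks <- function(tracks, path) {
  hdr <- "# tracks: frame 0-based; x,y 0-based pixel-center, x = column"
  writeLines(hdr, path)
  readr::write_csv(track_table(tracks), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname read_detections
#' @param truth Tibble from [simulate_tracks()].
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(
    dplyr::select(tibble::as_tibble(truth), "particle_id", "frame",
                  "x", "y", "visible"),
    path)
  invisible(path)
}
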