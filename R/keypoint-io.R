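#' Write a Xenium Explorer keypoint alignment CSV
#'
#' One row per matched nucleus pair, columns
#' `fixedX,fixedY,alignmentX,alignmentY`: fixed coordinates are in the
#' DAPI morphology image, alignment coordinates in the (oriented) H&E
#' image, both in full-resolution pixels. Xenium Explorer requires at
#' least three keypoints, so fewer than three pairs is refused. Written
#' UTF-8 with LF line endings and full coordinate precision.
#'
#' @param pairs data frame with numeric columns `fixedX`, `fixedY`,
#'   `alignmentX`, `alignmentY` (extra columns are ignored).
#' @param path output file path.
#' @param header column names to emit, in order.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(pairs, path,
                               header = c("fixedX", "fixedY",
                                          "alignmentX", "alignmentY")) {
  cols <- c("fixedX", "fixedY", "alignmentX", "alignmentY")
  missing <- setdiff(cols, names(pairs))
  if (length(missing) > 0L) {
    stop(sprintf("`pairs` lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(pairs) < 3L) {
    stop(sprintf(paste0(
      "refusing to write %d keypoint pair(s): Xenium Explorer requires at ",
      "least three keypoints in the imported file"), nrow(pairs)),
      call. = FALSE)
  }
  fmt <- function(x) sprintf("%.17g", x)
  rows <- paste(fmt(pairs$fixedX), fmt(pairs$fixedY),
                fmt(pairs$alignmentX), fmt(pairs$alignmentY), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a keypoint alignment CSV
#'
#' Inverse of [write_keypoint_csv()]; used for round-trip validation and
#' by the `validate` CLI subcommand. Provenance nucleus ids are not stored
#' in the format and hence not recovered.
#'
#' @param path CSV file with the `fixedX,fixedY,alignmentX,alignmentY`
#'   header.
#' @param header expected column names.
#' @return data frame of keypoint coordinates (possibly zero rows, with a
#'   warning).
#' @export
read_keypoint_csv <- function(path, header = c("fixedX", "fixedY",
                                               "alignmentX", "alignmentY")) {
  if (!file.exists(path)) {
    stop(sprintf("keypoint file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0L) stop("keypoint file is empty", call. = FALSE)
  got <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(got), header)) {
    stop(sprintf("malformed header: expected '%s', got '%s'",
                 paste(header, collapse = ","), lines[1]), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    warning("keypoint file contains a header but no keypoints", call. = FALSE)
    return(data.frame(fixedX = numeric(0), fixedY = numeric(0),
                      alignmentX = numeric(0), alignmentY = numeric(0)))
  }
  out <- matrix(NA_real_, nrow = length(body), ncol = 4L)
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(cells) != 4L) {
      stop(sprintf("line %d: expected 4 cells, found %d", i + 1L,
                   length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric cell '%s'", i + 1L,
                   cells[which(is.na(vals))[1]]), call. = FALSE)
    }
    out[i, ] <- vals
  }
  stats::setNames(as.data.frame(out),
                  c("fixedX", "fixedY", "alignmentX", "alignmentY"))
}

#' Write the sidecar run manifest
#'
#' Records the image dimensions, the orientation applied to the H&E image,
#' and the configuration, so the coordinates in the keypoint CSV remain
#' interpretable.
#'
#' @param path output JSON path.
#' @param dims_he,dims_dapi `c(width, length)` of the two images.
#' @param orientation the applied `orientation_code`.
#' @param cfg the `pipeline_config`.
#' @param report the `run_report`.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, dims_he, dims_dapi, orientation, cfg,
                               report) {
  manifest <- list(
    he_image = list(width = dims_he[1], length = dims_he[2],
                    orientation_applied = list(rotation = orientation$rotation,
                                               mirrored = orientation$mirrored)),
    dapi_image = list(width = dims_dapi[1], length = dims_dapi[2]),
    config = unclass(cfg),
    report = unclass(report)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
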