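#' Write a movie as a 16-bit multi-page TIFF
#'
#' One page per frame, one file per channel (call once per channel).
#'
#' @param movie integer H x W x T array with values in [0, 65535].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3L)
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(t) movie[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file written by \code{\link{write_movie_tiff}} (or any
#'   single-channel multi-page TIFF).
#' @return integer H x W x T array with raw sample values.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  arr
}

#' Flatten a list of tracks into a long data.frame
#' @param tracks list of \code{granule_track}s.
#' @return data.frame(track_id, frame, x, y, intensity).
#' @export
tracks_to_df <- function(tracks) {
  out <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$id, frame = tr$frame, x = tr$x, y = tr$y,
               intensity = tr$intensity)))
  if (is.null(out))
    out <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), intensity = numeric())
  out
}

#' Serialize ground truth to JSON
#' @param gt a \code{ground_truth}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(list(spots = gt$spots,
                            fusion_events = gt$fusion_events,
                            structure_centers = gt$structure_centers),
                       path, digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest recording full provenance
#'
#' Every numeric result file produced by the pipeline is accompanied by a
#' manifest carrying the inputs, the complete parameter set, the package
#' version and the seed.
#'
#' @param path manifest JSON path.
#' @param cmd pipeline stage name.
#' @param params named list of all parameters used.
#' @param inputs,outputs character vectors of file paths.
#' @param counts named list of stage counts (spots, tracks, events, ...).
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, cmd, params, inputs = character(),
                           outputs = character(), counts = list()) {
  jsonlite::write_json(list(
    command = cmd,
    package = "tirfgranule",
    version = as.character(utils::packageVersion("tirfgranule")),
    parameters = params, inputs = inputs, outputs = outputs,
    counts = counts, timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
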