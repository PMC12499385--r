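# TIFF + sidecar-JSON serialization of image lapses.
#
# Frames are written as multi-page 32-bit float TIFF, channel
# interleaved (frame 1 lipid, frame 1 actin, frame 2 lipid, ...), with
# intensities divided by a power-of-two scale so they fit the [0, 1]
# range the format stores.  The sidecar JSON carries the physical
# calibration (pixel size, timestamps), the channel order, the scale,
# the seed and the embedded ground truth, since TIFF tag dialects for
# calibration vary between vendors.

#' Write an image lapse to TIFF + sidecar JSON
#'
#' @param lapse An [image_lapse()].
#' @param tiff_path Output TIFF path.
#' @param json_path Sidecar path (default `<tiff_path>.json`).
#' @return Invisibly, the two paths.
#' @export
write_lapse <- function(lapse, tiff_path,
                        json_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(lapse, "image_lapse"))
  mx <- max(vapply(lapse$frames, function(f) max(f$lipid, f$actin), 1.0))
  scale <- 2^ceiling(log2(max(mx, 1)))
  pages <- list()
  for (f in lapse$frames) {
    pages[[length(pages) + 1L]] <- t(f$lipid) / scale
    pages[[length(pages) + 1L]] <- t(f$actin) / scale
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  gt <- NULL
  if (!is.null(lapse$ground_truth)) {
    gt <- lapply(lapse$ground_truth, function(s) {
      s <- unclass(s)
      if (!is.null(s$domain_arc_bounds_deg)) {
        s$domain_arc_bounds_deg <- apply(s$domain_arc_bounds_deg, 1,
                                         function(r) as.numeric(r),
                                         simplify = FALSE)
      }
      s
    })
  }
  sidecar <- list(
    format = "guvactin-lapse-v1",
    pixel_size_um = lapse$pixel_size_um,
    times_min = lapse$times_min,
    n_frames = length(lapse$frames),
    channels = c("lipid", "actin"),
    intensity_scale = scale,
    ground_truth = gt
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tiff = tiff_path, json = json_path))
}

#' Read an image lapse from TIFF + sidecar JSON
#'
#' @param tiff_path Path to a multi-page TIFF written by
#'   [write_lapse()].
#' @param json_path Sidecar path (default `<tiff_path>.json`).
#' @return An [image_lapse()] (ground truth restored when present).
#' @export
read_lapse <- function(tiff_path, json_path = paste0(tiff_path, ".json")) {
  if (!file.exists(json_path)) {
    stop_validation(paste0(
      "missing sidecar JSON (", json_path, "); it must supply pixel_size_um",
      " and times_min"))
  }
  side <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (is.null(side$pixel_size_um)) {
    stop_validation("sidecar lacks pixel_size_um")
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nf <- side$n_frames
  if (length(pages) != 2L * nf) {
    stop_validation(sprintf(
      "page count mismatch: %d pages for %d two-channel frames (channels: %s)",
      length(pages), nf,
      paste(unlist(side$channels), collapse = ", ")))
  }
  times_min <- unlist(side$times_min)
  if (nf > 1 && any(diff(times_min) <= 0)) {
    stop_validation("sidecar times_min not strictly increasing")
  }
  scale <- side$intensity_scale %||% 1
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    frames[[k]] <- list(lipid = t(pages[[2L * k - 1L]]) * scale,
                        actin = t(pages[[2L * k]]) * scale)
  }
  gt <- NULL
  if (!is.null(side$ground_truth)) {
    gt <- lapply(side$ground_truth, function(s) {
      s <- lapply(s, function(x) if (is.list(x)) x else unlist(x))
      if (!is.null(s$domain_arc_bounds_deg)) {
        s$domain_arc_bounds_deg <-
          do.call(rbind, lapply(s$domain_arc_bounds_deg, unlist))
      }
      s$image_shape <- as.integer(unlist(s$image_shape))
      class(s) <- "synth_spec"
      s
    })
  }
  image_lapse(frames, times_min, as.numeric(side$pixel_size_um),
              ground_truth = gt)
}
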