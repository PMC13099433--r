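# Format plumbing: NIfTI BOLD volumes + JSON sidecar, flat-binary EEG with
# a JSON header, ratings TSV.  All writers are paired with readers that
# reproduce the object (exact for integers and labels, to float precision
# for data).

#' Write / read a BOLD dataset as 4-D NIfTI plus a JSON sidecar
#'
#' Voxels are placed on their integer lattice positions inside a dense 4-D
#' array (background zero); the sidecar records the TR, spacing, origin,
#' per-voxel grid indices (so the voxel ordering round-trips exactly) and
#' the mask labels.
#'
#' @param bold a `BOLDDataset`.
#' @param path output `.nii` (or `.nii.gz`) path; the sidecar is written
#'   next to it with extension `.json`.
#' @return `write_bold_nifti` returns `path` invisibly; `read_bold_nifti`
#'   returns the `BOLDDataset`.
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "BOLDDataset"))
  origin <- apply(bold$coords, 2, min)
  grid <- sweep(bold$coords, 2, origin, `-`) / bold$spacing_mm
  grid <- round(grid) + 1L
  dims <- apply(grid, 2, max)
  arr <- array(0, dim = c(dims, ncol(bold$data)))
  for (v in seq_len(nrow(bold$data))) {
    arr[grid[v, 1], grid[v, 2], grid[v, 3], ] <- bold$data[v, ]
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(rep(bold$spacing_mm, 3), bold$tr))
  RNifti::writeNifti(img, path)
  sidecar <- list(format = "efpcouple-bold-v1",
                  tr = bold$tr,
                  spacing_mm = bold$spacing_mm,
                  origin_mm = as.numeric(origin),
                  subject_id = bold$subject_id,
                  voxel_grid_index = unname(grid),
                  voxel_coords_mm = unname(bold$coords),
                  mask_labels = bold$mask_labels)
  jsonlite::write_json(sidecar, .sidecar_path(path), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  sc <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  if (is.null(sc$format) || sc$format != "efpcouple-bold-v1") {
    stopf("'%s' has no compatible efpcouple sidecar", path)
  }
  arr <- as.array(RNifti::readNifti(path))
  grid <- as.matrix(sc$voxel_grid_index)
  data <- t(vapply(seq_len(nrow(grid)), function(v) {
    arr[grid[v, 1], grid[v, 2], grid[v, 3], ]
  }, numeric(dim(arr)[4])))
  coords <- as.matrix(sc$voxel_coords_mm)
  masks <- lapply(sc$mask_labels, as.integer)
  bold_dataset(data, sc$tr, coords, sc$spacing_mm, masks, sc$subject_id)
}

#' Write / read an EEG recording as flat binary plus a JSON header
#'
#' Samples are stored as little-endian float64, channel-major; the header
#' records shape, sampling rate and channel labels.
#'
#' @param rec an `EEGRecording`.
#' @param path output `.bin` path; the header goes next to it as `.json`.
#' @export
write_eeg_binary <- function(rec, path) {
  stopifnot(inherits(rec, "EEGRecording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
  header <- list(format = "efpcouple-eeg-v1",
                 fs = rec$fs,
                 n_channels = nrow(rec$samples),
                 n_samples = ncol(rec$samples),
                 channel_labels = rec$channel_labels,
                 reference = rec$reference,
                 dtype = "float64-le")
  jsonlite::write_json(header, sub("\\.bin$", ".json", path), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eeg_binary
#' @export
read_eeg_binary <- function(path) {
  hd <- jsonlite::read_json(sub("\\.bin$", ".json", path),
                            simplifyVector = TRUE)
  if (is.null(hd$format) || hd$format != "efpcouple-eeg-v1") {
    stopf("'%s' has no compatible efpcouple EEG header", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = hd$n_channels * hd$n_samples, size = 8,
               endian = "little")
  samples <- matrix(x, nrow = hd$n_channels, byrow = TRUE)
  eeg_recording(samples, hd$fs, hd$channel_labels, hd$reference)
}

#' Write / read rating traces as TSV
#'
#' Long format with columns `subject`, `scene`, `time_s`, `value`.
#'
#' @param traces list of `RatingTrace` objects (possibly nested per
#'   subject).
#' @param path output file path.
#' @export
write_ratings_tsv <- function(traces, path) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "RatingTrace")) {
      flat[[length(flat) + 1L]] <<- x
    } else if (is.list(x)) {
      lapply(x, collect)
    }
    invisible(NULL)
  }
  collect(traces)
  if (length(flat) == 0L) stopf("no rating traces supplied")
  df <- do.call(rbind, lapply(flat, function(tr) {
    data.frame(subject = tr$subject_id, scene = tr$scene,
               time_s = tr$t, value = tr$values, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_tsv
#' @export
read_ratings_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(df$subject)) {
    per <- list()
    sub_df <- df[df$subject == sid, ]
    for (sc in unique(sub_df$scene)) {
      d <- sub_df[sub_df$scene == sc, ]
      per[[sc]] <- rating_trace(d$time_s, d$value, scene = sc,
                                subject_id = sid)
    }
    out[[sid]] <- per
  }
  out
}
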