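#' Population activity raster
#'
#' A raster is a neurons x frames numeric matrix of extracted calcium traces
#' with a frame-rate attribute. Downstream model fitting assumes traces have
#' been z-scored per neuron.
#'
#' @param mat neurons x frames numeric matrix.
#' @param frame_rate sampling rate in Hz.
#' @param zscored logical; set by [zscore_raster()].
#' @return a `population_raster` matrix.
#' @export
population_raster <- function(mat, frame_rate = 10, zscored = FALSE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  attr(mat, "frame_rate") <- frame_rate
  attr(mat, "zscored") <- zscored
  class(mat) <- c("population_raster", class(mat))
  mat
}

#' Z-score each neuron's trace
#'
#' Rows with zero variance cannot be z-scored; they are flagged and dropped
#' with a warning rather than silently producing NaNs.
#'
#' @param raster a [population_raster()].
#' @return z-scored `population_raster` (possibly with fewer rows); dropped
#'   row indices in attribute `dropped`.
#' @export
zscore_raster <- function(raster) {
  fr <- attr(raster, "frame_rate")
  m <- unclass(raster)
  sds <- apply(m, 1, stats::sd)
  drop <- which(sds == 0 | !is.finite(sds))
  if (length(drop) > 0) {
    warning(length(drop), " constant/non-finite neuron(s) dropped before z-scoring")
    m <- m[-drop, , drop = FALSE]
    sds <- sds[-drop]
  }
  z <- (m - rowMeans(m)) / sds
  out <- population_raster(z, frame_rate = fr, zscored = TRUE)
  attr(out, "dropped") <- drop
  out
}

#' Read a raster from CSV
#'
#' Expects a plain numeric CSV, one neuron per row, one frame per column.
#' Traces are z-scored on load unless `zscore = FALSE`.
#'
#' @param path CSV file path.
#' @param frame_rate sampling rate in Hz (required; there is no in-band
#'   metadata in a bare CSV).
#' @param zscore apply [zscore_raster()] (default TRUE).
#' @return a `population_raster`.
#' @export
read_raster <- function(path, frame_rate, zscore = TRUE) {
  if (missing(frame_rate) || is.null(frame_rate))
    stop("frame_rate must be supplied when reading a raster")
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))
    warning(length(bad), " row(s) with NaN dropped")
    m <- m[-bad, , drop = FALSE]
  }
  r <- population_raster(m, frame_rate = frame_rate)
  if (zscore) r <- zscore_raster(r)
  r
}

#' Write a raster to CSV
#' @param raster a [population_raster()].
#' @param path output path.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(unclass(raster), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bout table from CSV
#'
#' Schema: columns `actor`, `behavior`, `start_frame`, `stop_frame`.
#' Overlapping bouts within an (actor, behaviour) pair are rejected with the
#' offending row numbers.
#'
#' @param path CSV path.
#' @param frame_rate Hz.
#' @param grouping grouping map (default [default_grouping()]).
#' @return a [bout_table()].
#' @export
read_bouts <- function(path, frame_rate = 10, grouping = default_grouping()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("actor", "behavior", "start_frame", "stop_frame")
  if (!all(need %in% names(df)))
    stop("bout CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$start_frame) | !is.finite(df$stop_frame) |
                 df$start_frame >= df$stop_frame)
  if (length(bad) > 0)
    stop("malformed bout row(s): ", paste(bad, collapse = ", "))
  # report overlaps with row numbers before delegating to the constructor
  o <- order(df$actor, df$behavior, df$start_frame)
  ds <- df[o, ]
  key <- paste(ds$actor, ds$behavior)
  same <- key[-1] == key[-length(key)]
  ovl <- which(same & ds$start_frame[-1] < ds$stop_frame[-nrow(ds)])
  if (length(ovl) > 0)
    stop("overlapping bouts at row(s): ",
         paste(sort(o[ovl + 1]), collapse = ", "))
  bout_table(df$actor, df$behavior, df$start_frame, df$stop_frame,
             frame_rate = frame_rate, grouping = grouping)
}

#' Write a bout table to CSV
#' @param bouts a [bout_table()].
#' @param path output path.
#' @export
write_bouts <- function(bouts, path) {
  df <- data.frame(actor = bouts$actor, behavior = bouts$behavior,
                   start_frame = bouts$start, stop_frame = bouts$stop)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
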