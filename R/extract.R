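#' Extract the nine morpho-colorimetric descriptors for every grain
#'
#' One row per labeled grain with columns `grain_id`, `FD`, `Cir`, `AR`,
#' `Ext`, `APIdx`, `L`, `a`, `b`, `YI`. APIdx is normalized within this
#' image's batch of grains (its minimum over rows is 0); for a single-grain
#' image APIdx is set to 0.
#'
#' @param image Height x width x 3 array in \[0,1\].
#' @param labels A `labeled_regions` object from [label_grains()], or an
#'   integer label matrix.
#' @return A data.frame with 10 columns (empty for a grain-free image).
#' @examples
#' sc <- render_grain_scene(read_class_specs()[1:2], 5, seed = 3)
#' feats <- extract_features(sc$image, label_grains(sc$image))
#' colnames(feats)
#' @export
extract_features <- function(image, labels) {
  labm <- if (inherits(labels, "labeled_regions")) labels$labels else labels
  n <- max(labm)
  if (n == 0) {
    return(data.frame(grain_id = integer(0), FD = numeric(0), Cir = numeric(0),
                      AR = numeric(0), Ext = numeric(0), APIdx = numeric(0),
                      L = numeric(0), a = numeric(0), b = numeric(0),
                      YI = numeric(0)))
  }
  geoms <- lapply(seq_len(n), function(k) measure_geometry(labm, k))
  apidx <- if (n >= 2) api_index(geoms) else 0
  rows <- lapply(seq_len(n), function(k) {
    g <- geoms[[k]]
    col <- grain_color(image, labm, k)
    data.frame(grain_id = k,
               FD = fractal_dimension(labm == k),
               Cir = circularity(g), AR = aspect_ratio(g), Ext = extent(g),
               APIdx = apidx[k],
               L = col["L"], a = col["a"], b = col["b"],
               YI = yellowness_index(col["L"], col["b"]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write a feature table to CSV
#'
#' @param table Feature data.frame (any column set).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
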