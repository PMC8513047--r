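#' Read a grain class specification file
#'
#' A class specification describes, for each grain class, the geometry used
#' by the scene renderer (semi-major axis in pixels, aspect ratio,
#' boundary-waviness amplitude), the CIELab color, the background polarity
#' the class is photographed on, and the per-class moments of the nine
#' morpho-colorimetric descriptors used by [sample_feature_table()].
#'
#' @param path Path to a JSON specification file. The default reads the
#'   packaged catalogue of 15 commercial rice classes (Koshihikari through
#'   organic wild rice) whose descriptor moments span short/bold to
#'   long/slender grain shapes (aspect-ratio means 1.58-5.19) and white
#'   through black pericarp color (L means 27.5-59.5).
#' @return A list of class `class_specs`: one element per class, each with
#'   fields `class_id`, `abbreviation`, `name`, `n_ref`,
#'   `background_polarity`, `geometry`, `color` and `features`.
#' @examples
#' specs <- read_class_specs()
#' length(specs)            # 15
#' specs[[15]]$abbreviation # "WRO"
#' @export
read_class_specs <- function(path = system.file("extdata", "rice_classes.json",
                                                package = "grainclass")) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- raw$classes
  if (is.null(specs) || length(specs) == 0L)
    stop("class specification file contains no classes: ", path)
  for (s in specs) validate_class_spec(s)
  structure(specs, class = "class_specs")
}

validate_class_spec <- function(s) {
  stopifnot(is.numeric(s$class_id), s$class_id >= 1)
  if (s$geometry$aspect_ratio$mean < 1)
    stop("class ", s$abbreviation, ": aspect-ratio mean must be >= 1")
  if (s$color$L$mean < 0 || s$color$L$mean > 100)
    stop("class ", s$abbreviation, ": L mean must lie in [0, 100]")
  disp <- c(s$geometry$semi_major$sd, s$geometry$aspect_ratio$sd,
            s$geometry$waviness$sd,
            vapply(s$features, function(f) f$sd, numeric(1)))
  if (any(disp < 0))
    stop("class ", s$abbreviation, ": dispersions must be >= 0")
  if (!s$background_polarity %in% c("dark", "light"))
    stop("class ", s$abbreviation, ": background_polarity must be dark or light")
  invisible(TRUE)
}

#' @export
print.class_specs <- function(x, ...) {
  cat("Grain class specification:", length(x), "classes\n")
  for (s in x)
    cat(sprintf("  %2d %-4s AR %.2f  L %5.1f  bg %s  n_ref %d\n",
                s$class_id, s$abbreviation, s$geometry$aspect_ratio$mean,
                s$color$L$mean, s$background_polarity, s$n_ref))
  invisible(x)
}

#' Per-class reference grain counts of a class specification
#'
#' @param specs A `class_specs` list, see [read_class_specs()].
#' @return Named integer vector of reference grain counts (names are class
#'   abbreviations).
#' @export
class_counts <- function(specs) {
  setNames(vapply(specs, function(s) as.integer(s$n_ref), integer(1)),
           vapply(specs, function(s) s$abbreviation, character(1)))
}

# per-class feature moment matrices (rows = classes, cols = features)
spec_feature_means <- function(specs) {
  m <- t(vapply(specs, function(s)
    vapply(s$features[FEATURE_NAMES], function(f) f$mean, numeric(1)),
    numeric(length(FEATURE_NAMES))))
  rownames(m) <- vapply(specs, function(s) s$abbreviation, character(1))
  colnames(m) <- FEATURE_NAMES
  m
}

spec_feature_sds <- function(specs) {
  m <- t(vapply(specs, function(s)
    vapply(s$features[FEATURE_NAMES], function(f) f$sd, numeric(1)),
    numeric(length(FEATURE_NAMES))))
  rownames(m) <- vapply(specs, function(s) s$abbreviation, character(1))
  colnames(m) <- FEATURE_NAMES
  m
}
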