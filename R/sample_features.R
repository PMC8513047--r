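#' Sample a labeled feature table directly in descriptor space
#'
#' Draws per-grain descriptor vectors from the per-class moments of a class
#' specification, bypassing rendering and extraction. Eight descriptors (FD,
#' Cir, AR, Ext, APIdx, L, a, b) are independent Gaussian draws per class;
#' the yellowness index is then computed from the sampled L and b as
#' `YI = 142.86 * b / L`, never sampled independently, so the YI column is
#' exactly consistent with the color columns. Values are clipped to
#' descriptor domains (Cir > 0, AR >= 1, 0 < Ext <= 1, 0 <= L <= 100).
#'
#' @param specs A `class_specs` list providing `features` moments per class.
#' @param n_per_class Rows sampled per class (0 gives an empty table).
#' @param seed Integer seed for reproducible draws.
#' @param sd_scale Multiplier applied to all class dispersions (1 keeps the
#'   specified moments; small values give well-separated classes for
#'   classifier stress tests).
#' @return A data.frame with the nine feature columns plus `class_id`.
#' @examples
#' tab <- sample_feature_table(read_class_specs(), n_per_class = 10, seed = 1)
#' dim(tab)  # 150 x 10
#' @export
sample_feature_table <- function(specs, n_per_class, seed = NULL, sd_scale = 1) {
  stopifnot(n_per_class >= 0, sd_scale >= 0)
  for (s in specs) {
    sds <- vapply(s$features, function(f) f$sd, numeric(1))
    if (any(sds < 0)) stop("negative dispersion in class ", s$abbreviation)
  }
  empty <- as.data.frame(c(
    setNames(rep(list(numeric(0)), length(FEATURE_NAMES)), FEATURE_NAMES),
    list(class_id = integer(0))))
  if (n_per_class == 0) return(empty)
  with_seed(seed, {
    out <- lapply(specs, function(s) {
      draw <- function(f, lo = -Inf, hi = Inf)
        pmin(hi, pmax(lo, rnorm(n_per_class, s$features[[f]]$mean,
                                sd_scale * s$features[[f]]$sd)))
      L <- draw("L", 1e-6, 100)
      b <- draw("b")
      data.frame(FD = draw("FD", 0.95, 2.05), Cir = draw("Cir", 1e-6),
                 AR = draw("AR", 1), Ext = draw("Ext", 1e-6, 1),
                 APIdx = draw("APIdx", 0), L = L, a = draw("a"), b = b,
                 YI = yellowness_index(L, b), class_id = s$class_id)
    })
    do.call(rbind, out)
  })
}
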