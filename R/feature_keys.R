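#' Morphometric measures and cortical networks
#'
#' The pipeline works on 28 network-wise morphometric features: four
#' surface-based measures (cortical thickness, sulcal depth, surface area,
#' cortical volume) summarised within each of the seven canonical cortical
#' networks (visual, somatomotor, dorsal attention, ventral attention,
#' limbic, frontoparietal, default mode).
#'
#' @return `morph_measures()` and `morph_networks()` return character
#'   vectors; `feature_keys()` returns the 28 canonical feature column
#'   names in fixed (measure-major) order, each of the form
#'   `"<measure>__<network>"`.
#' @examples
#' feature_keys()[1:7]
#' @export
morph_measures <- function() {
  c("thickness", "sulcal_depth", "surface_area", "volume")
}

#' @rdname morph_measures
#' @export
morph_networks <- function() {
  c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")
}

#' @rdname morph_measures
#' @export
feature_keys <- function() {
  as.vector(t(outer(morph_measures(), morph_networks(), paste, sep = "__")))
}

#' Split feature keys into measure and network
#'
#' @param keys character vector of feature keys, e.g. `"thickness__VIS"`.
#' @return data.frame with columns `key`, `measure`, `network`.
#' @export
parse_feature_key <- function(keys) {
  parts <- strsplit(keys, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed feature key(s): ", paste(keys[bad], collapse = ", "))
  }
  measure <- vapply(parts, `[`, "", 1L)
  network <- vapply(parts, `[`, "", 2L)
  if (!all(measure %in% morph_measures())) {
    stop("unknown measure in key(s): ",
         paste(unique(measure[!measure %in% morph_measures()]), collapse = ", "))
  }
  if (!all(network %in% morph_networks())) {
    stop("unknown network in key(s): ",
         paste(unique(network[!network %in% morph_networks()]), collapse = ", "))
  }
  data.frame(key = keys, measure = measure, network = network,
             stringsAsFactors = FALSE, row.names = NULL)
}
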