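#' @include AllClasses.R
NULL

#' Number of spots in a grid, slide or cohort member
#' @param x a SpotGrid or Slide.
#' @return integer spot count.
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' Spot grid accessor
#' @param x a Slide.
#' @return the [SpotGrid-class].
#' @export
setGeneric("spotGrid", function(x) standardGeneric("spotGrid"))

#' Protocol profile accessor
#' @param x a Slide.
#' @return the [ProtocolProfile-class].
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Slide identifier accessor
#' @param x a Slide.
#' @return character slide id.
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' Per-spot region labels
#' @param x a Slide or TissueField.
#' @return character vector of tumor/interface/distal labels.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' Extract one image patch centered on a spot
#' @param x an image source or Slide.
#' @param spotIndex index of the spot in grid order.
#' @param patchPx patch side length in pixels.
#' @return numeric patchPx x patchPx x channels array.
#' @export
setGeneric("spotPatch",
  function(x, spotIndex, patchPx) standardGeneric("spotPatch"))

#' Per-slide Shapley values
#' @param x a ShapleyEstimate or ValuationResult.
#' @return named numeric vector of phi values.
#' @export
setGeneric("shapleyValues", function(x) standardGeneric("shapleyValues"))

#' Evaluate the coalition value of a training-slide subset
#' @param valueFn a [ValueFunction-class].
#' @param subset character vector of slide ids (possibly empty).
#' @return numeric coalition value V(subset); memoized.
#' @export
setGeneric("evaluateSubset",
  function(valueFn, subset) standardGeneric("evaluateSubset"))
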