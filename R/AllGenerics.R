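#' Accessors for harvalue data objects
#'
#' Bioconductor-style accessor generics: use these rather than reaching into
#' slots with `@`.
#'
#' @param x a harvalue S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname accessors
#' @export
setGeneric("splits", function(x) standardGeneric("splits"))

#' @rdname accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname accessors
#' @export
setGeneric("channelStats", function(x) standardGeneric("channelStats"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("sampleIndex", function(x) standardGeneric("sampleIndex"))

#' @rdname accessors
#' @export
setGeneric("corruptedIndices", function(x) standardGeneric("corruptedIndices"))

#' @rdname accessors
#' @export
setGeneric("originalLabels", function(x) standardGeneric("originalLabels"))

#' @rdname accessors
#' @export
setGeneric("discovery", function(x) standardGeneric("discovery"))

#' @rdname accessors
#' @export
setGeneric("removalFractions", function(x) standardGeneric("removalFractions"))

# ---- methods ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("signals", "WindowedDataset", function(x) x@signals)

#' @rdname accessors
#' @export
setMethod("windowLabels", "WindowedDataset", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("splits", "WindowedDataset", function(x) x@split)

#' @rdname accessors
#' @export
setMethod("nClasses", "WindowedDataset", function(x) x@nClasses)

#' @rdname accessors
#' @export
setMethod("channelStats", "WindowedDataset", function(x) x@channelStats)

#' @rdname accessors
#' @export
setMethod("values", "ValueTable", function(x) x@probs)

#' @rdname accessors
#' @export
setMethod("sampleIndex", "ValueTable", function(x) x@sampleIndex)

#' @rdname accessors
#' @export
setMethod("corruptedIndices", "CorruptionRecord", function(x) x@indices)

#' @rdname accessors
#' @export
setMethod("originalLabels", "CorruptionRecord", function(x) x@originalLabels)

#' @rdname accessors
#' @export
setMethod("discovery", "CSDCurve", function(x) x@discovery)

#' @rdname accessors
#' @export
setMethod("removalFractions", "CSDCurve", function(x) x@removalFractions)

#' @rdname accessors
#' @export
setMethod("removalFractions", "RHLVSCurve", function(x) x@removalFractions)

# ---- show -------------------------------------------------------------------

setMethod("show", "WindowedDataset", function(object) {
  d <- dim(object@signals)
  cat(
    "WindowedDataset:", d[1L], "windows x", d[2L], "timesteps x",
    d[3L], "channels,", object@nClasses, "classes\n"
  )
  tb <- table(factor(object@split, c("train", "validation", "test")))
  cat(
    "  split: train", tb[["train"]], "| validation", tb[["validation"]],
    "| test", tb[["test"]], "\n"
  )
  cat(
    "  normalised:",
    if (nrow(object@channelStats)) "yes (training-split z-score)" else "no",
    "\n"
  )
})

setMethod("show", "CorruptionRecord", function(object) {
  cat(
    "CorruptionRecord:", length(object@indices), "flipped training labels",
    sprintf("(rate %.2f, seed %d)\n", object@rate, object@seed)
  )
})

setMethod("show", "ValueTable", function(object) {
  cat("ValueTable:", length(object@probs), "training-sample values\n")
  if (length(object@probs)) {
    q <- stats::quantile(object@probs, c(0, .25, .5, .75, 1))
    cat(sprintf(
      "  min %.4f | q25 %.4f | median %.4f | q75 %.4f | max %.4f\n",
      q[1L], q[2L], q[3L], q[4L], q[5L]
    ))
  }
})

setMethod("show", "CSDCurve", function(object) {
  cat("CSDCurve over removal fractions",
    paste0(range(object@removalFractions), collapse = ".."), "\n")
  cat(sprintf(
    "  max discovery %.3f at fraction %.2f\n",
    max(object@discovery),
    object@removalFractions[which.max(object@discovery)]
  ))
})

setMethod("show", "RHLVSCurve", function(object) {
  cat("RHLVSCurve (", object@classifier, ")\n", sep = "")
  cat(sprintf(
    "  max accuracy removing low-value data: %.3f (baseline %.3f)\n",
    max(object@removeLowAcc), object@removeLowAcc[1L]
  ))
})
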