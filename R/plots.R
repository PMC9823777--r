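#' Plot a corrupted-sample-discovery curve
#'
#' Discovery fraction against the fraction of low-value data accumulated,
#' with the ideal (optimal) curve as a dashed reference line.
#'
#' @param x a [CSDCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "CSDCurve", y = "missing"), function(x, y, ...) {
  graphics::plot(x@removalFractions, x@optimal,
    type = "l", lty = 2, col = "grey40", ylim = c(0, 1),
    xlab = "fraction of low-value data accumulated",
    ylab = "fraction of corrupted samples discovered",
    main = "Corrupted sample discovery", ...
  )
  graphics::lines(x@removalFractions, x@discovery, type = "b", pch = 16)
  graphics::legend("bottomright", c("discovery", "optimal"),
    lty = c(1, 2), pch = c(16, NA), col = c("black", "grey40"), bty = "n")
  invisible(x)
})

#' Plot remove-high/low-value accuracy curves
#'
#' @param x an [RHLVSCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "RHLVSCurve", y = "missing"), function(x, y, ...) {
  rng <- range(c(x@removeHighAcc, x@removeLowAcc))
  graphics::plot(x@removalFractions, x@removeLowAcc,
    type = "b", pch = 16, ylim = rng + c(-0.02, 0.02),
    xlab = "fraction of data removed", ylab = "test accuracy",
    main = paste0("Remove high/low value data (", x@classifier, ")"), ...
  )
  graphics::lines(x@removalFractions, x@removeHighAcc, type = "b", pch = 1,
    lty = 2)
  graphics::legend("bottomleft", c("remove low-value", "remove high-value"),
    lty = c(1, 2), pch = c(16, 1), bty = "n")
  invisible(x)
})
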