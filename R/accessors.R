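## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for gdqprop objects
#' @description Slot access goes through these accessors rather than `@`.
#' @param object a gdqprop S4 object.
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("quadPoints", function(object) standardGeneric("quadPoints"))
#' @rdname accessors
#' @export
setGeneric("quadWeights", function(object) standardGeneric("quadWeights"))
#' @rdname accessors
#' @export
setGeneric("momentValues", function(object) standardGeneric("momentValues"))
#' @rdname accessors
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))
#' @rdname accessors
#' @export
setGeneric("nNear", function(object) standardGeneric("nNear"))
#' @rdname accessors
#' @export
setGeneric("nFar", function(object) standardGeneric("nFar"))
#' @rdname accessors
#' @export
setGeneric("rMax", function(object) standardGeneric("rMax"))
#' @rdname accessors
#' @export
setGeneric("propMatrix", function(object) standardGeneric("propMatrix"))
#' @rdname accessors
#' @export
setGeneric("sourceVector", function(object) standardGeneric("sourceVector"))
#' @rdname accessors
#' @export
setGeneric("nnzCount", function(object) standardGeneric("nnzCount"))
#' @rdname accessors
#' @export
setGeneric("epsTrace", function(object) standardGeneric("epsTrace"))
#' @rdname accessors
#' @export
setGeneric("epsMax", function(object) standardGeneric("epsMax"))
#' @rdname accessors
#' @export
setGeneric("isDiverged", function(object) standardGeneric("isDiverged"))
#' @rdname accessors
#' @export
setGeneric("profileRho", function(object) standardGeneric("profileRho"))
#' @rdname accessors
#' @export
setGeneric("sourceHistory", function(object) standardGeneric("sourceHistory"))

#' @rdname accessors
#' @export
setMethod("quadPoints", "QuadratureRule", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("quadWeights", "QuadratureRule", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("momentValues", "MomentTable", function(object) object@moments)
#' @rdname accessors
#' @export
setMethod("gridPoints", "InterpolationGrid", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("nNear", "InterpolationGrid",
          function(object) sum(object@points <= 10))
#' @rdname accessors
#' @export
setMethod("nFar", "InterpolationGrid",
          function(object) sum(object@points > 10))
#' @rdname accessors
#' @export
setMethod("rMax", "InterpolationGrid", function(object) object@RMax)
#' @rdname accessors
#' @export
setMethod("gridPoints", "PropagationMatrix", function(object) object@grid@points)
#' @rdname accessors
#' @export
setMethod("propMatrix", "PropagationMatrix", function(object) object@W)
#' @rdname accessors
#' @export
setMethod("sourceVector", "PropagationMatrix", function(object) object@s)
#' @rdname accessors
#' @export
setMethod("nnzCount", "PropagationMatrix",
          function(object) length(object@W@x))
#' @rdname accessors
#' @export
setMethod("nnzCount", "ErrorReport", function(object) object@nnz)
#' @rdname accessors
#' @export
setMethod("epsTrace", "ErrorReport",
          function(object) data.frame(step = object@epsSteps,
                                      eps = object@epsTrace))
#' @rdname accessors
#' @export
setMethod("epsMax", "ErrorReport", function(object) object@epsMax)
#' @rdname accessors
#' @export
setMethod("isDiverged", "ErrorReport", function(object) object@diverged)
#' @rdname accessors
#' @export
setMethod("isDiverged", "SimulationState", function(object) object@diverged)
#' @rdname accessors
#' @export
setMethod("profileRho", "SimulationState", function(object) object@rho)
#' @rdname accessors
#' @export
setMethod("sourceHistory", "SimulationState",
          function(object) data.frame(step = seq_len(object@step),
                                      chi = object@chi, F = object@F))
#' @rdname accessors
#' @export
setMethod("isDiverged", "Trajectory", function(object) object@state@diverged)
#' @rdname accessors
#' @export
setMethod("sourceHistory", "Trajectory",
          function(object) sourceHistory(object@state))
#' @rdname accessors
#' @export
setMethod("profileRho", "Trajectory", function(object) object@state@rho)
#' @rdname accessors
#' @export
setGeneric("recordedProfiles", function(object) standardGeneric("recordedProfiles"))
#' @rdname accessors
#' @export
setMethod("recordedProfiles", "Trajectory",
          function(object) {
            out <- object@recorded
            rownames(out) <- object@recSteps
            out
          })

setMethod("show", "QuadratureRule", function(object) {
  cat(sprintf("QuadratureRule (Gauss-diffusion): R = %g, N = %d\n",
              object@R, object@N))
  cat(sprintf("  points in [%.6g, %.6g], sum(weights) = %.15g\n",
              min(object@points), max(object@points), sum(object@weights)))
})

setMethod("show", "MomentTable", function(object) {
  cat(sprintf("MomentTable: R = %g, orders 0..%d at %d digits\n",
              object@R, object@nMax, object@precisionDigits))
  n <- min(object@nMax, 4L)
  for (k in 0:n) cat(sprintf("  M_%d = %s\n", k, object@momentStrings[k + 1]))
  if (object@nMax > n) cat("  ...\n")
})

setMethod("show", "InterpolationGrid", function(object) {
  cat(sprintf(
    "InterpolationGrid: I = %d (near %d, far %d), RMax = %g, tol = %g\n",
    length(object@points), nNear(object), nFar(object), object@RMax,
    object@tol))
})

setMethod("show", "PropagationMatrix", function(object) {
  I <- length(object@grid@points)
  cat(sprintf(
    "PropagationMatrix: I = %d, N = %d, NF = %d, nnz = %d (%.1f%% filled)\n",
    I, object@N, object@NF, nnzCount(object),
    100 * nnzCount(object) / I^2))
})

setMethod("show", "SimulationState", function(object) {
  cat(sprintf("SimulationState: step %d, max rho = %.6g%s\n", object@step,
              if (length(object@rho)) max(abs(object@rho)) else NA_real_,
              if (object@diverged) " [DIVERGED]" else ""))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d recorded profiles on %d grid points, %d steps%s\n",
              nrow(object@recorded), ncol(object@recorded), object@state@step,
              if (object@state@diverged) " [DIVERGED]" else ""))
})

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf(
    "ErrorReport [%s]: eps_max = %.3g over %d evaluated steps, nnz = %d%s\n",
    object@protocol, object@epsMax, length(object@epsSteps), object@nnz,
    if (object@diverged) " [DIVERGED]" else ""))
})
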