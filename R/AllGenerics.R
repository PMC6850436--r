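#' @include AllClasses.R
NULL

#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("oppHom", function(x) standardGeneric("oppHom"))

#' @export
setGeneric("hetHet", function(x) standardGeneric("hetHet"))

#' @export
setGeneric("hetHom", function(x) standardGeneric("hetHom"))

#' @export
setGeneric("homSame", function(x) standardGeneric("homSame"))

#' @export
setGeneric("relabelAlleles", function(x) standardGeneric("relabelAlleles"))

#' @export
setGeneric("swapIndividuals", function(x) standardGeneric("swapIndividuals"))

#' @export
setGeneric("r0", function(x) standardGeneric("r0"))

#' @export
setGeneric("r1", function(x) standardGeneric("r1"))

#' @export
setGeneric("kingKinship", function(x) standardGeneric("kingKinship"))

#' @export
setGeneric("ibsFractions", function(x) standardGeneric("ibsFractions"))

#' @export
setGeneric("leeStatistic", function(x) standardGeneric("leeStatistic"))

#' @export
setGeneric("thetaFromK", function(x) standardGeneric("thetaFromK"))

#' @export
setGeneric("kValues", function(x) standardGeneric("kValues"))

#' @export
setGeneric("sampleFreq", function(x, n, ...) standardGeneric("sampleFreq"))

#' @export
setGeneric("proportions10", function(x) standardGeneric("proportions10"))

#' @export
setGeneric("emLogLik", function(x) standardGeneric("emLogLik"))

#' @export
setGeneric("emConverged", function(x) standardGeneric("emConverged"))

#' @export
setGeneric("seEstimate", function(x) standardGeneric("seEstimate"))
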