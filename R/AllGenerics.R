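#' @rdname MinimizerSketchSet-class
#' @param x a `MinimizerSketchSet`
#' @export
setGeneric("sketchRecords", function(x) standardGeneric("sketchRecords"))

#' @rdname MinimizerSketchSet-class
#' @export
setGeneric("minimizerCounts", function(x) standardGeneric("minimizerCounts"))

#' @rdname MinimizerSketchSet-class
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname MinimizerSketchSet-class
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname MinimizerSketchSet-class
#' @export
setGeneric("sequenceLengths", function(x) standardGeneric("sequenceLengths"))

#' @rdname MinimizerSketchSet-class
#' @export
setGeneric("inputLabel", function(x) standardGeneric("inputLabel"))

#' @rdname ScaffoldingResult-class
#' @param x a `ScaffoldingResult`
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("unplacedSequences", function(x) standardGeneric("unplacedSequences"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("scaffoldPaths", function(x) standardGeneric("scaffoldPaths"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("agpTable", function(x) standardGeneric("agpTable"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("contigCuts", function(x) standardGeneric("contigCuts"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("placementReport", function(x) standardGeneric("placementReport"))

#' @rdname ScaffoldingResult-class
#' @export
setGeneric("minimizerGraph", function(x, ...) standardGeneric("minimizerGraph"))
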