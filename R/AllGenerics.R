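#' @include AllClasses.R
NULL

#' Accessors for EnvGrid objects
#'
#' @param x an [EnvGrid-class].
#' @return \code{layerNames} the layer identifiers; \code{gridValues} the
#'   rows x cols x layers array (masked cells are \code{NA});
#'   \code{gridMask} the logical validity matrix; \code{cellSize} the cell
#'   edge in degrees; \code{gridExtent} \code{c(xmin, xmax, ymin, ymax)};
#'   \code{nLayers} the layer count.
#' @name EnvGrid-accessors
NULL

#' @rdname EnvGrid-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname EnvGrid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname EnvGrid-accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @rdname EnvGrid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname EnvGrid-accessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))
#' @rdname EnvGrid-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Accessors for TallyTable objects
#'
#' @param x a [TallyTable-class].
#' @return \code{useCount} and \code{cumImportance} return named vectors over
#'   the pool; \code{avgImportance} returns cumulative importance divided by
#'   use count (0 for unused variables).
#' @name TallyTable-accessors
NULL

#' @rdname TallyTable-accessors
#' @export
setGeneric("useCount", function(x) standardGeneric("useCount"))
#' @rdname TallyTable-accessors
#' @export
setGeneric("cumImportance", function(x) standardGeneric("cumImportance"))
#' @rdname TallyTable-accessors
#' @export
setGeneric("avgImportance", function(x) standardGeneric("avgImportance"))

#' Accessors for EnsembleResult objects
#'
#' @param x an [EnsembleResult-class].
#' @return \code{sprintRecords} the list of sprint records; \code{finalTopK}
#'   the ordered final top-k variables; \code{tallyOf} the final
#'   [TallyTable-class]; \code{totalRuns} the number of runs executed.
#' @name EnsembleResult-accessors
NULL

#' @rdname EnsembleResult-accessors
#' @export
setGeneric("sprintRecords", function(x) standardGeneric("sprintRecords"))
#' @rdname EnsembleResult-accessors
#' @export
setGeneric("finalTopK", function(x) standardGeneric("finalTopK"))
#' @rdname EnsembleResult-accessors
#' @export
setGeneric("tallyOf", function(x) standardGeneric("tallyOf"))
#' @rdname EnsembleResult-accessors
#' @export
setGeneric("totalRuns", function(x) standardGeneric("totalRuns"))
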