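#' Accessor generics
#'
#' Small accessor family for the planning containers: structure masks and
#' names, voxel geometry, spot tables and achieved objective values are read
#' through these rather than via slot access.
#'
#' @param x object
#' @param name structure name
#' @param value replacement value
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname accessors
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname accessors
#' @export
setGeneric("bodyMask", function(x) standardGeneric("bodyMask"))

#' @rdname accessors
#' @export
setGeneric("rspMap", function(x) standardGeneric("rspMap"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeCm3", function(x) standardGeneric("voxelVolumeCm3"))

#' @rdname accessors
#' @export
setGeneric("structureVolumeCm3", function(x, name) standardGeneric("structureVolumeCm3"))

#' @rdname accessors
#' @export
setGeneric("addStructure", function(x, name, value) standardGeneric("addStructure"))

#' @rdname accessors
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname accessors
#' @export
setGeneric("scenarioTable", function(x) standardGeneric("scenarioTable"))

#' @rdname accessors
#' @export
setGeneric("spotWeights", function(x) standardGeneric("spotWeights"))

#' @rdname accessors
#' @export
setGeneric("achievedValues", function(x) standardGeneric("achievedValues"))

#' @rdname accessors
#' @export
setGeneric("activeSpots", function(x) standardGeneric("activeSpots"))

#' @rdname accessors
#' @export
setGeneric("tbFraction", function(x) standardGeneric("tbFraction"))

#' @rdname accessors
#' @export
setGeneric("metricTable", function(x) standardGeneric("metricTable"))

#' @rdname accessors
#' @export
setGeneric("ntcpTable", function(x) standardGeneric("ntcpTable"))
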