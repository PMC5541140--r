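#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("fieldAffine", function(x) standardGeneric("fieldAffine"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("meshNormals", function(x) standardGeneric("meshNormals"))

#' @rdname accessors
#' @export
setGeneric("planTrajectories", function(x) standardGeneric("planTrajectories"))

#' @rdname accessors
#' @export
setGeneric("planFeasible", function(x) standardGeneric("planFeasible"))

#' @rdname accessors
#' @export
setGeneric("planScore", function(x) standardGeneric("planScore"))

#' @rdname accessors
#' @export
setGeneric("candidateTargetPoints", function(x) standardGeneric("candidateTargetPoints"))

#' Accessors for seegplan S4 objects
#'
#' Slot access for the planner's data classes: field values and affines,
#' mesh geometry, plan trajectories and summaries.
#'
#' @param x the object.
#' @return The corresponding slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fieldValues", "TargetRiskMap", function(x) x@field@values)

#' @rdname accessors
#' @export
setMethod("fieldValues", "LabelVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("fieldAffine", "ScalarField", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("fieldAffine", "LabelVolume", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("fieldAffine", "TargetRiskMap", function(x) x@field@affine)

#' @rdname accessors
#' @export
setMethod("gridDim", "ScalarField", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("gridDim", "LabelVolume", function(x) dim(x@labels))

#' @rdname accessors
#' @export
setMethod("gridDim", "TargetRiskMap", function(x) dim(x@field@values))

#' @rdname accessors
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setMethod("meshNormals", "SurfaceMesh", function(x) x@vertexNormals)

#' @rdname accessors
#' @export
setMethod("planTrajectories", "ImplantationPlan", function(x) x@trajectories)

#' @rdname accessors
#' @export
setMethod("planFeasible", "ImplantationPlan", function(x) x@feasible)

#' @rdname accessors
#' @export
setMethod("planScore", "ImplantationPlan", function(x) x@STotal)

#' @rdname accessors
#' @export
setMethod("candidateTargetPoints", "CandidateTargetSet", function(x) x@targets)
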