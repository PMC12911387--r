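#' @name accessors
#' @title Accessors for DefCom, ANIMatrix and LineageMap
#' @description Accessor generics for the package's S4 containers.
#' @param x a `DefCom`, `ANIMatrix` or `LineageMap` object.
#' @return `genomes()` a `DNAStringSet`; `annotations()` a `data.frame`;
#'   `groundTruth()` a list; `aniValues()` a numeric matrix;
#'   `lineageAssignment()` a named character vector;
#'   `endosphereLineages()` a character vector; `strainIds()` a character
#'   vector of strain ids.
NULL

#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))
#' @rdname accessors
#' @export
setGeneric("lineageAssignment", function(x) standardGeneric("lineageAssignment"))
#' @rdname accessors
#' @export
setGeneric("endosphereLineages", function(x) standardGeneric("endosphereLineages"))
#' @rdname accessors
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname accessors
setMethod("genomes", "DefCom", function(x) x@genomes)
#' @rdname accessors
setMethod("annotations", "DefCom", function(x) x@annotations)
#' @rdname accessors
setMethod("groundTruth", "DefCom", function(x) x@groundTruth)
#' @rdname accessors
setMethod("strainIds", "DefCom", function(x) names(x@genomes))
#' @rdname accessors
setMethod("aniValues", "ANIMatrix", function(x) x@ani)
#' @rdname accessors
setMethod("strainIds", "ANIMatrix", function(x) rownames(x@ani))
#' @rdname accessors
setMethod("lineageAssignment", "LineageMap", function(x) x@assignment)
#' @rdname accessors
setMethod("endosphereLineages", "LineageMap", function(x)
  x@endosphereAssociated)
#' @rdname accessors
setMethod("strainIds", "LineageMap", function(x) names(x@assignment))
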