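#' Accessors for SFPGtools classes
#'
#' @param x a \linkS4class{ProteinCatalog}, \linkS4class{ScoringScheme} or
#'   \linkS4class{SFPGSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("keptRecords", function(x) standardGeneric("keptRecords"))
#' @rdname accessors
#' @export
setGeneric("excludedRecords", function(x) standardGeneric("excludedRecords"))
#' @rdname accessors
#' @export
setGeneric("toolNames", function(x) standardGeneric("toolNames"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("cutoffUsed", function(x) standardGeneric("cutoffUsed"))
#' @rdname accessors
#' @export
setGeneric("scoreType", function(x) standardGeneric("scoreType"))
#' @rdname accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname accessors
setMethod("keptRecords", "ProteinCatalog", function(x) x@records)
#' @rdname accessors
setMethod("excludedRecords", "ProteinCatalog", function(x) x@excluded)
#' @rdname accessors
setMethod("toolNames", "ScoringScheme", function(x) rownames(x@toolWeights))
#' @rdname accessors
setMethod("groups", "SFPGSet", function(x) x@groups)
#' @rdname accessors
setMethod("membership", "SFPGSet", function(x) x@membership)
#' @rdname accessors
setMethod("cutoffUsed", "SFPGSet", function(x) x@cutoff)
#' @rdname accessors
setMethod("scoreType", "SFPGSet", function(x) x@scoreType)
#' @rdname accessors
setMethod("groupSizes", "SFPGSet", function(x) lengths(x@groups))

#' @rdname accessors
#' @export
setMethod("length", "SFPGSet", function(x) length(x@groups))

#' @rdname accessors
#' @export
setMethod("length", "ProteinCatalog",
          function(x) nrow(x@records) + nrow(x@excluded))
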