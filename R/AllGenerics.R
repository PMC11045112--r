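#' Accessors
#'
#' Accessor generics for the package's S4 classes.
#'
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname accessors
#' @export
setGeneric("snpTable", function(x) standardGeneric("snpTable"))

#' @rdname accessors
#' @export
setGeneric("caseFraction", function(x) standardGeneric("caseFraction"))

#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' @rdname accessors
#' @export
setGeneric("totalR2", function(x) standardGeneric("totalR2"))

#' @rdname accessors
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))

#' @rdname accessors
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))

#' @rdname accessors
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' @rdname accessors
#' @export
setGeneric("outlierIds", function(x) standardGeneric("outlierIds"))

#' @rdname accessors
#' @export
setGeneric("globalPval", function(x) standardGeneric("globalPval"))

#' @rdname accessors
#' @export
setGeneric("directionOk", function(x) standardGeneric("directionOk"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("trueBeta", function(x) standardGeneric("trueBeta"))

#' @rdname accessors
#' @export
setGeneric("invalidIds", function(x) standardGeneric("invalidIds"))

#' Symmetric LD lookup
#'
#' Pairwise r-squared lookup: \code{ldR2(ld, a, b) == ldR2(ld, b, a)},
#' self-pairs return 1, absent pairs return 0 by convention (conservative
#' for clumping, strict for proxy search).
#'
#' @param ld an \linkS4class{LdTable}.
#' @param a,b character vectors of SNP ids (recycled to equal length).
#' @return numeric vector of r-squared values.
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))
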