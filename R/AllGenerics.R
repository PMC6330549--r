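#' @rdname ProteinStructure-class
#' @param x,object an object
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname ContactMap-class
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname ContactMap-class
#' @export
setGeneric("dnaFlags", function(x) standardGeneric("dnaFlags"))

#' @rdname ConsensusPattern-class
#' @export
setGeneric("patternText", function(x) standardGeneric("patternText"))

#' @rdname ConsensusPattern-class
#' @export
setGeneric("patternPositions", function(x) standardGeneric("patternPositions"))

#' @rdname BindingSiteProposal-class
#' @export
setGeneric("proposalEntries", function(x) standardGeneric("proposalEntries"))
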