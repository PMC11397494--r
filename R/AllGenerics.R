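#' Accessors for CneCatalog and MafAlignment
#'
#' `cneRanges()` returns the reference-coordinate `GRanges` of a catalog,
#' `cneStatus()` the species-by-element status matrix, `cneProjections()`
#' the per-species projected intervals, and `keptCnes()` the ids of elements
#' a given species retains after the redundancy and length-ratio filters.
#' `mafSpecies()` lists the species present in an alignment.
#'
#' @param x A `CneCatalog` (or `MafAlignment` for `mafSpecies`).
#' @param species Species name.
#' @return See the individual descriptions.
#' @name cne-accessors
NULL

#' @rdname cne-accessors
#' @export
setGeneric("cneRanges", function(x) standardGeneric("cneRanges"))

#' @rdname cne-accessors
#' @export
setMethod("cneRanges", "CneCatalog", function(x) x@ranges)

#' @rdname cne-accessors
#' @export
setGeneric("cneStatus", function(x) standardGeneric("cneStatus"))

#' @rdname cne-accessors
#' @export
setMethod("cneStatus", "CneCatalog", function(x) x@status)

#' @rdname cne-accessors
#' @export
setGeneric("cneProjections", function(x) standardGeneric("cneProjections"))

#' @rdname cne-accessors
#' @export
setMethod("cneProjections", "CneCatalog", function(x) x@projections)

#' @rdname cne-accessors
#' @export
setGeneric("keptCnes", function(x, species) standardGeneric("keptCnes"))

#' @rdname cne-accessors
#' @export
setMethod("keptCnes", "CneCatalog", function(x, species) {
  if (species == x@refSpecies)
    return(S4Vectors::mcols(x@ranges)$id)
  if (!species %in% rownames(x@status))
    stop("unknown species: ", species)
  S4Vectors::mcols(x@ranges)$id[x@status[species, ] == "kept"]
})

#' @rdname cne-accessors
#' @export
setGeneric("mafSpecies", function(x) standardGeneric("mafSpecies"))

#' @rdname cne-accessors
#' @export
setMethod("mafSpecies", "MafAlignment", function(x) {
  unique(unlist(lapply(x@blocks, function(b) names(b$seq)), use.names = FALSE))
})
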