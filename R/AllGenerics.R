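#' @include AllClasses.R
NULL

#' Accessors for ProteoRenorm containers
#'
#' `accessions`, `geneSymbols` and `uniquePeptides` extract per-protein
#' annotation; `sampleRoles` and `replicateGroups` extract the sample design;
#' `abundances` returns the abundance matrix (`NA` = not detected).
#' `geneSetIds`, `geneSetDescriptions` and `geneSetMembers` access a
#' [GeneSetCollection-class].
#'
#' @param x a [ProteinQuantExperiment-class] or [GeneSetCollection-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setGeneric("uniquePeptides", function(x) standardGeneric("uniquePeptides"))
#' @rdname accessors
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))
#' @rdname accessors
#' @export
setGeneric("replicateGroups", function(x) standardGeneric("replicateGroups"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("geneSetIds", function(x) standardGeneric("geneSetIds"))
#' @rdname accessors
#' @export
setGeneric("geneSetDescriptions",
           function(x) standardGeneric("geneSetDescriptions"))
#' @rdname accessors
#' @export
setGeneric("geneSetMembers", function(x) standardGeneric("geneSetMembers"))

#' @rdname accessors
#' @export
setMethod("accessions", "ProteinQuantExperiment",
          function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "ProteinQuantExperiment",
          function(x) rowData(x)$gene_symbol)
#' @rdname accessors
#' @export
setMethod("uniquePeptides", "ProteinQuantExperiment",
          function(x) rowData(x)$unique_peptides)
#' @rdname accessors
#' @export
setMethod("sampleRoles", "ProteinQuantExperiment", function(x) {
  r <- colData(x)$role
  names(r) <- colnames(x)
  r
})
#' @rdname accessors
#' @export
setMethod("replicateGroups", "ProteinQuantExperiment", function(x) {
  g <- colData(x)$replicate_group
  names(g) <- colnames(x)
  g
})
#' @rdname accessors
#' @export
setMethod("abundances", "ProteinQuantExperiment",
          function(x) assay(x, "abundance"))

#' @rdname accessors
#' @export
setMethod("geneSetIds", "GeneSetCollection", function(x) x@setIds)
#' @rdname accessors
#' @export
setMethod("geneSetDescriptions", "GeneSetCollection",
          function(x) stats::setNames(x@setDescriptions, x@setIds))
#' @rdname accessors
#' @export
setMethod("geneSetMembers", "GeneSetCollection",
          function(x) stats::setNames(x@members, x@setIds))

#' @rdname accessors
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setIds))
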