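#' Accessor generics
#'
#' Accessors for the S4 containers: \code{variantRecords} and
#' \code{growthResults} return the two tables of a
#' \code{\link{VariantPanel}}; \code{nVariants} its record count;
#' \code{curveData} and \code{endpointData} the tables of a
#' \code{\link{GrowthCurveSet}}; \code{atomData} the atom table of a
#' \code{\link{StructureModel}}.
#'
#' @param x the object.
#' @return the requested table or count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname accessors
#' @export
setGeneric("growthResults", function(x) standardGeneric("growthResults"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))

#' @rdname accessors
#' @export
setGeneric("endpointData", function(x) standardGeneric("endpointData"))

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setMethod("variantRecords", "VariantPanel", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("growthResults", "VariantPanel", function(x) x@growth)

#' @rdname accessors
#' @export
setMethod("nVariants", "VariantPanel", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("curveData", "GrowthCurveSet", function(x) x@curves)

#' @rdname accessors
#' @export
setMethod("endpointData", "GrowthCurveSet", function(x) x@endpoints)

#' @rdname accessors
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

setMethod("show", "VariantPanel", function(object) {
  cat("VariantPanel with", nrow(object@records), "variant records\n")
  if (nrow(object@records)) {
    tab <- table(factor(object@records$category, levels = .CATEGORIES))
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat("  ddG present:", sum(!is.na(object@records$ddg)), "of",
        nrow(object@records), "\n")
  }
  cat("  growth results:", nrow(object@growth), "variant x condition rows\n")
  cat("  reference:", object@referenceProtein, "/", object@referenceMrna, "\n")
})

setMethod("show", "GrowthCurveSet", function(object) {
  nw <- if (nrow(object@curves))
    length(unique(paste(object@curves$plate_id, object@curves$well_id))) else 0L
  cat("GrowthCurveSet:", nw, "wells,",
      nrow(object@curves), "reads,",
      length(unique(object@curves$plate_id)), "plate(s)\n")
})

setMethod("show", "StructureModel", function(object) {
  prot <- object@atoms[!object@atoms$het, , drop = FALSE]
  cat("StructureModel:", nrow(object@atoms), "atoms,",
      length(unique(paste(prot$chain, prot$resno))), "protein residues,",
      "chains:", paste(unique(object@atoms$chain), collapse = ","), "\n")
  het <- unique(object@atoms$resid[object@atoms$het])
  if (length(het)) cat("  ligand residues:", paste(het, collapse = ", "), "\n")
  cat("  numbering offset (NP - file):", object@offset, "\n")
})

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep over", length(object@thresholds), "cutoffs [",
      min(object@thresholds), ",", max(object@thresholds), "] kcal/mol,",
      object@nAlleles, "alleles\n")
  cat("  best threshold:", object@bestThreshold, "kcal/mol, percent correct:",
      sprintf("%.1f%%", 100 * max(object@percentCorrect)), "\n")
})
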