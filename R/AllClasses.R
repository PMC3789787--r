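#' @import methods
NULL

## Canonical one-letter amino-acid alphabet used throughout.
.AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.CATEGORIES <- c("nonfunctional", "sensitive", "benign")
.FLAGS <- c("none", "p01", "p001")

#' VariantPanel: a panel of single amino-acid CBS substitutions
#'
#' Container for a set of variant records (one substitution each, with an
#' optional Rosetta ddG prediction and a phenotype category) together with
#' the per-condition relative growth measurements in long form.
#'
#' The \code{records} slot has one row per variant with columns
#' \code{plasmid_id}, \code{nt_change}, \code{substitution}, \code{wt_aa},
#' \code{position} (NP_000062 numbering), \code{mut_aa}, \code{ddg}
#' (kcal/mol, \code{NA} when the residue is outside the solved structure),
#' \code{category} (nonfunctional/sensitive/benign) and \code{construction}
#' (directed/random/unknown). The \code{growth} slot has one row per
#' variant x assay condition with columns \code{substitution},
#' \code{pyridoxine} (ng/mL), \code{dala} (ug/mL, \code{NA} for HEM1
#' strains), \code{hem1_deleted}, \code{rate} (ratio to the major allele,
#' \code{NA} = no determinable growth), \code{sd}, \code{flag}
#' (none/p01/p001 mirroring the */** significance marks) and
#' \code{n_replicates}.
#'
#' Structural validity (column presence and types) is enforced by the class
#' validity method; domain invariants are checked by
#' \code{\link{validatePanel}}, which reports violations as data so that
#' deliberately broken panels can be constructed and inspected.
#'
#' @slot records data.frame of variant records.
#' @slot growth data.frame of per-condition growth results.
#' @slot referenceProtein protein reference sequence identifier.
#' @slot referenceMrna mRNA reference sequence identifier.
#' @export
setClass("VariantPanel",
  representation(
    records = "data.frame",
    growth = "data.frame",
    referenceProtein = "character",
    referenceMrna = "character"
  ),
  prototype(
    records = data.frame(),
    growth = data.frame(),
    referenceProtein = "NP_000062",
    referenceMrna = "NM_000071"
  )
)

setValidity("VariantPanel", function(object) {
  msgs <- character()
  rec_cols <- c("plasmid_id", "nt_change", "substitution", "wt_aa",
                "position", "mut_aa", "ddg", "category", "construction")
  gr_cols <- c("substitution", "pyridoxine", "dala", "hem1_deleted",
               "rate", "sd", "flag", "n_replicates")
  if (nrow(object@records) > 0 && !all(rec_cols %in% names(object@records)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(setdiff(rec_cols, names(object@records)), collapse = ", ")))
  if (nrow(object@growth) > 0 && !all(gr_cols %in% names(object@growth)))
    msgs <- c(msgs, paste("growth must have columns:",
                          paste(setdiff(gr_cols, names(object@growth)), collapse = ", ")))
  if (length(object@referenceProtein) != 1)
    msgs <- c(msgs, "referenceProtein must be length 1")
  if (length(object@referenceMrna) != 1)
    msgs <- c(msgs, "referenceMrna must be length 1")
  if (length(msgs)) msgs else TRUE
})

#' GrowthCurveSet: microplate OD595 time-series
#'
#' Long-format kinetic reads for a set of wells plus the per-well endpoint
#' read taken after resuspension. \code{curves} has columns
#' \code{plate_id}, \code{well_id}, \code{strain_label} (a substitution
#' token or \code{"major"}), \code{pyridoxine}, \code{dala},
#' \code{hem1_deleted}, \code{time_h}, \code{od595}; \code{endpoints} has
#' \code{plate_id}, \code{well_id}, \code{endpoint_od}.
#'
#' @slot curves data.frame of kinetic reads.
#' @slot endpoints data.frame of endpoint reads.
#' @export
setClass("GrowthCurveSet",
  representation(curves = "data.frame", endpoints = "data.frame"),
  prototype(curves = data.frame(), endpoints = data.frame())
)

setValidity("GrowthCurveSet", function(object) {
  msgs <- character()
  cc <- c("plate_id", "well_id", "strain_label", "pyridoxine", "dala",
          "hem1_deleted", "time_h", "od595")
  ec <- c("plate_id", "well_id", "endpoint_od")
  if (nrow(object@curves) > 0) {
    if (!all(cc %in% names(object@curves)))
      msgs <- c(msgs, paste("curves must have columns:",
                            paste(setdiff(cc, names(object@curves)), collapse = ", ")))
    else {
      if (any(object@curves$od595 < 0, na.rm = TRUE))
        msgs <- c(msgs, "od595 readings must be >= 0")
      key <- paste(object@curves$plate_id, object@curves$well_id)
      if (any(tapply(object@curves$time_h, key,
                     function(t) any(diff(t) <= 0) || length(t) < 2)))
        msgs <- c(msgs, "each well needs >= 2 strictly increasing time points")
    }
  }
  if (nrow(object@endpoints) > 0) {
    if (!all(ec %in% names(object@endpoints)))
      msgs <- c(msgs, paste("endpoints must have columns:",
                            paste(setdiff(ec, names(object@endpoints)), collapse = ", ")))
    else if (any(object@endpoints$endpoint_od <= 0, na.rm = TRUE))
      msgs <- c(msgs, "endpoint_od must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' StructureModel: a parsed protein structure with cofactor ligands
#'
#' Flat atom table distilled from a PDB file, plus helix/sheet annotation
#' ranges, the residue-name sets identifying the heme and PLP ligand
#' groups, and the offset mapping file residue numbering to NP_000062
#' numbering (\code{file_resno = position - offset}).
#'
#' Hydrogens are dropped on reading; alternate locations are resolved to
#' the highest-occupancy conformer; insertion codes are rejected.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety},
#'   \code{resid}, \code{chain}, \code{resno}, \code{x}, \code{y},
#'   \code{z}, \code{b}, \code{o}, \code{elesy}, \code{het}.
#' @slot helix data.frame of helix spans (\code{chain}, \code{start}, \code{end}).
#' @slot sheet data.frame of strand spans (\code{chain}, \code{start}, \code{end}).
#' @slot ligands named list of residue-name sets, elements \code{heme}, \code{plp}.
#' @slot offset integer scalar; NP numbering minus file numbering.
#' @export
setClass("StructureModel",
  representation(
    atoms = "data.frame",
    helix = "data.frame",
    sheet = "data.frame",
    ligands = "list",
    offset = "integer"
  ),
  prototype(
    atoms = data.frame(),
    helix = data.frame(chain = character(), start = integer(), end = integer()),
    sheet = data.frame(chain = character(), start = integer(), end = integer()),
    ligands = list(heme = "HEM", plp = c("PLP", "LLP")),
    offset = 0L
  )
)

setValidity("StructureModel", function(object) {
  msgs <- character()
  ac <- c("eleno", "elety", "resid", "chain", "resno",
          "x", "y", "z", "b", "o", "elesy", "het")
  if (nrow(object@atoms) > 0) {
    if (!all(ac %in% names(object@atoms)))
      msgs <- c(msgs, paste("atoms must have columns:",
                            paste(setdiff(ac, names(object@atoms)), collapse = ", ")))
    else {
      xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
      if (!all(is.finite(xyz)))
        msgs <- c(msgs, "atom coordinates must be finite")
      if (!any(!object@atoms$het))
        msgs <- c(msgs, "model must contain at least one protein (ATOM) record")
    }
  }
  if (!all(c("heme", "plp") %in% names(object@ligands)))
    msgs <- c(msgs, "ligands must name 'heme' and 'plp' residue-name sets")
  if (length(object@offset) != 1 || is.na(object@offset))
    msgs <- c(msgs, "offset must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' ThresholdSweep: classification accuracy as a function of a ddG cutoff
#'
#' @slot thresholds numeric grid of cutoffs (kcal/mol), strictly increasing.
#' @slot percentCorrect fraction correctly classified at each cutoff.
#' @slot nAlleles number of alleles used (those with both a ddG and a call).
#' @slot bestThreshold argmax cutoff; ties resolved to the smallest.
#' @export
setClass("ThresholdSweep",
  representation(
    thresholds = "numeric",
    percentCorrect = "numeric",
    nAlleles = "integer",
    bestThreshold = "numeric"
  )
)

setValidity("ThresholdSweep", function(object) {
  msgs <- character()
  if (length(object@thresholds) != length(object@percentCorrect))
    msgs <- c(msgs, "thresholds and percentCorrect must have equal length")
  if (any(diff(object@thresholds) <= 0))
    msgs <- c(msgs, "thresholds must be strictly increasing")
  if (any(object@percentCorrect < 0 | object@percentCorrect > 1))
    msgs <- c(msgs, "percentCorrect must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
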