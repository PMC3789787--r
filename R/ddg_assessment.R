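#' Growth indicator per variant
#'
#' \code{TRUE} for every variant that conferred some growth (category
#' sensitive or benign), \code{FALSE} for nonfunctional.
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @return named logical vector, one element per record.
#' @export
growthIndicator <- function(panel) {
  rec <- variantRecords(panel)
  stats::setNames(rec$category != "nonfunctional", rec$substitution)
}

#' Classification accuracy of a ddG threshold
#'
#' For the alleles with a ddG prediction, the fraction correctly
#' classified at cutoff \code{threshold}: growing alleles with ddG
#' strictly below the cutoff, plus non-growing alleles with ddG at or
#' above it, over all scored alleles. ("Below" is strict and "above" is
#' inclusive; the 0.5 kcal/mol sweep grid is offset from the one-decimal
#' ddG values so the boundary convention rarely binds.)
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @param threshold cutoff in kcal/mol.
#' @return fraction in [0, 1].
#' @examples
#' percentCorrect(loadTable1(), 4.0)
#' @export
percentCorrect <- function(panel, threshold) {
  rec <- variantRecords(panel)
  rec <- rec[!is.na(rec$ddg), , drop = FALSE]
  if (nrow(rec) == 0) stop("no alleles with a ddG prediction")
  grows <- rec$category != "nonfunctional"
  (sum(grows & rec$ddg < threshold) +
     sum(!grows & rec$ddg >= threshold)) / nrow(rec)
}

#' Sweep classification accuracy over a ddG grid
#'
#' Evaluates \code{\link{percentCorrect}} on a regular cutoff grid
#' (default 0.5 kcal/mol steps) and reports the best cutoff, resolving
#' ties to the smallest (most inclusive impaired class).
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @param t_min,t_max grid limits in kcal/mol.
#' @param step grid increment (default 0.5).
#' @return a \code{\link{ThresholdSweep}}.
#' @examples
#' sw <- thresholdSweep(loadTable1())
#' sw
#' @export
thresholdSweep <- function(panel, t_min = -3, t_max = 15, step = 0.5) {
  stopifnot(t_min < t_max, step > 0)
  grid <- seq(t_min, t_max, by = step)
  pc <- vapply(grid, function(t) percentCorrect(panel, t), numeric(1))
  rec <- variantRecords(panel)
  new("ThresholdSweep", thresholds = grid, percentCorrect = pc,
      nAlleles = sum(!is.na(rec$ddg)),
      bestThreshold = grid[which.max(pc)])
}

#' Scatter-plot table of ddG against high-B6 growth
#'
#' One row per allele with a ddG prediction: predicted ddG, relative
#' growth rate at 400 ng/mL pyridoxine (0 for nonfunctional alleles, as
#' printed), and phenotype category.
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @param high_dose the plotted dose (ng/mL).
#' @return data.frame: \code{substitution}, \code{ddg}, \code{growth},
#'   \code{category}.
#' @export
scatterTable <- function(panel, high_dose = 400) {
  rec <- variantRecords(panel)
  gr <- growthResults(panel)
  rec <- rec[!is.na(rec$ddg), , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(substitution = character(), ddg = numeric(),
                      growth = numeric(), category = character()))
  hi <- gr[!gr$hem1_deleted & gr$pyridoxine == high_dose, ]
  growth <- hi$rate[match(rec$substitution, hi$substitution)]
  growth[rec$category == "nonfunctional"] <- 0
  data.frame(substitution = rec$substitution, ddg = rec$ddg,
             growth = growth, category = rec$category)
}
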