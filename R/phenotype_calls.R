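#' Welch comparison of replicate relative rates
#'
#' Two-sided Welch (unequal-variance) two-sample t-test of variant
#' replicate ratios against major-allele replicate ratios, with the assay
#' significance cuts: \code{p01} for P < 0.01 and \code{p001} for
#' P < 0.001. Direction is the sign of the mean difference. When both
#' samples are constant, P is 1 for equal means and 0 otherwise by
#' convention.
#'
#' @param variant_ratios,major_ratios numeric vectors of replicate values
#'   (at least 2 each; the assay uses >= 3 independent transformants).
#' @return list with \code{p_value}, \code{flag} (none/p01/p001) and
#'   \code{direction} (faster/slower/none).
#' @export
compareReplicates <- function(variant_ratios, major_ratios) {
  variant_ratios <- variant_ratios[!is.na(variant_ratios)]
  major_ratios <- major_ratios[!is.na(major_ratios)]
  if (length(variant_ratios) < 2 || length(major_ratios) < 2)
    stop("insufficient replicates: need >= 2 values per sample")
  diff_mean <- mean(variant_ratios) - mean(major_ratios)
  if (stats::var(variant_ratios) == 0 && stats::var(major_ratios) == 0) {
    p <- if (diff_mean == 0) 1 else 0
  } else {
    p <- stats::t.test(variant_ratios, major_ratios,
                       alternative = "two.sided", var.equal = FALSE)$p.value
  }
  flag <- if (p < 0.001) "p001" else if (p < 0.01) "p01" else "none"
  direction <- if (flag == "none") "none"
               else if (diff_mean > 0) "faster" else "slower"
  list(p_value = p, flag = flag, direction = direction)
}

.call_one <- function(high_rate, flags, directions) {
  if (is.na(high_rate) || high_rate == 0) {
    list(category = "nonfunctional", faster_than_wt = NA)
  } else if (any(flags != "none")) {
    list(category = "sensitive",
         faster_than_wt = all(directions[flags != "none"] == "faster"))
  } else {
    list(category = "benign", faster_than_wt = FALSE)
  }
}

#' Assign the three growth-phenotype categories
#'
#' A variant that confers no growth at the highest pyridoxine dose (400
#' ng/mL) is \emph{nonfunctional}; otherwise it is \emph{sensitive} if its
#' relative rate differs significantly from the major allele at any dose,
#' and \emph{benign} if not. A sensitive variant is additionally marked
#' \code{faster_than_wt} when every flagged condition points faster than
#' the major allele.
#'
#' With the bundled tables no raw replicates exist, so the printed
#' significance flags are taken as authoritative and direction comes from
#' the sign of \code{rate - 1}. For synthetic or raw data, pass
#' \code{ratios} (the \code{replicates} table of
#' \code{\link{relativeRates}} plus a \code{major} column of reference
#' replicate ratios) to recompute flags with
#' \code{\link{compareReplicates}}.
#'
#' @param panel a \code{\link{VariantPanel}} (HEM1-background growth rows).
#' @param high_dose the dose defining "highest supplementation" (ng/mL).
#' @return data.frame with one row per variant: \code{substitution},
#'   \code{category}, \code{faster_than_wt}.
#' @examples
#' calls <- classifyPanel(loadTable1())
#' table(calls$category)
#' @export
classifyPanel <- function(panel, high_dose = 400) {
  stopifnot(is(panel, "VariantPanel"))
  gr <- growthResults(panel)
  subs <- variantRecords(panel)$substitution
  out <- lapply(subs, function(s) {
    g <- gr[gr$substitution == s & !gr$hem1_deleted, ]
    hi <- g[g$pyridoxine == high_dose, ]
    if (nrow(hi) == 0)
      stop("missing high-pyridoxine (", high_dose, " ng/mL) observation for ", s)
    direction <- ifelse(is.na(g$rate), "none",
                        ifelse(g$rate > 1, "faster", "slower"))
    .call_one(hi$rate[1], g$flag, direction)
  })
  data.frame(substitution = subs,
             category = vapply(out, `[[`, character(1), "category"),
             faster_than_wt = vapply(out, function(x)
               as.logical(x$faster_than_wt), logical(1)))
}

#' Recompute phenotype calls from replicate-level ratios
#'
#' Runs \code{\link{compareReplicates}} per variant and condition on raw
#' replicate relative rates (e.g. from a synthetic panel put through the
#' rate pipeline) and then applies the same category logic as
#' \code{\link{classifyPanel}}. The major-allele replicate ratios per
#' condition are each well's normalized rate over the reference
#' per-condition mean, so they scatter around 1.
#'
#' @param replicate_ratios data.frame with columns \code{strain_label},
#'   \code{pyridoxine}, \code{dala}, \code{hem1_deleted}, \code{ratio}
#'   (NA = no attained growth).
#' @param major_ratios data.frame with columns \code{pyridoxine},
#'   \code{dala}, \code{hem1_deleted}, \code{ratio} for the reference
#'   strain wells.
#' @param high_dose dose defining the nonfunctional cut (ng/mL).
#' @return data.frame: \code{substitution}, \code{category},
#'   \code{faster_than_wt}, plus per-condition long rows in attribute
#'   \code{"per_condition"} (condition, p_value, flag, direction).
#' @export
classifyFromReplicates <- function(replicate_ratios, major_ratios,
                                   high_dose = 400) {
  ckey <- function(d) paste(d$pyridoxine, d$dala, d$hem1_deleted, sep = "\r")
  per_cond <- list()
  subs <- unique(replicate_ratios$strain_label)
  calls <- lapply(subs, function(s) {
    v <- replicate_ratios[replicate_ratios$strain_label == s, ]
    conds <- unique(ckey(v))
    hi <- v$ratio[v$pyridoxine == high_dose]
    if (length(hi) == 0)
      stop("missing high-pyridoxine observation for ", s)
    res <- lapply(conds, function(cn) {
      vr <- v$ratio[ckey(v) == cn]
      mr <- major_ratios$ratio[ckey(major_ratios) == cn]
      if (all(is.na(vr)))
        return(list(p_value = NA_real_, flag = "none", direction = "none"))
      compareReplicates(vr, mr)
    })
    pc <- data.frame(substitution = s, condition = conds,
                     p_value = vapply(res, `[[`, numeric(1), "p_value"),
                     flag = vapply(res, `[[`, character(1), "flag"),
                     direction = vapply(res, `[[`, character(1), "direction"))
    per_cond[[s]] <<- pc
    grew <- any(!is.na(hi))
    .call_one(if (grew) mean(hi, na.rm = TRUE) else NA_real_,
              pc$flag, pc$direction)
  })
  out <- data.frame(substitution = subs,
                    category = vapply(calls, `[[`, character(1), "category"),
                    faster_than_wt = vapply(calls, function(x)
                      as.logical(x$faster_than_wt), logical(1)))
  attr(out, "per_condition") <- do.call(rbind, per_cond)
  out
}

#' Variants growing faster than the major allele
#'
#' The cofactor-sensitive variants whose every flagged condition points
#' faster than wild type.
#'
#' @param calls data.frame from \code{\link{classifyPanel}} or
#'   \code{\link{classifyFromReplicates}}.
#' @return character vector of substitution tokens (possibly empty).
#' @export
fasterSet <- function(calls) {
  sort(calls$substitution[calls$category == "sensitive" &
                            !is.na(calls$faster_than_wt) &
                            calls$faster_than_wt])
}

#' Variants sensitive to both cofactors
#'
#' From a hem1-delta titration panel, the variants that are extremely
#' sensitive to the heme precursor even at high pyridoxine: relative rate
#' at (pyridoxine = \code{high_dose}, delta-ALA = \code{low_dala}) absent
#' (no determinable growth) or below \code{rate_floor}.
#'
#' @param panel a hem1-delta \code{\link{VariantPanel}} (see
#'   \code{\link{loadTable2}}).
#' @param rate_floor ratio threshold operationalizing "extremely
#'   sensitive" (default 0.1).
#' @param high_dose,low_dala the evaluated condition (defaults 400 ng/mL
#'   pyridoxine, 5 ug/mL delta-ALA).
#' @return sorted character vector of substitution tokens.
#' @examples
#' dualSensitivity(loadTable2())
#' @export
dualSensitivity <- function(panel, rate_floor = 0.1, high_dose = 400,
                            low_dala = 5) {
  stopifnot(is(panel, "VariantPanel"))
  gr <- growthResults(panel)
  g <- gr[gr$hem1_deleted & gr$pyridoxine == high_dose & gr$dala == low_dala, ]
  subs <- variantRecords(panel)$substitution
  miss <- setdiff(subs, g$substitution)
  if (length(miss))
    stop("missing (", high_dose, " ng/mL B6, ", low_dala,
         " ug/mL dALA) condition for: ", paste(miss, collapse = ", "))
  g <- g[match(subs, g$substitution), ]
  hit <- is.na(g$rate) | g$rate < rate_floor
  sort(subs[hit])
}

#' Heme saturation from an absorbance ratio
#'
#' Fraction of full heme incorporation from the 430 nm (heme Soret) to
#' 280 nm (aromatic) absorbance ratio, using the one-to-one calibration
#' at which the major-allele protein is fully loaded. The ratio is
#' clipped to [0, 1].
#'
#' @param a430 absorbance at 430 nm (>= 0).
#' @param a280 absorbance at 280 nm (> 0).
#' @return fraction in [0, 1]; 1 means full incorporation.
#' @export
hemeSaturation <- function(a430, a280) {
  if (any(a280 <= 0)) stop("a280 must be > 0")
  if (any(a430 < 0)) stop("a430 must be >= 0")
  pmin(pmax(a430 / a280, 0), 1)
}
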