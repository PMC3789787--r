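#' Endpoint-normalize growth curves
#'
#' Rescales each well's kinetic OD595 reads so that the final timepoint
#' equals the well's endpoint read (taken after resuspension). This is a
#' pure per-well scaling: it cancels any multiplicative gain (plate-reader
#' or well geometry) without altering the shape of the curve.
#'
#' A well whose final kinetic read is not positive cannot be scaled
#' (nothing grew and the read noise consumed the signal); by default this
#' is an error, while \code{degenerate = "drop"} removes such wells so
#' that batch processing can report them as non-attained instead.
#'
#' @param gcs a \code{\link{GrowthCurveSet}}.
#' @param degenerate \code{"error"} (default) or \code{"drop"}.
#' @return a \code{GrowthCurveSet} with rescaled \code{od595}.
#' @export
normalizeCurves <- function(gcs, degenerate = c("error", "drop")) {
  degenerate <- match.arg(degenerate)
  stopifnot(is(gcs, "GrowthCurveSet"))
  cur <- gcs@curves
  ep <- gcs@endpoints
  key <- paste(cur$plate_id, cur$well_id)
  ekey <- paste(ep$plate_id, ep$well_id)
  idx <- match(key, ekey)
  if (anyNA(idx))
    stop("wells without endpoint read: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  endpoint <- ep$endpoint_od[idx]
  if (any(endpoint <= 0))
    stop("invalid curve: endpoint_od must be > 0")
  ord <- order(key, cur$time_h)
  last <- !duplicated(key[ord], fromLast = TRUE)
  final_od <- numeric(length(key))
  final_od[ord] <- rep(cur$od595[ord][last],
                       times = rle(key[ord])$lengths)
  if (any(final_od <= 0)) {
    if (degenerate == "error")
      stop("invalid curve: final OD reading is not positive, cannot scale (well ",
           paste(unique(key[final_od <= 0]), collapse = ", "), ")")
    keep <- final_od > 0
    cur <- cur[keep, , drop = FALSE]
    endpoint <- endpoint[keep]
    final_od <- final_od[keep]
  }
  cur$od595 <- cur$od595 * endpoint / final_od
  initialize(gcs, curves = cur)
}

#' Estimate a growth rate from one normalized curve
#'
#' Implements the fixed-density-window slope: OD595 values inside the
#' window (inclusive on both bounds) are log10-transformed and regressed
#' on time; the slope is the growth rate in log10 OD per hour. Readings
#' <= 0 are dropped before the log transform (with a warning). If fewer
#' than two readings fall inside the window, the window was not attained
#' and no rate is reported.
#'
#' @param time_h numeric vector of times (hours), strictly increasing.
#' @param od numeric vector of normalized OD595 readings.
#' @param window length-2 numeric, lower and upper OD bounds. The assay
#'   convention is \code{c(0.05, 0.1)} for HEM1 strains and
#'   \code{c(0.1, 0.2)} for hem1-delta strains.
#' @param method \code{"ols"} (least-squares slope over all in-window
#'   points, the default) or \code{"two_point"} (slope between the first
#'   and last in-window point), retained for sensitivity analysis.
#' @return list with elements \code{rate} (NA when not attained),
#'   \code{window}, \code{n_points_used}, \code{attained_window}.
#' @examples
#' t <- seq(0, 48, 0.5)
#' estimateRate(t, 0.01 * 10^(0.05 * t), c(0.05, 0.1))
#' @export
estimateRate <- function(time_h, od, window = c(0.05, 0.1),
                         method = c("ols", "two_point")) {
  method <- match.arg(method)
  stopifnot(length(time_h) == length(od), length(window) == 2,
            window[1] < window[2])
  if (any(od <= 0)) {
    warning("dropping ", sum(od <= 0), " non-positive OD reading(s) before log transform")
    keep <- od > 0
    time_h <- time_h[keep]; od <- od[keep]
  }
  inw <- od >= window[1] & od <= window[2]
  n <- sum(inw)
  if (n < 2)
    return(list(rate = NA_real_, window = window, n_points_used = n,
                attained_window = FALSE))
  t <- time_h[inw]
  y <- log10(od[inw])
  rate <- if (method == "two_point") {
    (y[n] - y[1]) / (t[n] - t[1])
  } else {
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  }
  list(rate = rate, window = window, n_points_used = n,
       attained_window = TRUE)
}

#' Estimate rates for every well of a curve set
#'
#' Runs \code{\link{normalizeCurves}} then \code{\link{estimateRate}} on
#' each well, choosing the density window by the well's background
#' (\code{hem1_deleted}).
#'
#' @param gcs a \code{\link{GrowthCurveSet}}.
#' @param window_hem1,window_hem1d density windows for HEM1 and
#'   hem1-delta wells.
#' @param method slope method, see \code{\link{estimateRate}}.
#' @return data.frame with one row per well: \code{plate_id},
#'   \code{well_id}, \code{strain_label}, \code{pyridoxine}, \code{dala},
#'   \code{hem1_deleted}, \code{rate}, \code{n_points_used},
#'   \code{attained_window}.
#' @export
estimateRates <- function(gcs, window_hem1 = c(0.05, 0.1),
                          window_hem1d = c(0.1, 0.2),
                          method = c("ols", "two_point")) {
  method <- match.arg(method)
  key0 <- paste(gcs@curves$plate_id, gcs@curves$well_id, sep = "\r")
  wells <- gcs@curves[!duplicated(key0),
                      c("plate_id", "well_id", "strain_label", "pyridoxine",
                        "dala", "hem1_deleted")]
  wkey <- key0[!duplicated(key0)]
  gcs <- normalizeCurves(gcs, degenerate = "drop")
  cur <- gcs@curves
  key <- paste(cur$plate_id, cur$well_id, sep = "\r")
  res <- lapply(split(seq_len(nrow(cur)), key), function(i) {
    w <- if (cur$hem1_deleted[i[1]]) window_hem1d else window_hem1
    suppressWarnings(estimateRate(cur$time_h[i], cur$od595[i], w, method))
  })
  wells$rate <- NA_real_
  wells$n_points_used <- 0L
  wells$attained_window <- FALSE
  hit <- match(names(res), wkey)
  wells$rate[hit] <- vapply(res, `[[`, numeric(1), "rate")
  wells$n_points_used[hit] <- vapply(res, function(r)
    as.integer(r$n_points_used), integer(1))
  wells$attained_window[hit] <- vapply(res, `[[`, logical(1),
                                       "attained_window")
  rownames(wells) <- NULL
  wells
}

#' Apply plate normalization to per-well rate estimates
#'
#' Corrects plate-to-plate variation by anchoring every plate to the
#' reference (major-allele) strain: each plate's factor is the grand mean
#' of reference rates across plates divided by the mean reference rate on
#' that plate, and all rates on the plate are multiplied by its factor.
#' After normalization the reference plate means are equal, which
#' preserves the convention that the major allele has relative rate 1.
#'
#' @param rates data.frame as returned by \code{\link{estimateRates}}.
#' @param reference strain label of the major-allele wells.
#' @return list with \code{rates} (the input with normalized \code{rate})
#'   and \code{factors} (data.frame \code{plate_id}, \code{factor}).
#' @export
plateNormalize <- function(rates, reference = "major") {
  ref <- rates[rates$strain_label == reference & rates$attained_window, ]
  plates <- unique(rates$plate_id)
  missing <- setdiff(plates, unique(ref$plate_id))
  if (length(missing))
    stop("no attained reference ('", reference, "') rate on plate(s): ",
         paste(missing, collapse = ", "))
  plate_mean <- tapply(ref$rate, ref$plate_id, mean)
  grand <- mean(ref$rate)
  factors <- data.frame(plate_id = names(plate_mean),
                        factor = as.numeric(grand / plate_mean))
  if (any(factors$factor <= 0))
    stop("non-positive plate normalization factor")
  rates$rate <- rates$rate * factors$factor[match(rates$plate_id,
                                                  factors$plate_id)]
  list(rates = rates, factors = factors)
}

#' Relative growth rate
#'
#' Ratio of a variant rate to the major-allele rate measured in the same
#' medium.
#'
#' @param variant_rate,major_rate growth rates (log10 OD per hour).
#' @return dimensionless ratio, vectorized over \code{variant_rate}.
#' @export
relativeRate <- function(variant_rate, major_rate) {
  if (any(!is.finite(major_rate)) || any(major_rate <= 0))
    stop("reference strain failed to grow (major_rate must be > 0)")
  variant_rate / major_rate
}

#' Summarize per-strain relative rates
#'
#' Full post-estimation pipeline: plate-normalize, average the reference
#' rate per condition, express every well as a ratio to that reference
#' mean, and summarize replicates per strain and condition.
#'
#' @param rates data.frame from \code{\link{estimateRates}}.
#' @param reference major-allele strain label.
#' @return list with \code{replicates} (one row per non-reference well:
#'   strain, condition, \code{ratio}) and \code{summary} (per strain x
#'   condition: \code{mean_ratio}, \code{sd_ratio}, \code{n}).
#' @export
relativeRates <- function(rates, reference = "major") {
  norm <- plateNormalize(rates, reference)
  r <- norm$rates
  cond <- paste(r$pyridoxine, r$dala, r$hem1_deleted, sep = "\r")
  ref <- r[r$strain_label == reference & r$attained_window, ]
  ref_mean <- tapply(ref$rate, cond[r$strain_label == reference &
                                      r$attained_window], mean)
  var <- r[r$strain_label != reference, ]
  vcond <- cond[r$strain_label != reference]
  miss <- setdiff(unique(vcond), names(ref_mean))
  if (length(miss))
    stop("no reference rate for condition(s): ", length(miss))
  var$ratio <- relativeRate(ifelse(var$attained_window, var$rate, NA_real_),
                            ref_mean[vcond])
  gkey <- paste(var$strain_label, vcond, sep = "\r")
  agg <- do.call(rbind, lapply(split(seq_len(nrow(var)), gkey), function(i) {
    x <- var$ratio[i]
    data.frame(strain_label = var$strain_label[i[1]],
               pyridoxine = var$pyridoxine[i[1]],
               dala = var$dala[i[1]],
               hem1_deleted = var$hem1_deleted[i[1]],
               mean_ratio = if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
               sd_ratio = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else NA_real_,
               n = sum(!is.na(x)))
  }))
  rownames(agg) <- NULL
  list(replicates = var, summary = agg, factors = norm$factors)
}
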