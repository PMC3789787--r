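#' Parse a substitution token
#'
#' Parses tokens of the form \code{"I278T"} (one-letter) or
#' \code{"Ile278Thr"} (three-letter) into wild-type residue, 1-based
#' position on the reference protein, and mutant residue.
#'
#' @param token character vector of substitution tokens.
#' @return data.frame with columns \code{wt_aa}, \code{position},
#'   \code{mut_aa}, one row per token.
#' @examples
#' parseSubstitution("I278T")
#' @export
parseSubstitution <- function(token) {
  stopifnot(is.character(token), length(token) >= 1)
  one <- regmatches(token, regexec("^([A-Z])([0-9]+)([A-Z])$", token))
  three <- regmatches(token,
    regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", token))
  wt <- mut <- character(length(token))
  pos <- integer(length(token))
  for (i in seq_along(token)) {
    if (length(one[[i]]) == 4) {
      wt[i] <- one[[i]][2]; pos[i] <- as.integer(one[[i]][3]); mut[i] <- one[[i]][4]
    } else if (length(three[[i]]) == 4) {
      m3 <- toupper(c(three[[i]][2], three[[i]][4]))
      idx <- match(m3, .AA3)
      if (any(is.na(idx)))
        stop("non-canonical amino-acid code in token '", token[i], "'")
      wt[i] <- names(.AA3)[idx[1]]; mut[i] <- names(.AA3)[idx[2]]
      pos[i] <- as.integer(three[[i]][3])
    } else {
      stop("malformed substitution token '", token[i], "'")
    }
    if (!(wt[i] %in% .AA1) || !(mut[i] %in% .AA1))
      stop("non-canonical amino-acid letter in token '", token[i], "'")
    if (wt[i] == mut[i])
      stop("silent substitution (wild-type equals mutant) in token '",
           token[i], "'")
    if (pos[i] < 1)
      stop("position must be >= 1 in token '", token[i], "'")
  }
  data.frame(wt_aa = wt, position = pos, mut_aa = mut)
}

#' Format a substitution back to its one-letter token
#'
#' Inverse of \code{\link{parseSubstitution}}.
#'
#' @param wt_aa,position,mut_aa components as returned by
#'   \code{parseSubstitution} (or a data.frame with those columns as the
#'   first argument).
#' @return character vector of tokens.
#' @export
formatSubstitution <- function(wt_aa, position, mut_aa) {
  if (is.data.frame(wt_aa)) {
    df <- wt_aa
    return(paste0(df$wt_aa, df$position, df$mut_aa))
  }
  paste0(wt_aa, position, mut_aa)
}

.panel_from_tables <- function(records, growth,
                               referenceProtein = "NP_000062",
                               referenceMrna = "NM_000071",
                               validate = TRUE) {
  panel <- new("VariantPanel", records = records, growth = growth,
               referenceProtein = referenceProtein,
               referenceMrna = referenceMrna)
  if (validate) {
    v <- validatePanel(panel)
    if (length(v))
      stop("panel failed validation:\n  ", paste(v, collapse = "\n  "))
  }
  panel
}

.parse_rate_cell <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("", "n/d", "n/a", "NA")] <- NA_real_
  out
}

.flag_from_mark <- function(x) {
  x <- trimws(x)
  out <- rep("none", length(x))
  out[x == "*"] <- "p01"
  out[x == "**"] <- "p001"
  out
}

.mark_from_flag <- function(x) c(none = "", p01 = "*", p001 = "**")[x]

#' Load the HEM1-background variant table
#'
#' Reads the bundled transcription of the 58-variant panel (or a file in
#' the same TSV dialect): one row per variant with plasmid id, nucleotide
#' change, substitution, Rosetta ddG (empty = not predicted), phenotype
#' category, and rate/sd/significance triplets at 400, 4, 2 and 1 ng/mL
#' pyridoxine. A printed rate of 0 for a nonfunctional variant is stored
#' as an absent rate (no determinable growth); category retains the
#' distinction.
#'
#' @param path path to a panel TSV; default is the bundled fixture.
#' @return a validated \code{\link{VariantPanel}}.
#' @examples
#' panel <- loadTable1()
#' nVariants(panel)
#' @export
loadTable1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cbs_table1.tsv", package = "cbscofactor",
                        mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  raw$nt_change <- gsub("→", ">", raw$nt_change)
  raw$plasmid_id[raw$plasmid_id %in% c("", "NA")] <- NA_character_
  raw$nt_change[raw$nt_change %in% c("", "NA")] <- NA_character_
  sub <- parseSubstitution(raw$substitution)
  records <- data.frame(
    plasmid_id = raw$plasmid_id,
    nt_change = raw$nt_change,
    substitution = raw$substitution,
    wt_aa = sub$wt_aa,
    position = sub$position,
    mut_aa = sub$mut_aa,
    ddg = .parse_rate_cell(raw$ddg),
    category = raw$category,
    construction = if ("construction" %in% names(raw)) raw$construction
                   else "unknown"
  )
  doses <- sort(as.numeric(sub("^rate_", "",
                               grep("^rate_", names(raw), value = TRUE))),
                decreasing = TRUE)
  growth <- do.call(rbind, lapply(doses, function(d) {
    data.frame(
      substitution = raw$substitution,
      pyridoxine = d,
      dala = NA_real_,
      hem1_deleted = FALSE,
      rate = .parse_rate_cell(raw[[paste0("rate_", d)]]),
      sd = .parse_rate_cell(raw[[paste0("sd_", d)]]),
      flag = .flag_from_mark(raw[[paste0("flag_", d)]]),
      n_replicates = 3L
    )
  }))
  ## printed 0 at high B6 for nonfunctional variants means no growth
  nonf <- records$substitution[records$category == "nonfunctional"]
  zero <- growth$substitution %in% nonf & !is.na(growth$rate) & growth$rate == 0
  growth$rate[zero] <- NA_real_
  growth <- growth[order(match(growth$substitution, records$substitution),
                         -growth$pyridoxine), ]
  rownames(growth) <- NULL
  .panel_from_tables(records, growth)
}

#' Load the hem1-delta cofactor-titration table
#'
#' Reads the bundled transcription of the heme-precursor titration of the
#' nine B6-remediable variants (or a file in the same long-format TSV
#' dialect): one row per variant x condition, conditions crossing 400/2
#' ng/mL pyridoxine with 50/5 ug/mL delta-ALA, rates relative to the major
#' allele grown in the same medium. \code{"n/d"} cells become absent
#' rates.
#'
#' @param path path to a long-format TSV; default is the bundled fixture.
#' @return a \code{\link{VariantPanel}} whose growth rows all have
#'   \code{hem1_deleted = TRUE}.
#' @export
loadTable2 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cbs_table2.tsv", package = "cbscofactor",
                        mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  subs <- unique(raw$substitution)
  sub <- parseSubstitution(subs)
  records <- data.frame(
    plasmid_id = NA_character_,
    nt_change = NA_character_,
    substitution = subs,
    wt_aa = sub$wt_aa,
    position = sub$position,
    mut_aa = sub$mut_aa,
    ddg = NA_real_,
    category = "sensitive",
    construction = "unknown"
  )
  growth <- data.frame(
    substitution = raw$substitution,
    pyridoxine = as.numeric(raw$pyridoxine_ng_ml),
    dala = as.numeric(raw$dala_ug_ml),
    hem1_deleted = TRUE,
    rate = .parse_rate_cell(raw$rate),
    sd = .parse_rate_cell(raw$sd),
    flag = "none",
    n_replicates = 3L
  )
  .panel_from_tables(records, growth)
}

#' Check the domain invariants of a panel
#'
#' Returns violations as character descriptions (empty when the panel is
#' clean) rather than raising conditions, so that malformed panels remain
#' inspectable. Checked rules: unique plasmid ids and substitutions;
#' canonical residues with wild-type distinct from mutant; positions >= 1;
#' nucleotide-change position consistent with the substitution position
#' (within the codon, +/- 2 nt); rates and sds non-negative; significance
#' flags only on present rates; nonfunctional records carrying no rates;
#' delta-ALA present exactly for hem1-deleted conditions.
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validatePanel <- function(panel) {
  stopifnot(is(panel, "VariantPanel"))
  rec <- panel@records
  gr <- panel@growth
  v <- character()
  if (nrow(rec) == 0) return(v)
  pid <- rec$plasmid_id[!is.na(rec$plasmid_id)]
  if (anyDuplicated(pid))
    v <- c(v, paste0("duplicate plasmid_id: ",
                     paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  if (anyDuplicated(rec$substitution))
    v <- c(v, paste0("duplicate substitution: ",
                     paste(unique(rec$substitution[duplicated(rec$substitution)]),
                           collapse = ", ")))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (!(r$wt_aa %in% .AA1) || !(r$mut_aa %in% .AA1))
      v <- c(v, paste0(r$substitution, ": non-canonical amino acid"))
    else if (r$wt_aa == r$mut_aa)
      v <- c(v, paste0(r$substitution, ": wild-type equals mutant"))
    if (is.na(r$position) || r$position < 1)
      v <- c(v, paste0(r$substitution, ": position must be >= 1"))
    if (!(r$category %in% .CATEGORIES))
      v <- c(v, paste0(r$substitution, ": unknown category '", r$category, "'"))
    if (!(r$construction %in% c("directed", "random", "unknown")))
      v <- c(v, paste0(r$substitution, ": unknown construction '",
                       r$construction, "'"))
    if (!is.na(r$nt_change)) {
      nt <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", r$nt_change)))
      if (!is.na(nt) && abs(nt - (3 * r$position - 1)) > 2)
        v <- c(v, paste0(r$substitution, ": nt_change position ", nt,
                         " inconsistent with codon of residue ", r$position))
    }
  }
  if (nrow(gr) > 0) {
    orphan <- setdiff(gr$substitution, rec$substitution)
    if (length(orphan))
      v <- c(v, paste0("growth rows for unknown substitution: ",
                       paste(orphan, collapse = ", ")))
    if (any(gr$rate < 0, na.rm = TRUE))
      v <- c(v, "negative relative_rate")
    if (any(gr$sd < 0, na.rm = TRUE))
      v <- c(v, "negative sd")
    if (!all(gr$flag %in% .FLAGS))
      v <- c(v, "significance flag outside {none, p01, p001}")
    bad_flag <- gr$flag != "none" & is.na(gr$rate)
    if (any(bad_flag))
      v <- c(v, paste0("significance flag on absent rate: ",
                       paste(unique(gr$substitution[bad_flag]), collapse = ", ")))
    bad_dala <- xor(gr$hem1_deleted, !is.na(gr$dala))
    if (any(bad_dala))
      v <- c(v, paste0("dala present iff hem1_deleted violated: ",
                       paste(unique(gr$substitution[bad_dala]), collapse = ", ")))
    nonf <- rec$substitution[rec$category == "nonfunctional"]
    bad_nf <- gr$substitution %in% nonf & !is.na(gr$rate)
    if (any(bad_nf))
      v <- c(v, paste0("nonfunctional record carries a growth rate: ",
                       paste(unique(gr$substitution[bad_nf]), collapse = ", ")))
  }
  v
}

#' Write / read a variant panel in the fixture TSV dialect
#'
#' \code{writeVariantPanel} serializes the wide one-row-per-variant layout
#' with rate/sd/flag triplets per condition; \code{readVariantPanel} reads
#' it back. A round trip restores every field. Only HEM1-background
#' panels (one pyridoxine titration, no delta-ALA) use the wide dialect;
#' hem1-delta panels round-trip through the long dialect of
#' \code{\link{loadTable2}}.
#'
#' @param panel a \code{\link{VariantPanel}}.
#' @param path output / input TSV path.
#' @return \code{readVariantPanel} returns a \code{VariantPanel};
#'   \code{writeVariantPanel} returns \code{path} invisibly.
#' @export
writeVariantPanel <- function(panel, path) {
  stopifnot(is(panel, "VariantPanel"), !any(panel@growth$hem1_deleted))
  rec <- panel@records
  doses <- sort(unique(panel@growth$pyridoxine), decreasing = TRUE)
  out <- data.frame(plasmid_id = rec$plasmid_id, nt_change = rec$nt_change,
                    substitution = rec$substitution,
                    ddg = ifelse(is.na(rec$ddg), "", format(rec$ddg)),
                    category = rec$category,
                    construction = rec$construction,
                    check.names = FALSE)
  for (d in doses) {
    g <- panel@growth[panel@growth$pyridoxine == d, ]
    g <- g[match(rec$substitution, g$substitution), ]
    nonf <- rec$category == "nonfunctional" & d == max(doses)
    rate <- ifelse(is.na(g$rate), ifelse(nonf, "0", "n/d"), format(g$rate))
    out[[paste0("rate_", d)]] <- rate
    out[[paste0("sd_", d)]] <- ifelse(is.na(g$sd), "", format(g$sd))
    out[[paste0("flag_", d)]] <- .mark_from_flag(g$flag)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname writeVariantPanel
#' @export
readVariantPanel <- function(path) {
  loadTable1(path)
}
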