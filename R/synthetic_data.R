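#' Configuration for synthetic growth curves
#'
#' Defaults emulate the plate-reader assay: reads every 30 min for 84 h,
#' inoculation at OD595 = 0.01, logistic growth with a lag, additive
#' Gaussian read noise, and an optional multiplicative plate gain on the
#' kinetic reads (the resuspended endpoint read measures the true final
#' density and so carries no gain).
#'
#' @param start_od inoculation density (OD595).
#' @param carrying_capacity plateau density (OD595); \code{Inf} gives a
#'   pure exponential.
#' @param max_rate exponential-phase growth rate, log10 OD per hour.
#' @param lag lag before growth starts (h).
#' @param read_interval time between reads (h).
#' @param duration total kinetic run (h); must be >= 10 read intervals.
#' @param noise_sd additive read noise (OD595).
#' @param plate_gain multiplicative gain applied to kinetic reads.
#' @return a validated config list of class \code{CurveSimConfig}.
#' @export
curveSimConfig <- function(start_od = 0.01, carrying_capacity = 1.0,
                           max_rate = 0.05, lag = 5, read_interval = 0.5,
                           duration = 84, noise_sd = 0.005,
                           plate_gain = 1) {
  stopifnot(start_od > 0, carrying_capacity > 0, max_rate >= 0, lag >= 0,
            read_interval > 0, duration >= 10 * read_interval,
            noise_sd >= 0, plate_gain > 0)
  structure(list(start_od = start_od,
                 carrying_capacity = carrying_capacity,
                 max_rate = max_rate, lag = lag,
                 read_interval = read_interval, duration = duration,
                 noise_sd = noise_sd, plate_gain = plate_gain),
            class = "CurveSimConfig")
}

.logistic_od <- function(t, cfg, true_rate) {
  te <- pmax(0, t - cfg$lag)
  g <- 10^(true_rate * te)
  if (is.infinite(cfg$carrying_capacity)) return(cfg$start_od * g)
  K <- cfg$carrying_capacity
  K * cfg$start_od * g / (K + cfg$start_od * (g - 1))
}

#' Simulate one growth curve
#'
#' Lagged logistic trajectory sampled at the configured interval,
#' multiplied by the plate gain, plus independent additive noise floored
#' at zero. The endpoint read is the noise-free, gain-free final density.
#' Deterministic given \code{seed}.
#'
#' @param cfg a \code{\link{curveSimConfig}}.
#' @param true_rate exponential-phase rate (log10 OD per hour); 0 gives a
#'   flat no-growth curve.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return list with \code{time_h}, \code{od595}, \code{endpoint_od} and
#'   \code{true_rate}.
#' @export
simulateCurve <- function(cfg = curveSimConfig(), true_rate = cfg$max_rate,
                          seed = NULL) {
  stopifnot(inherits(cfg, "CurveSimConfig"), true_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, cfg$duration, by = cfg$read_interval)
  signal <- .logistic_od(t, cfg, true_rate)
  od <- signal * cfg$plate_gain
  if (cfg$noise_sd > 0)
    od <- pmax(0, od + stats::rnorm(length(od), sd = cfg$noise_sd))
  list(time_h = t, od595 = od, endpoint_od = signal[length(signal)],
       true_rate = true_rate)
}

#' Configuration for synthetic variant panels
#'
#' The defaults mirror the structure of the assayed panel: 58 alleles in
#' category proportions 19/14/25
#' (nonfunctional/sensitive/benign), three replicate transformants per
#' allele, pyridoxine doses 400/4/2/1 ng/mL, replicates laid out one
#' plate per replicate index.
#'
#' @param n_alleles number of variant alleles.
#' @param category_proportions length-3 proportions
#'   (nonfunctional, sensitive, benign) summing to 1.
#' @param n_replicates replicate transformants per allele (>= 2).
#' @param doses pyridoxine doses (ng/mL), decreasing.
#' @param sensitive_base range of the sensitive-category true ratio at
#'   the highest dose.
#' @param sensitive_decline range of the per-dose-step multiplicative
#'   decline for sensitive alleles.
#' @param benign_sd biological scatter of benign true ratios around 1.
#' @param plate_effects named multiplier per plate applied to all true
#'   rates on that plate (NULL = none).
#' @param feature_shift additive shift planted on the sensitive group's
#'   numeric structural features (0 = null).
#' @param curve a \code{\link{curveSimConfig}} for the underlying wells.
#' @return config list of class \code{PanelSimConfig}.
#' @export
panelSimConfig <- function(n_alleles = 58,
                           category_proportions = c(19, 14, 25) / 58,
                           n_replicates = 3, doses = c(400, 4, 2, 1),
                           sensitive_base = c(0.5, 0.95),
                           sensitive_decline = c(0.6, 0.9),
                           benign_sd = 0.05,
                           plate_effects = NULL,
                           feature_shift = 0,
                           curve = curveSimConfig()) {
  stopifnot(n_alleles >= 1, length(category_proportions) == 3,
            all(category_proportions >= 0),
            abs(sum(category_proportions) - 1) < 1e-8,
            n_replicates >= 2, length(doses) >= 1)
  structure(list(n_alleles = n_alleles,
                 category_proportions = category_proportions,
                 n_replicates = n_replicates, doses = doses,
                 sensitive_base = sensitive_base,
                 sensitive_decline = sensitive_decline,
                 benign_sd = benign_sd, plate_effects = plate_effects,
                 feature_shift = feature_shift, curve = curve),
            class = "PanelSimConfig")
}

.simulate_features <- function(alleles, category, shift, shift_category) {
  n <- length(alleles)
  feat <- data.frame(
    allele = alleles,
    dist_heme = stats::rnorm(n, 20, 5),
    dist_plp = stats::rnorm(n, 20, 5),
    rsa = pmin(1, pmax(0, stats::rnorm(n, 0.3, 0.15))),
    in_regular_ss = stats::runif(n) < 0.5,
    mean_bfactor = stats::rnorm(n, 30, 8)
  )
  if (shift != 0) {
    hit <- category == shift_category
    for (f in c("dist_heme", "dist_plp", "mean_bfactor"))
      feat[[f]][hit] <- feat[[f]][hit] + shift
    feat$rsa[hit] <- pmin(1, pmax(0, feat$rsa[hit] + shift / 100))
  }
  feat
}

#' Simulate a full variant panel with raw replicate curves
#'
#' Draws allele categories, per-allele true relative rates at each dose
#' (nonfunctional: flat curves; sensitive: true ratios declining
#' monotonically with decreasing dose; benign: ratios scattered about 1),
#' lays replicates out one plate per replicate index with major-allele
#' reference wells on every plate and dose, simulates each well's curve,
#' and returns the complete true-parameter ledger so every downstream
#' estimate can be scored.
#'
#' @param cfg a \code{\link{panelSimConfig}}.
#' @param seed integer seed; the generator is bit-reproducible given
#'   (cfg, seed).
#' @param major_rate the major-allele exponential-phase rate (log10/h).
#' @return list with \code{curves} (a \code{\link{GrowthCurveSet}}),
#'   \code{truth} (data.frame allele x dose: \code{true_ratio}),
#'   \code{records} (allele, category, construction), and
#'   \code{features} (per-allele synthetic structural features; the
#'   planted shift, if any, is applied to the sensitive group).
#' @export
simulatePanel <- function(cfg = panelSimConfig(), seed = 1,
                          major_rate = cfg$curve$max_rate) {
  stopifnot(inherits(cfg, "PanelSimConfig"))
  set.seed(seed)
  n <- cfg$n_alleles
  sizes <- c(
    nonfunctional = floor(n * cfg$category_proportions[1] + 1e-9),
    sensitive = floor(n * cfg$category_proportions[2] + 1e-9)
  )
  sizes <- c(sizes, benign = n - sum(sizes))
  category <- rep(names(sizes), sizes)
  alleles <- sprintf("VAR%03d", seq_len(n))
  construction <- sample(c("directed", "random"), n, replace = TRUE)

  ndose <- length(cfg$doses)
  ratio <- matrix(NA_real_, n, ndose,
                  dimnames = list(alleles, as.character(cfg$doses)))
  for (i in seq_len(n)) {
    ratio[i, ] <- switch(category[i],
      nonfunctional = rep(0, ndose),
      benign = pmax(0.2, stats::rnorm(ndose, 1, cfg$benign_sd)),
      sensitive = {
        base <- stats::runif(1, cfg$sensitive_base[1], cfg$sensitive_base[2])
        dec <- stats::runif(1, cfg$sensitive_decline[1],
                            cfg$sensitive_decline[2])
        base * dec^(seq_len(ndose) - 1)
      })
  }

  plates <- sprintf("P%02d", seq_len(cfg$n_replicates))
  gain <- function(p) {
    if (is.null(cfg$plate_effects)) 1 else {
      g <- cfg$plate_effects[p]
      ifelse(is.na(g), 1, g)
    }
  }
  rows <- list(); eps <- list(); wi <- 0L
  add_well <- function(plate, strain, dose, rate) {
    wi <<- wi + 1L
    sim <- simulateCurve(cfg$curve, true_rate = rate)
    well <- sprintf("W%04d", wi)
    rows[[wi]] <<- data.frame(plate_id = plate, well_id = well,
                              strain_label = strain, pyridoxine = dose,
                              dala = NA_real_, hem1_deleted = FALSE,
                              time_h = sim$time_h, od595 = sim$od595)
    eps[[wi]] <<- data.frame(plate_id = plate, well_id = well,
                             endpoint_od = max(sim$endpoint_od,
                                               cfg$curve$start_od))
  }
  for (p in plates) {
    for (d in cfg$doses) add_well(p, "major", d, major_rate * gain(p))
    for (i in seq_len(n))
      for (j in seq_len(ndose))
        add_well(p, alleles[i], cfg$doses[j],
                 major_rate * ratio[i, j] * gain(p))
  }
  curves <- new("GrowthCurveSet", curves = do.call(rbind, rows),
                endpoints = do.call(rbind, eps))
  truth <- data.frame(allele = rep(alleles, each = ndose),
                      category = rep(category, each = ndose),
                      pyridoxine = rep(cfg$doses, n),
                      true_ratio = as.vector(t(ratio)))
  features <- .simulate_features(alleles, category, cfg$feature_shift,
                                 "sensitive")
  list(curves = curves, truth = truth,
       records = data.frame(allele = alleles, category = category,
                            construction = construction),
       features = features)
}

## NeRF atom placement: position D such that |C-D| = l, angle(B,C,D) =
## theta and dihedral(A,B,C,D) = chi (degrees).
.place_atom <- function(a, b, c, l, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-l * cos(th), l * sin(th) * cos(ch), l * sin(th) * sin(ch))
  c + cbind(bc, m, n) %*% d2
}

.pdb_atom_line <- function(record, serial, name, resn, chain, resno,
                           xyz, occ, b, element) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resn, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Write a synthetic helical structure as a PDB file
#'
#' Ideal poly-alanine alpha-helix (backbone built from standard internal
#' coordinates with phi = -57, psi = -47, omega = 180) with one dummy
#' side-chain atom (CB) per residue, an optional HELIX record spanning
#' the chain, and single-atom HETATM ligand groups named HEM (iron) and
#' PLP (phosphorus) at caller-specified coordinates. The file re-reads
#' with \code{\link{readStructure}} into an equivalent model. Intended
#' for tests and demonstrations; labelled synthetic, it stands in for no
#' particular deposited structure.
#'
#' @param n_residues chain length (>= 4).
#' @param ligand_xyz named list with numeric length-3 elements
#'   \code{heme} and/or \code{plp}; default places both 8-10 Angstrom
#'   off the helix near its middle. A ligand closer than 1 Angstrom to
#'   any protein atom is an error.
#' @param bfactor_profile per-residue B-factor (scalar recycled).
#' @param helix_record write the HELIX annotation (set \code{FALSE} to
#'   exercise the dihedral fallback of
#'   \code{\link{secondaryStructure}}).
#' @param path output file path.
#' @return \code{path}, invisibly; attribute \code{"coords"} holds the
#'   atom table that was written.
#' @export
simulateStructure <- function(n_residues, ligand_xyz = NULL,
                              bfactor_profile = 20, helix_record = TRUE,
                              path = tempfile(fileext = ".pdb")) {
  stopifnot(n_residues >= 4)
  b_res <- rep_len(bfactor_profile, n_residues)
  ## seed residue
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[[1]] <- CA[[1]] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:n_residues) {
    N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                          1.329, 116.2, -47)     # psi
    CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                           1.458, 121.7, 180)    # omega
    C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]],
                          1.525, 111.2, -57)     # phi
  }
  lines <- character()
  if (helix_record)
    lines <- sprintf(
      "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s%5d",
      1L, "H1", "ALA", "A", 1L, "ALA", "A", n_residues, 1L, "",
      n_residues)
  serial <- 0L
  coords <- list()
  emit <- function(record, name, resn, chain, resno, xyz, b, element) {
    serial <<- serial + 1L
    coords[[serial]] <<- data.frame(name = name, resn = resn, resno = resno,
                                    x = xyz[1], y = xyz[2], z = xyz[3],
                                    b = b, element = element)
    lines <<- c(lines, .pdb_atom_line(record, serial, name, resn, chain,
                                      resno, xyz, 1.00, b, element))
  }
  for (i in seq_len(n_residues)) {
    cb <- .place_atom(C[[i]], N[[i]], CA[[i]], 1.53, 110.5, 122.5)
    emit("ATOM", "N", "ALA", "A", i, N[[i]], b_res[i], "N")
    emit("ATOM", "CA", "ALA", "A", i, CA[[i]], b_res[i], "C")
    emit("ATOM", "C", "ALA", "A", i, C[[i]], b_res[i], "C")
    emit("ATOM", "CB", "ALA", "A", i, cb, b_res[i], "C")
  }
  prot_xyz <- do.call(rbind, lapply(coords, function(d)
    c(d$x, d$y, d$z)))
  mid <- CA[[max(1, n_residues %/% 2)]]
  if (is.null(ligand_xyz))
    ligand_xyz <- list(heme = mid + c(9, 0, 0), plp = mid + c(0, 10, 0))
  lig_resno <- n_residues
  for (lig in names(ligand_xyz)) {
    xyz <- ligand_xyz[[lig]]
    stopifnot(length(xyz) == 3)
    dmin <- sqrt(min(rowSums(sweep(prot_xyz, 2, xyz)^2)))
    if (dmin < 1)
      stop("ligand '", lig, "' overlaps the backbone (", round(dmin, 2),
           " A); place it further away")
    lig_resno <- lig_resno + 1L
    info <- switch(lig, heme = c("HEM", "FE", "FE"),
                   plp = c("PLP", "P", "P"),
                   stop("unknown ligand '", lig, "'"))
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line("HETATM", serial, info[2], info[1],
                                     "A", lig_resno, xyz, 1.00, 20, info[3]))
  }
  writeLines(c(lines, "END"), path)
  out <- invisible(path)
  attr(out, "coords") <- do.call(rbind, coords)
  out
}
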