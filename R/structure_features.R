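## van der Waals radii by element symbol (Angstrom). Bondi-style set with
## the common extensions used by SASA implementations; metals as in
## typical heme-containing structures.
.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
          SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
          FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CU = 1.40,
          `NA` = 2.27, K = 2.75, CA = 2.31)

## Theoretical tripeptide maximum accessible surface areas per residue
## type (Tien et al. 2013), Angstrom^2; denominators for relative solvent
## accessibility.
.MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLU = 223.0, GLN = 225.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

.element_of <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  guess <- toupper(substr(trimws(elety), 1, 1))
  ifelse(is.na(el) | el == "", guess, el)
}

#' Read a structure file into a StructureModel
#'
#' Parses a PDB file (via \pkg{bio3d}), drops hydrogens, resolves
#' alternate locations to the highest-occupancy conformer, rejects
#' insertion codes, and records HELIX/SHEET annotation spans plus the
#' residue-name sets identifying the heme and PLP ligand groups.
#'
#' @param path path to a PDB file.
#' @param offset integer; NP_000062 position minus file residue number
#'   (0 when the file already uses reference numbering).
#' @param heme,plp character vectors of HETATM residue names treated as
#'   the heme and PLP ligand groups.
#' @return a \code{\link{StructureModel}}.
#' @export
readStructure <- function(path, offset = 0L, heme = "HEM",
                          plp = c("PLP", "LLP")) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported")
  at$elesy <- .element_of(at$elety, at$elesy)
  at <- at[at$elesy != "H", , drop = FALSE]
  ## resolve altloc: keep highest occupancy per (chain, resno, elety)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    o <- at$o
    o[is.na(o)] <- 1
    ord <- order(key, -o)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(at$eleno), ]
  }
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    b = at$b, o = ifelse(is.na(at$o), 1, at$o),
    elesy = at$elesy, het = at$type == "HETATM"
  )
  span_df <- function(h) {
    if (is.null(h) || length(h$start) == 0)
      return(data.frame(chain = character(), start = integer(),
                        end = integer()))
    data.frame(chain = ifelse(is.na(h$chain) | h$chain == "", "A",
                              as.character(h$chain)),
               start = as.integer(h$start), end = as.integer(h$end))
  }
  new("StructureModel", atoms = atoms, helix = span_df(pdb$helix),
      sheet = span_df(pdb$sheet), ligands = list(heme = heme, plp = plp),
      offset = as.integer(offset))
}

## protein heavy atoms of an NP-numbered residue; errors if absent
.residue_atoms <- function(model, position, chain = NULL) {
  at <- model@atoms
  sel <- !at$het & at$resno == (position - model@offset)
  if (!is.null(chain)) sel <- sel & at$chain == chain
  if (!any(sel))
    stop("residue at NP position ", position, " not present in the model")
  at[sel, , drop = FALSE]
}

.has_residue <- function(model, position) {
  at <- model@atoms
  any(!at$het & at$resno == (position - model@offset))
}

#' Minimum distance from a residue to a cofactor ligand
#'
#' Minimum Euclidean distance over all pairs of residue heavy atoms and
#' ligand heavy atoms. CBS is oligomeric, so the default scope considers
#' ligand copies in every chain; \code{scope = "same_chain"} restricts to
#' the residue's own chain for monomer-level analysis.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param position residue index in NP_000062 numbering.
#' @param ligand \code{"heme"} or \code{"plp"}.
#' @param scope \code{"all_chains"} (default) or \code{"same_chain"}.
#' @return distance in Angstrom.
#' @export
minLigandDistance <- function(model, position, ligand = c("heme", "plp"),
                              scope = c("all_chains", "same_chain")) {
  ligand <- match.arg(ligand)
  scope <- match.arg(scope)
  res <- .residue_atoms(model, position)
  at <- model@atoms
  lig <- at[at$het & at$resid %in% model@ligands[[ligand]], , drop = FALSE]
  if (scope == "same_chain")
    lig <- lig[lig$chain %in% unique(res$chain), , drop = FALSE]
  if (nrow(lig) == 0)
    stop("no '", ligand, "' ligand atoms in scope '", scope, "'")
  a <- as.matrix(res[, c("x", "y", "z")])
  b <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

## deterministic near-uniform sphere points (Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements, vdw = .VDW) {
  r <- vdw[elements]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

## molecule-fixed orthonormal frame for atom i, built from the directions
## to its two nearest neighbors; rotates with the molecule, making the
## discretized SASA exactly rigid-body invariant. Falls back to the
## identity frame for isolated or fully collinear environments (where the
## occlusion geometry is axially symmetric anyway).
.local_frame <- function(xyz, i) {
  d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
  d2[i] <- Inf
  ord <- order(d2)
  if (!is.finite(d2[ord[1]])) return(diag(3))
  e1 <- xyz[ord[1], ] - xyz[i, ]
  e1 <- e1 / sqrt(sum(e1^2))
  for (j in ord[-1]) {
    if (!is.finite(d2[j])) break
    v <- xyz[j, ] - xyz[i, ]
    v <- v - sum(v * e1) * e1
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) {
      e2 <- v / nv
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      return(cbind(e1, e2, e3))
    }
  }
  ## collinear: any perpendicular completes the frame
  a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

## Shrake-Rupley accessible surface area per atom, in the context of all
## occluding atoms of the model. Returns a numeric vector aligned with
## `idx`.
.atom_sasa <- function(model, idx, probe = 1.4, n_points = 960) {
  at <- model@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .atom_radii(at$elesy) + probe
  pts <- .sphere_points(n_points)
  vapply(idx, function(i) {
    ri <- rad[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(nrow(xyz)) != i)
    surf <- sweep(pts %*% t(.local_frame(xyz, i)) * ri, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= rad[j]^2
    }
    4 * pi * ri^2 * sum(acc) / n_points
  }, numeric(1))
}

#' Solvent accessibility of a residue
#'
#' Numerical rolling-probe (Shrake-Rupley) accessible surface area:
#' each heavy atom's sphere is expanded by the probe radius and sampled
#' with a deterministic near-uniform point lattice; points occluded by any
#' neighboring expanded sphere are removed. The residue's absolute area
#' is the sum over its atoms; relative accessibility divides by the
#' theoretical tripeptide maximum for the residue type.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param position residue index (NP_000062 numbering).
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points sphere sample points per atom (960).
#' @param relative if \code{TRUE} (default) return relative accessibility
#'   in [0, 1]; otherwise the absolute area in Angstrom^2.
#' @return numeric scalar.
#' @export
solventAccessibility <- function(model, position, probe = 1.4,
                                 n_points = 960, relative = TRUE) {
  res <- .residue_atoms(model, position)
  idx <- match(res$eleno, model@atoms$eleno)
  area <- sum(.atom_sasa(model, idx, probe = probe, n_points = n_points))
  if (!relative) return(area)
  maxasa <- .MAX_ASA[res$resid[1]]
  if (is.na(maxasa))
    stop("no reference maximum area for residue type '", res$resid[1], "'")
  min(1, area / as.numeric(maxasa))
}

## dihedral angle (degrees) of four points given as rows of a matrix
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## phi/psi table for one chain from backbone N, CA, C atoms
.phi_psi <- function(model, chain) {
  at <- model@atoms
  bb <- at[!at$het & at$chain == chain & at$elety %in% c("N", "CA", "C"), ]
  resnos <- sort(unique(bb$resno))
  get <- function(resno, name) {
    m <- bb[bb$resno == resno & bb$elety == name, c("x", "y", "z")]
    if (nrow(m) != 1) return(NULL)
    as.numeric(m)
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- get(r, "N"); CA <- get(r, "CA"); C <- get(r, "C")
    Cm <- get(r - 1, "C"); Np <- get(r + 1, "N")
    if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(C))
      phi[k] <- .dihedral(Cm, N, CA, C)
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Np))
      psi[k] <- .dihedral(N, CA, C, Np)
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

.dihedral_ss <- function(phi, psi) {
  helix <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  strand <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -80 &
    ((psi >= 80 & psi <= 180) | (psi >= -180 & psi <= -170))
  reg <- helix | strand
  ## keep only runs of length >= 3
  r <- rle(reg)
  r$values <- r$values & r$lengths >= 3
  inverse.rle(r)
}

#' Regular secondary structure membership
#'
#' \code{TRUE} when the residue lies in a helix or strand. Primary
#' source: the file's HELIX/SHEET records. When the file carries none,
#' falls back to backbone-dihedral windows (helix: phi in [-100, -30] and
#' psi in [-80, -5]; strand: phi in [-180, -80] and psi in [80, 180] or
#' [-180, -170]), keeping runs of at least three consecutive residues.
#' Returns \code{NA} when neither records nor backbone geometry are
#' available for the residue.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param position residue index (NP_000062 numbering).
#' @return logical scalar (possibly NA).
#' @export
secondaryStructure <- function(model, position) {
  resno <- position - model@offset
  res <- .residue_atoms(model, position)
  chains <- unique(res$chain)
  spans <- rbind(model@helix, model@sheet)
  if (nrow(spans) > 0) {
    hit <- any(spans$chain %in% chains & spans$start <= resno &
                 spans$end >= resno)
    return(hit)
  }
  for (ch in chains) {
    pp <- .phi_psi(model, ch)
    k <- match(resno, pp$resno)
    if (is.na(k)) next
    if (is.na(pp$phi[k]) && is.na(pp$psi[k])) next
    reg <- .dihedral_ss(pp$phi, pp$psi)
    return(reg[k])
  }
  NA
}

#' Mean crystallographic B-factor of a residue
#'
#' Unweighted mean of the atomic B-factors over the residue's heavy
#' atoms; \code{NA} when no atom carries a B value.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param position residue index (NP_000062 numbering).
#' @return numeric scalar (possibly NA).
#' @export
meanBfactor <- function(model, position) {
  res <- .residue_atoms(model, position)
  b <- res$b[!is.na(res$b)]
  if (length(b) == 0) return(NA_real_)
  mean(b)
}

#' Per-residue structural features for a variant panel
#'
#' Computes the five physical characteristics used in the
#' phenotype-association analysis for every distinct mutated residue of
#' the panel: minimum distance to heme, minimum distance to PLP, relative
#' solvent accessibility, regular-secondary-structure membership, and
#' mean B-factor. Residues outside the model are reported with all
#' features absent; the mapped/unmapped bookkeeping (counting
#' substitutions, not distinct positions) is attached as attributes
#' \code{"n_mapped"} and \code{"n_unmapped"}.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param panel a \code{\link{VariantPanel}}.
#' @param scope ligand-distance scope, see \code{\link{minLigandDistance}}.
#' @param probe,n_points solvent-accessibility parameters.
#' @return data.frame keyed by \code{position} with columns
#'   \code{dist_heme}, \code{dist_plp}, \code{rsa}, \code{in_regular_ss},
#'   \code{mean_bfactor}, \code{mapped}.
#' @export
featureTable <- function(model, panel, scope = "all_chains", probe = 1.4,
                         n_points = 960) {
  rec <- variantRecords(panel)
  positions <- sort(unique(rec$position))
  if (length(positions) == 0) {
    out <- data.frame(position = integer(), dist_heme = numeric(),
                      dist_plp = numeric(), rsa = numeric(),
                      in_regular_ss = logical(), mean_bfactor = numeric(),
                      mapped = logical())
    attr(out, "n_mapped") <- 0L
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  rows <- lapply(positions, function(p) {
    if (!.has_residue(model, p))
      return(data.frame(position = p, dist_heme = NA_real_,
                        dist_plp = NA_real_, rsa = NA_real_,
                        in_regular_ss = NA, mean_bfactor = NA_real_,
                        mapped = FALSE))
    data.frame(
      position = p,
      dist_heme = minLigandDistance(model, p, "heme", scope),
      dist_plp = minLigandDistance(model, p, "plp", scope),
      rsa = solventAccessibility(model, p, probe = probe,
                                 n_points = n_points),
      in_regular_ss = secondaryStructure(model, p),
      mean_bfactor = meanBfactor(model, p),
      mapped = TRUE
    )
  })
  out <- do.call(rbind, rows)
  mapped_pos <- out$position[out$mapped]
  attr(out, "n_mapped") <- length(mapped_pos)
  attr(out, "n_unmapped") <- sum(!(rec$position %in% mapped_pos))
  out
}
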