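# Builders shared across test files. Everything is generated in code;
# no stored fixtures beyond the bundled variant tables.

# A curve set of paired major/variant wells at one dose, nrep replicate
# wells each, laid out on the plates given by `plates` (recycled).
make_pair_curves <- function(ratio, nrep = 3, cfg = curveSimConfig(),
                             plates = "P1", dose = 400, seed = 1) {
  set.seed(seed)
  rows <- list(); eps <- list(); k <- 0
  plates <- rep_len(plates, nrep)
  for (i in seq_len(nrep)) {
    for (s in c("major", "var")) {
      k <- k + 1
      r <- if (s == "major") cfg$max_rate else cfg$max_rate * ratio
      sim <- simulateCurve(cfg, true_rate = r)
      w <- sprintf("W%03d", k)
      rows[[k]] <- data.frame(plate_id = plates[i], well_id = w,
                              strain_label = s, pyridoxine = dose,
                              dala = NA_real_, hem1_deleted = FALSE,
                              time_h = sim$time_h, od595 = sim$od595)
      eps[[k]] <- data.frame(plate_id = plates[i], well_id = w,
                             endpoint_od = sim$endpoint_od)
    }
  }
  new("GrowthCurveSet", curves = do.call(rbind, rows),
      endpoints = do.call(rbind, eps))
}

# Minimal StructureModel built directly from an atom table (bypasses the
# PDB writer/reader for toy-geometry tests).
make_model <- function(atoms, helix = NULL, sheet = NULL, offset = 0L) {
  empty <- data.frame(chain = character(), start = integer(),
                      end = integer())
  new("StructureModel", atoms = atoms,
      helix = if (is.null(helix)) empty else helix,
      sheet = if (is.null(sheet)) empty else sheet,
      ligands = list(heme = "HEM", plp = c("PLP", "LLP")),
      offset = as.integer(offset))
}

atom_row <- function(eleno, elety, resid, chain, resno, x, y, z,
                     b = 20, o = 1, elesy = "C", het = FALSE) {
  data.frame(eleno = eleno, elety = elety, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, b = b, o = o,
             elesy = elesy, het = het)
}

# Random rigid-body transform applied to a StructureModel.
rigid_transform <- function(model, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3)
  R <- Rx %*% Ry %*% Rz
  shift <- runif(3, -20, 20)
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")]) %*% R
  model@atoms$x <- xyz[, 1] + shift[1]
  model@atoms$y <- xyz[, 2] + shift[2]
  model@atoms$z <- xyz[, 3] + shift[3]
  model
}

# Brute-force residue-to-ligand minimum distance over every atom pair.
brute_min_distance <- function(model, position, ligand) {
  at <- model@atoms
  res <- at[!at$het & at$resno == (position - model@offset), ]
  lig <- at[at$het & at$resid %in% model@ligands[[ligand]], ]
  best <- Inf
  for (i in seq_len(nrow(res)))
    for (j in seq_len(nrow(lig)))
      best <- min(best, sqrt(sum((c(res$x[i], res$y[i], res$z[i]) -
                                    c(lig$x[j], lig$y[j], lig$z[j]))^2)))
  best
}
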