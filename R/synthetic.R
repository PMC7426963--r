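# Synthetic Fab-like couples with known ground truth.
#
# Chains are built as ideal-geometry backbones (fixed bond lengths/angles,
# torsions extended atom by atom), with two gently supercoiled helical
# pseudo-domains joined by an extended linker. The bound form is derived
# from the free form by an exact rigid rotation of everything past the
# linker anchor about an axis through the anchor atom perpendicular to the
# anchor plane -- so the applied hinge angle maps one-to-one onto the
# measured C-S-C / C-R-C angle change -- plus tapered displacements of the
# designated C_Loop1 and CDR segments and independent Gaussian noise on both
# forms.

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Rodrigues rotation matrix: angle in degrees about unit axis
rotation_about <- function(axis, angle_deg) {
  a <- unit3(axis); t <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Natural-extension placement: position D such that |CD| = bond,
# angle(B,C,D) = angle_deg, dihedral(A,B,C,D) = torsion_deg.
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; chi <- torsion_deg * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Backbone N/CA/C trace from torsion vectors (psi[i] and phi[i+1] consumed
# between residues i and i+1; omega fixed trans).
nerf_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.6, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.0, phi[i + 1])
  }
  list(N = N, CA = CA, C = C)
}

#' Specification of a synthetic Fab couple
#'
#' Defines the ground truth of a generated free/bound couple. Hinge angles
#' are magnitudes (degrees); the generator applies them with the sense
#' observed in hinging couples -- the heavy-chain angle closes and the
#' light-chain angle opens on binding. `c_loop1_displacement` moves the heavy
#' chain's C_Loop1 window; `cdr_displacement` moves the CDR windows (full
#' magnitude on the heavy chain, half on the light chain, reflecting
#' heavy-dominant paratope changes). Gaussian noise of `noise_sigma` per
#' coordinate is added independently to the free and bound forms, emulating
#' independent crystal determinations.
#'
#' @param n_variable,n_linker,n_constant Residue counts (defaults 105/8/105,
#'   matching the default [region_scheme()]).
#' @param hinge_angle_heavy,hinge_angle_light Hinge magnitudes in degrees
#'   (`>= 0`).
#' @param c_loop1_displacement,cdr_displacement Displacement magnitudes in
#'   Angstrom (`>= 0`).
#' @param noise_sigma Gaussian noise, Angstrom per coordinate (default 0.2,
#'   a typical coordinate uncertainty at ~2.5 Angstrom resolution).
#' @param seed Integer RNG seed; fixed seed gives bitwise-identical output.
#' @param light_type `"light_kappa"` or `"light_lambda"`.
#' @param anchor_plan Optional list with `v_cys`, `linker`, `c_cys` planted
#'   positions; defaults scale with the residue counts (72/108/160 for the
#'   default sizes).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_variable = 105L, n_linker = 8L, n_constant = 105L,
                           hinge_angle_heavy = 0, hinge_angle_light = 0,
                           c_loop1_displacement = 0, cdr_displacement = 0,
                           noise_sigma = 0.2, seed = 1L,
                           light_type = c("light_kappa", "light_lambda"),
                           anchor_plan = NULL) {
  light_type <- match.arg(light_type)
  n_variable <- as.integer(n_variable); n_linker <- as.integer(n_linker)
  n_constant <- as.integer(n_constant)
  if (n_variable < 40 || n_linker < 4 || n_constant < 40)
    spec_error("residue counts too small: need variable/constant >= 40, linker >= 4")
  if (any(c(hinge_angle_heavy, hinge_angle_light, c_loop1_displacement,
            cdr_displacement, noise_sigma) < 0))
    spec_error("hinge angles, displacements and noise must be >= 0")
  if (is.null(anchor_plan))
    anchor_plan <- list(v_cys = n_variable - 33L,
                        linker = n_variable + 3L,
                        c_cys = n_variable + n_linker + 47L)
  structure(list(n_variable = n_variable, n_linker = n_linker,
                 n_constant = n_constant,
                 hinge_angle_heavy = hinge_angle_heavy,
                 hinge_angle_light = hinge_angle_light,
                 c_loop1_displacement = c_loop1_displacement,
                 cdr_displacement = cdr_displacement,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 light_type = light_type, anchor_plan = anchor_plan),
            class = "synthetic_spec")
}

#' Region scheme matching a synthetic spec's residue counts
#' @param spec A [synthetic_spec()].
#' @return A [region_scheme()].
#' @export
synthetic_region_scheme <- function(spec) {
  nv <- spec$n_variable; nl <- spec$n_linker; nc <- spec$n_constant
  region_scheme(variable = c(1L, nv), linker = c(nv + 1L, nv + nl),
                constant = c(nv + nl + 1L, nv + nl + nc),
                entire = c(1L, nv + nl + nc))
}

aa_pool <- setdiff(c("A", "R", "N", "D", "E", "Q", "G", "H", "I", "L", "K",
                     "M", "F", "P", "S", "T", "W", "Y", "V"), character(0))

synthetic_sequence <- function(spec, chain_type) {
  n <- spec$n_variable + spec$n_linker + spec$n_constant
  plan <- spec$anchor_plan
  linker_aa <- linker_anchor_aa[[chain_type]]
  aa <- sample(aa_pool, n, replace = TRUE)
  lnk <- seq.int(spec$n_variable + 1L, spec$n_variable + spec$n_linker)
  redraw <- lnk[aa[lnk] == linker_aa]
  if (length(redraw) > 0)
    aa[redraw] <- sample(setdiff(aa_pool, linker_aa), length(redraw), replace = TRUE)
  aa[plan$v_cys] <- "C"
  aa[plan$c_cys] <- "C"
  aa[plan$linker] <- linker_aa
  aa
}

# torsion plan: supercoiled helices for the two pseudo-domains, extended linker
synthetic_torsions <- function(spec, phase = 0) {
  nv <- spec$n_variable; nl <- spec$n_linker; nc <- spec$n_constant
  i_v <- seq_len(nv); i_c <- seq_len(nc)
  phi <- c(-57 + 8 * sin(2 * pi * i_v / 30 + phase),
           rep(-120, nl),
           -57 + 8 * sin(2 * pi * i_c / 30 + phase + 1))
  psi <- c(-47 + 8 * cos(2 * pi * i_v / 30 + phase),
           rep(130, nl),
           -47 + 8 * cos(2 * pi * i_c / 30 + phase + 1))
  list(phi = phi, psi = psi)
}

build_synthetic_chain <- function(spec, chain_type, chain_id, phase = 0,
                                  placement = NULL) {
  n <- spec$n_variable + spec$n_linker + spec$n_constant
  tor <- synthetic_torsions(spec, phase)
  bb <- nerf_backbone(tor$phi, tor$psi)
  aa <- synthetic_sequence(spec, chain_type)
  plan <- spec$anchor_plan

  # carbonyl oxygens in the peptide plane
  O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1)) {
    O[i, ] <- bb$C[i, ] + 1.231 * unit3(unit3(bb$C[i, ] - bb$CA[i, ]) +
                                          unit3(bb$C[i, ] - bb$N[i + 1, ]))
  }
  O[n, ] <- bb$C[n, ] + 1.231 * unit3(bb$C[n, ] - bb$CA[n, ])

  # side-chain anchor atoms for the three planted anchors; the linker anchor
  # atom sits adjacent to the following backbone nitrogen, so the hinge pivot
  # lies on the chain and the rotated form stays peptide-bonded
  side <- list()
  for (nm in c("v_cys", "c_cys")) {
    i <- plan[[nm]]
    d1 <- unit3(bb$CA[i, ] - bb$N[i, ]); d2 <- unit3(bb$CA[i, ] - bb$C[i, ])
    dir <- unit3(0.6 * unit3(d1 + d2) + 0.8 * unit3(cross3(d1, d2)))
    side[[nm]] <- list(seq_index = i, elety = anchor_atom_for[[aa[i]]],
                       xyz = bb$CA[i, ] + 2.0 * dir)
  }
  il <- plan$linker
  d1 <- unit3(bb$CA[il, ] - bb$N[il, ]); d2 <- unit3(bb$CA[il, ] - bb$C[il, ])
  side$linker <- list(seq_index = il, elety = anchor_atom_for[[aa[il]]],
                      xyz = bb$N[il + 1, ] + 0.8 * unit3(cross3(d1, d2)))

  atoms <- data.frame(
    seq_index = rep(seq_len(n), each = 4L),
    elety = rep(c("N", "CA", "C", "O"), n),
    x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, 4L * n, 3)
  xyz[seq(1, 4 * n, 4), ] <- bb$N
  xyz[seq(2, 4 * n, 4), ] <- bb$CA
  xyz[seq(3, 4 * n, 4), ] <- bb$C
  xyz[seq(4, 4 * n, 4), ] <- O
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  for (s in side) {
    atoms <- rbind(atoms, data.frame(seq_index = s$seq_index, elety = s$elety,
                                     x = s$xyz[1], y = s$xyz[2], z = s$xyz[3],
                                     stringsAsFactors = FALSE))
  }
  atoms <- atoms[order(atoms$seq_index), , drop = FALSE]
  rownames(atoms) <- NULL

  if (!is.null(placement)) {
    moved <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(placement$R) +
      matrix(placement$t, nrow(atoms), 3, byrow = TRUE)
    atoms$x <- moved[, 1]; atoms$y <- moved[, 2]; atoms$z <- moved[, 3]
  }

  structure(list(chain_id = chain_id, chain_type = chain_type,
                 source_entry = "SYNTH",
                 residues = data.frame(seq_index = seq_len(n),
                                       author_number = as.character(seq_len(n)),
                                       aa = aa, stringsAsFactors = FALSE),
                 atoms = atoms),
            class = "fab_chain")
}

#' Build the free form of a synthetic Fab
#'
#' Deterministic given the spec's seed: two continuous 218-residue chains
#' (default sizes) with ideal peptide geometry, planted anchor residues and
#' designated CDR / C_Loop windows, assembled into a Fab-like pair. No noise
#' is applied here; [synthetic_couple()] adds it.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `heavy` and `light` (`fab_chain` objects).
#' @export
build_free_fab <- function(spec) {
  set.seed(spec$seed)
  heavy <- build_synthetic_chain(spec, "heavy", "H", phase = 0)
  light <- build_synthetic_chain(spec, spec$light_type, "L", phase = 0.9)
  # pair the chains: flip the light chain and set it down so the two linker
  # anchors sit 14 A apart, as at a Fab elbow
  ah <- planted_anchor_xyz(heavy, spec$anchor_plan)$a
  al <- planted_anchor_xyz(light, spec$anchor_plan)$a
  R <- rotation_about(c(1, 0, 0), 180)
  tr <- ah + c(0, 0, 14) - as.numeric(R %*% al)
  xyz <- chain_xyz(light) %*% t(R) + matrix(tr, nrow(light$atoms), 3, byrow = TRUE)
  list(heavy = heavy, light = set_chain_xyz(light, xyz))
}

chain_xyz <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

set_chain_xyz <- function(chain, xyz) {
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]; chain$atoms$z <- xyz[, 3]
  chain
}

planted_anchor_xyz <- function(chain, plan) {
  get <- function(i, nm) {
    aa <- chain$residues$aa[i]
    row <- chain$atoms[chain$atoms$seq_index == i &
                         chain$atoms$elety == anchor_atom_for[[aa]], , drop = FALSE]
    as.numeric(row[1, c("x", "y", "z")])
  }
  list(v = get(plan$v_cys), a = get(plan$linker), c = get(plan$c_cys))
}

# rigid hinge of everything past the linker anchor, about the axis through
# the anchor atom perpendicular to the anchor plane; signed degrees
apply_hinge <- function(chain, plan, angle_deg) {
  if (angle_deg == 0) return(chain)
  anc <- planted_anchor_xyz(chain, plan)
  axis <- cross3(anc$v - anc$a, anc$c - anc$a)
  R <- rotation_about(axis, angle_deg)
  xyz <- chain_xyz(chain)
  sel <- chain$atoms$seq_index > plan$linker
  xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, anc$a) %*% t(R) +
    matrix(anc$a, sum(sel), 3, byrow = TRUE)
  set_chain_xyz(chain, xyz)
}

# displace a residue window along a fixed direction with a smooth sine-squared
# taper (magnitude reached at the window centre)
apply_displacement <- function(chain, span, magnitude, domain_span) {
  if (magnitude == 0) return(chain)
  xyz <- chain_xyz(chain)
  ca <- chain$atoms$elety == "CA"
  in_span <- function(ix, sp) ix >= sp[1] & ix <= sp[2]
  loop_ca <- xyz[ca & in_span(chain$atoms$seq_index, span), , drop = FALSE]
  dom_ca <- xyz[ca & in_span(chain$atoms$seq_index, domain_span), , drop = FALSE]
  dir <- unit3(colMeans(loop_ca) - colMeans(dom_ca))
  len <- span[2] - span[1] + 1L
  for (j in seq.int(span[1], span[2])) {
    w <- sin(pi * (j - span[1] + 1) / (len + 1))^2
    sel <- chain$atoms$seq_index == j
    xyz[sel, ] <- xyz[sel, , drop = FALSE] +
      matrix(magnitude * w * dir, sum(sel), 3, byrow = TRUE)
  }
  set_chain_xyz(chain, xyz)
}

add_coordinate_noise <- function(chain, sigma) {
  if (sigma == 0) return(chain)
  xyz <- chain_xyz(chain)
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz), 3)
  set_chain_xyz(chain, xyz)
}

#' Derive the bound form of a synthetic Fab
#'
#' Applies, in order: the hinge rotation of each chain's constant side (heavy
#' closing, light opening, by the spec's magnitudes), the tapered C_Loop1
#' displacement on the heavy chain, the tapered CDR displacements (heavy at
#' full magnitude, light at half), and finally Gaussian coordinate noise.
#'
#' @param free Output of [build_free_fab()] (the ideal, noise-free form).
#' @param spec The same [synthetic_spec()].
#' @return List with `heavy` and `light` bound `fab_chain` objects.
#' @export
derive_bound_fab <- function(free, spec) {
  plan <- spec$anchor_plan
  scheme <- synthetic_region_scheme(spec)
  heavy <- apply_hinge(free$heavy, plan, -spec$hinge_angle_heavy)
  light <- apply_hinge(free$light, plan, +spec$hinge_angle_light)

  loops_h <- default_c_loop_table()$heavy
  heavy <- apply_displacement(heavy, loops_h$C_Loop1, spec$c_loop1_displacement,
                              scheme$constant)
  for (sp in default_cdr_table()$heavy)
    heavy <- apply_displacement(heavy, sp, spec$cdr_displacement, scheme$variable)
  for (sp in default_cdr_table()[[spec$light_type]])
    light <- apply_displacement(light, sp, spec$cdr_displacement / 2, scheme$variable)

  set.seed(spec$seed + 2000003L)
  list(heavy = add_coordinate_noise(heavy, spec$noise_sigma),
       light = add_coordinate_noise(light, spec$noise_sigma))
}

#' Generate a complete synthetic couple
#'
#' Builds the ideal free Fab, derives the bound form, and adds independent
#' coordinate noise to the free form as well, with the ground truth recorded
#' alongside.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `free`, `bound` (each `heavy`/`light` chain lists),
#'   `spec`, and `truth` (applied signed hinge angles, displaced spans,
#'   planted anchor positions).
#' @export
synthetic_couple <- function(spec) {
  ideal <- build_free_fab(spec)
  bound <- derive_bound_fab(ideal, spec)
  set.seed(spec$seed + 1000003L)
  free <- list(heavy = add_coordinate_noise(ideal$heavy, spec$noise_sigma),
               light = add_coordinate_noise(ideal$light, spec$noise_sigma))
  list(free = free, bound = bound, spec = spec,
       truth = list(
         hinge_signed = c(heavy = -spec$hinge_angle_heavy,
                          light = +spec$hinge_angle_light),
         c_loop1_span = default_c_loop_table()$heavy$C_Loop1,
         c_loop1_displacement = spec$c_loop1_displacement,
         cdr_displacement = c(heavy = spec$cdr_displacement,
                              light = spec$cdr_displacement / 2),
         anchors = spec$anchor_plan, noise_sigma = spec$noise_sigma))
}

#' Canonical synthetic study conditions for the three classes
#'
#' Presets generating a hinging couple with a loop signal (B1-like:
#' 25-degree hinges plus a 2 Angstrom C_Loop1 displacement), a loop-only
#' couple (B2-like: no hinge, 2 Angstrom loop), and a CDR-only couple
#' (B3-like: no hinge, no loop, 2 Angstrom CDR displacement).
#'
#' @param class_label `"B1"`, `"B2"` or `"B3"`.
#' @param seed RNG seed.
#' @return A [synthetic_spec()].
#' @export
canonical_couple_spec <- function(class_label, seed = 1L) {
  switch(match.arg(class_label, c("B1", "B2", "B3")),
         B1 = synthetic_spec(hinge_angle_heavy = 25, hinge_angle_light = 25,
                             c_loop1_displacement = 2, cdr_displacement = 1,
                             seed = seed),
         B2 = synthetic_spec(c_loop1_displacement = 2, cdr_displacement = 1,
                             seed = seed),
         B3 = synthetic_spec(cdr_displacement = 2, seed = seed))
}

#' Write a synthetic couple to PDB files
#'
#' Emits `<prefix>_free.pdb` and `<prefix>_bound.pdb` (chains H and L) plus a
#' `<prefix>_truth.json` ground-truth sidecar; files are re-readable by
#' [parse_structure()] with lossless sequence and 0.001 Angstrom coordinates.
#'
#' @param couple Output of [synthetic_couple()].
#' @param directory Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the paths written.
#' @export
write_couple_pdb <- function(couple, directory, prefix = "synth") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(free = file.path(directory, paste0(prefix, "_free.pdb")),
             bound = file.path(directory, paste0(prefix, "_bound.pdb")),
             truth = file.path(directory, paste0(prefix, "_truth.json")))
  write_fab_pdb(couple$free, paths[["free"]])
  write_fab_pdb(couple$bound, paths[["bound"]])
  jsonlite::write_json(couple$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Write a two-chain Fab as one PDB file
#' @param fab List with `heavy` and `light` `fab_chain` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fab_pdb <- function(fab, path) {
  parts <- list(H = fab$heavy, L = fab$light)
  at <- do.call(rbind, lapply(names(parts), function(cid) {
    ch <- parts[[cid]]
    resid3 <- vapply(ch$residues$aa, function(a) {
      r <- suppressWarnings(bio3d::aa123(a)); if (is.na(r)) "UNK" else r
    }, character(1))
    data.frame(chain = cid, resno = ch$residues$seq_index[ch$atoms$seq_index],
               resid = resid3[ch$atoms$seq_index], elety = ch$atoms$elety,
               x = ch$atoms$x, y = ch$atoms$y, z = ch$atoms$z,
               stringsAsFactors = FALSE)
  }))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}
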