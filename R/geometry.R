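# Side-chain atom carrying the anchor geometry, per residue identity; CA is
# the fallback when the side-chain atom is absent from the model.
anchor_atom_for <- c(C = "SG", S = "OG", R = "CZ", Q = "CD")

linker_anchor_aa <- c(heavy = "S", light_kappa = "R", light_lambda = "Q")

anchor_coord <- function(chain, seq_index) {
  sub <- chain$atoms[chain$atoms$seq_index == seq_index, , drop = FALSE]
  aa <- chain$residues$aa[chain$residues$seq_index == seq_index]
  want <- anchor_atom_for[[aa]]
  row <- sub[sub$elety == want, , drop = FALSE]
  used <- want
  if (nrow(row) == 0) {
    warning(sprintf("residue %d (%s): side-chain atom %s missing, falling back to CA",
                    seq_index, aa, want))
    row <- sub[sub$elety == "CA", , drop = FALSE]
    used <- "CA"
  }
  list(xyz = as.numeric(row[1, c("x", "y", "z")]), atom = used)
}

#' Locate the conserved anchor residues of one chain
#'
#' The hinge geometry is read from three conserved residues: a cysteine in
#' the variable domain (the last Cys of the variable span), a cysteine in the
#' constant domain (the first Cys of the constant span), and the conserved
#' linker residue between them -- serine in heavy chains, arginine in kappa
#' light chains, glutamine in lambda light chains (the first such residue in
#' the linker span). Explicit overrides replace the defaults after identity
#' and region validation.
#'
#' @param chain A `fab_chain`.
#' @param annotation A `region_annotation` for the chain.
#' @param overrides Optional list with any of `v_cys`, `linker`, `c_cys`
#'   seq_index values.
#' @return An object of class `anchor_set`: list with `v_cys`, `linker`,
#'   `c_cys`, each a list of `seq_index`, `aa`, `atom`, `xyz`; plus
#'   `chain_type`.
#' @export
find_anchors <- function(chain, annotation, overrides = NULL) {
  sch <- annotation$scheme
  res <- chain$residues
  want_linker <- linker_anchor_aa[[chain$chain_type]]

  pick <- function(name, aa_want, span, take_last = FALSE) {
    ov <- overrides[[name]]
    if (!is.null(ov)) {
      ov <- as.integer(ov)
      hit <- res$aa[res$seq_index == ov]
      if (length(hit) == 0 || hit != aa_want)
        anchor_identity_error(sprintf(
          "%s override at %d is '%s', expected '%s'", name, ov,
          if (length(hit)) hit else "absent", aa_want))
      if (ov < span[1] || ov > span[2])
        anchor_identity_error(sprintf("%s override %d outside span %d-%d",
                                      name, ov, span[1], span[2]))
      return(ov)
    }
    cand <- res$seq_index[res$aa == aa_want &
                            res$seq_index >= span[1] & res$seq_index <= span[2]]
    if (length(cand) == 0)
      anchor_not_found_error(sprintf("no %s ('%s') found in span %d-%d of chain '%s'",
                                     name, aa_want, span[1], span[2], chain$chain_id),
                             anchor = name)
    if (take_last) cand[length(cand)] else cand[1]
  }

  iv <- pick("v_cys", "C", sch$variable, take_last = TRUE)
  il <- pick("linker", want_linker, sch$linker)
  ic <- pick("c_cys", "C", sch$constant)

  mk <- function(i) {
    ac <- anchor_coord(chain, i)
    list(seq_index = i, aa = res$aa[res$seq_index == i], atom = ac$atom, xyz = ac$xyz)
  }
  structure(list(v_cys = mk(iv), linker = mk(il), c_cys = mk(ic),
                 chain_type = chain$chain_type),
            class = "anchor_set")
}

#' Hinge (elbow) angle at the linker anchor
#'
#' The planar angle, in degrees, at the conserved linker residue between the
#' vectors to the variable-domain and constant-domain cysteine anchors
#' (C-S-C in heavy chains, C-R-C / C-Q-C in light chains).
#'
#' @param anchors An `anchor_set`.
#' @return Angle in degrees, in `(0, 180]`.
#' @export
hinge_angle <- function(anchors) {
  u <- anchors$v_cys$xyz - anchors$linker$xyz
  w <- anchors$c_cys$xyz - anchors$linker$xyz
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-6 || nw < 1e-6)
    degenerate_error("coincident anchor atoms; hinge angle undefined")
  cosang <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Anchor distances within and between chains
#'
#' Euclidean distances between the variable- and constant-domain cysteine
#' anchors within each chain, and between the heavy and light linker anchors
#' (the linker-linker distance that widens in class B1 couples).
#'
#' @param heavy,light `anchor_set` objects for the two chains of one Fab.
#' @return List with `cys_cys_heavy`, `cys_cys_light`,
#'   `linker_linker` (Angstrom).
#' @export
anchor_distances <- function(heavy, light) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  out <- list(cys_cys_heavy = d(heavy$v_cys$xyz, heavy$c_cys$xyz),
              cys_cys_light = d(light$v_cys$xyz, light$c_cys$xyz),
              linker_linker = d(heavy$linker$xyz, light$linker$xyz))
  if (any(unlist(out) < 1e-6))
    warning("degenerate anchor geometry: coincident anchor atoms")
  out
}

#' Angle and distance metrics of one Fab structure
#'
#' @param heavy,light `fab_chain` objects of one Fab.
#' @param annotation_heavy,annotation_light `region_annotation` objects.
#' @param overrides_heavy,overrides_light Optional anchor overrides (see
#'   [find_anchors()]).
#' @return An object of class `angle_metrics`: `heavy_angle`, `light_angle`
#'   (degrees), the three anchor distances, and the anchor sets used.
#' @export
fab_angle_metrics <- function(heavy, light, annotation_heavy, annotation_light,
                              overrides_heavy = NULL, overrides_light = NULL) {
  ah <- find_anchors(heavy, annotation_heavy, overrides_heavy)
  al <- find_anchors(light, annotation_light, overrides_light)
  dd <- anchor_distances(ah, al)
  structure(c(list(heavy_angle = hinge_angle(ah), light_angle = hinge_angle(al)),
              dd, list(anchors_heavy = ah, anchors_light = al)),
            class = "angle_metrics")
}

#' Hinge-angle change between free and bound forms
#'
#' Signed per-chain changes (bound minus free) and their average magnitude,
#' `(|delta_heavy| + |delta_light|) / 2` -- the per-couple summary compared
#' against the classification threshold.
#'
#' @param free,bound `angle_metrics` of the same couple, measured at the same
#'   anchor residues.
#' @return List with `delta_heavy`, `delta_light` (signed degrees),
#'   `average_abs_change` (degrees) and the distance changes
#'   `delta_cys_cys_heavy`, `delta_cys_cys_light`, `delta_linker_linker`
#'   (Angstrom).
#' @export
angle_change <- function(free, bound) {
  idx <- function(m) c(m$anchors_heavy$v_cys$seq_index, m$anchors_heavy$linker$seq_index,
                       m$anchors_heavy$c_cys$seq_index, m$anchors_light$v_cys$seq_index,
                       m$anchors_light$linker$seq_index, m$anchors_light$c_cys$seq_index)
  if (!identical(idx(free), idx(bound)))
    anchor_mismatch_error("free and bound forms use different anchor residues")
  dh <- bound$heavy_angle - free$heavy_angle
  dl <- bound$light_angle - free$light_angle
  list(delta_heavy = dh, delta_light = dl,
       average_abs_change = (abs(dh) + abs(dl)) / 2,
       delta_cys_cys_heavy = bound$cys_cys_heavy - free$cys_cys_heavy,
       delta_cys_cys_light = bound$cys_cys_light - free$cys_cys_light,
       delta_linker_linker = bound$linker_linker - free$linker_linker)
}
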