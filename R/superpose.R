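#' Root-mean-square deviation of paired coordinates
#'
#' Plain RMSD between two equally sized, correspondingly ordered coordinate
#' sets: `sqrt(sum |r_i,A - r_i,F|^2 / N)`. No fitting is performed.
#'
#' @param coords_a,coords_b Numeric `N x 3` matrices in Angstrom.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3)
    shape_error("coordinate sets must be matching N x 3 matrices")
  if (nrow(coords_a) < 1) shape_error("need at least one atom")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of the
#' mobile set onto the reference (SVD-based Kabsch algorithm with determinant
#' correction, so reflections are never returned).
#'
#' @param coords_mobile,coords_ref Numeric `N x 3` matrices (`N >= 3`,
#'   non-collinear).
#' @param scope Label recorded on the result (e.g. `"entire"` or a domain
#'   name).
#' @return An object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length-3), `rmsd` (Angstrom, of the transformed mobile set
#'   against the reference), `n_atoms` and `scope`. Apply with
#'   [apply_transform()]: `x %*% t(rotation) + translation`.
#' @export
superpose_fit <- function(coords_mobile, coords_ref, scope = "entire") {
  m <- as.matrix(coords_mobile); r <- as.matrix(coords_ref)
  if (!all(dim(m) == dim(r)) || ncol(m) != 3)
    shape_error("coordinate sets must be matching N x 3 matrices")
  if (nrow(m) < 3) degenerate_error("need at least 3 atoms to superpose")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (svd(mc)$d[2] < 1e-8 || svd(rc)$d[2] < 1e-8)
    degenerate_error("coordinate set is collinear or coincident")
  H <- crossprod(mc, rc)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- m %*% t(R) + matrix(tr, nrow(m), 3, byrow = TRUE)
  structure(list(rotation = R, translation = tr,
                 rmsd = rmsd_raw(fitted, r), n_atoms = nrow(m),
                 scope = scope, n_dropped = 0L),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords Numeric `N x 3` matrix.
#' @param fit A `superposition`.
#' @return Transformed `N x 3` matrix.
#' @export
apply_transform <- function(coords, fit) {
  coords <- as.matrix(coords)
  coords %*% t(fit$rotation) + matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

# default backbone atom set; O is used when present, residues keep N/CA/C
# otherwise (side chains are excluded from all RMSD/RMSF)
backbone_atoms <- c("N", "CA", "C", "O")

# Matched backbone coordinates of two chains over a residue span.
# Correspondence is by seq_index + atom name; atoms missing in either chain
# are dropped pairwise.
matched_backbone <- function(chain_a, chain_b, span = NULL,
                             atom_set = backbone_atoms) {
  sel_a <- chain_a$atoms[chain_a$atoms$elety %in% atom_set, , drop = FALSE]
  sel_b <- chain_b$atoms[chain_b$atoms$elety %in% atom_set, , drop = FALSE]
  if (!is.null(span)) {
    keep <- function(df) df[df$seq_index >= span[1] & df$seq_index <= span[2], , drop = FALSE]
    sel_a <- keep(sel_a); sel_b <- keep(sel_b)
  }
  ka <- paste(sel_a$seq_index, sel_a$elety)
  kb <- paste(sel_b$seq_index, sel_b$elety)
  common <- intersect(ka, kb)
  dropped <- (length(ka) - length(common)) + (length(kb) - length(common))
  ia <- match(common, ka); ib <- match(common, kb)
  list(a = as.matrix(sel_a[ia, c("x", "y", "z")]),
       b = as.matrix(sel_b[ib, c("x", "y", "z")]),
       seq_index = sel_a$seq_index[ia],
       elety = sel_a$elety[ia],
       n_dropped = dropped)
}

#' Superpose two chains over a residue scope
#'
#' Fits the bound chain onto the free chain using only the backbone atoms of
#' residues inside `span` (the fitting scope). The returned transform applies
#' to the whole chain, so deviations outside the scope can be measured under
#' an in-scope fit -- the basis of both the per-domain RMSD table and the
#' per-domain RMSF profiles.
#'
#' @param free,bound `fab_chain` objects with identical sequences.
#' @param span Integer `c(start, end)` in sequential numbering, or `NULL` for
#'   the whole chain.
#' @param scope Label recorded on the result.
#' @param atom_set Backbone atom names used for fitting.
#' @return A `superposition` (mobile = bound, reference = free) with
#'   `n_dropped` recording atoms without a pairwise match.
#' @export
fit_scope <- function(free, bound, span = NULL, scope = "entire",
                      atom_set = backbone_atoms) {
  mb <- matched_backbone(free, bound, span, atom_set)
  if (nrow(mb$a) < 3)
    degenerate_error(sprintf("scope '%s' has %d matched atoms; need >= 3", scope, nrow(mb$a)))
  fit <- superpose_fit(mb$b, mb$a, scope = scope)
  fit$n_dropped <- mb$n_dropped
  fit
}
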