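#' Per-residue deviation profile between free and bound chains
#'
#' Superposes the bound chain onto the free chain over the stated scope
#' (whole chain, or one domain) and reports, for every scored residue, the
#' RMSD over that residue's backbone atoms under the single scope transform.
#' This is the per-residue decomposition of the scope RMSD: the atom-weighted
#' root-mean-square of the profile equals the scope-wide RMSD exactly. When
#' the scope is a domain, values are reported only for residues of that
#' domain; residues lacking matched backbone atoms get `NA`, never zero.
#'
#' @param free,bound `fab_chain` objects with identical sequences.
#' @param span Fitting scope `c(start, end)` in sequential numbering, or
#'   `NULL` for the whole chain.
#' @param scope Label (e.g. `"whole-chain"`, `"variable"`, `"constant"`).
#' @param report_span Residues to score; defaults to `span` for domain scopes
#'   and to all residues for the whole chain.
#' @param atom_set Backbone atom names.
#' @param couple_id,chain_id Labels carried on the profile.
#' @return An object of class `rmsf_profile`: data frame with `seq_index`,
#'   `aa`, `n_atoms`, `rmsf` (Angstrom) plus attributes `scope`, `span`,
#'   `fit_rmsd`, `couple_id`, `chain_id`.
#' @export
rmsf_profile <- function(free, bound, span = NULL, scope = if (is.null(span)) "whole-chain" else "domain",
                         report_span = span, atom_set = backbone_atoms,
                         couple_id = NA_character_, chain_id = free$chain_id) {
  fit <- fit_scope(free, bound, span, scope = scope, atom_set = atom_set)
  mb <- matched_backbone(free, bound, report_span, atom_set)
  moved <- apply_transform(mb$b, fit)
  d2 <- rowSums((moved - mb$a)^2)

  if (is.null(report_span)) {
    resi <- free$residues$seq_index
  } else {
    resi <- span_seq(report_span)
    resi <- resi[resi %in% free$residues$seq_index]
  }
  vals <- rep(NA_real_, length(resi))
  nat <- integer(length(resi))
  grp <- match(mb$seq_index, resi)
  for (k in which(!is.na(grp))) {
    i <- grp[k]
    nat[i] <- nat[i] + 1L
  }
  ss <- tapply(d2, factor(grp, levels = seq_along(resi)), sum)
  has <- nat > 0
  vals[has] <- sqrt(as.numeric(ss[has]) / nat[has])

  out <- data.frame(seq_index = resi,
                    aa = free$residues$aa[match(resi, free$residues$seq_index)],
                    n_atoms = nat, rmsf = vals, stringsAsFactors = FALSE)
  structure(out, class = c("rmsf_profile", "data.frame"),
            scope = scope, span = span, fit_rmsd = fit$rmsd,
            fit = fit, couple_id = couple_id, chain_id = chain_id)
}

#' Summary statistics of a profile over a span
#'
#' @param profile An [rmsf_profile()].
#' @param span Integer `c(start, end)` within the profile coverage.
#' @return List with `mean`, `max` (Angstrom) and `argmax` (seq_index of the
#'   maximum).
#' @export
region_summary <- function(profile, span) {
  sel <- profile$seq_index >= span[1] & profile$seq_index <= span[2] & !is.na(profile$rmsf)
  if (!any(sel)) empty_span_error(sprintf("no scored residues in span %d-%d", span[1], span[2]))
  v <- profile$rmsf[sel]
  list(mean = mean(v), max = max(v),
       argmax = profile$seq_index[sel][which.max(v)])
}

#' C_Loop1 allosteric signal from a CH1-scope profile
#'
#' Scores the constant-domain loop 1 of the heavy chain against the rest of
#' the constant domain. `peak` is the maximum profile value inside the
#' C_Loop1 window; the baseline is the median over constant-domain residues
#' outside all three C_Loops, and `ratio = peak / baseline`. A flat profile
#' yields ratio 1; a rigid domain with only C_Loop1 displaced yields a large
#' ratio.
#'
#' @param profile An [rmsf_profile()] computed with the constant (CH1) domain
#'   as fitting scope.
#' @param c_loop_spans Named list of the three `C_Loop` windows (see
#'   [annotate_c_loops()]).
#' @return List with `peak` (Angstrom), `baseline` (Angstrom) and `ratio`.
#' @export
c_loop1_signal <- function(profile, c_loop_spans) {
  sp1 <- c_loop_spans$C_Loop1
  in_loop1 <- profile$seq_index >= sp1[1] & profile$seq_index <= sp1[2]
  if (!any(in_loop1 & !is.na(profile$rmsf)))
    empty_span_error("no scored residues in C_Loop1 span")
  in_any <- Reduce(`|`, lapply(c_loop_spans, function(sp)
    profile$seq_index >= sp[1] & profile$seq_index <= sp[2]))
  base_vals <- profile$rmsf[!in_any & !is.na(profile$rmsf)]
  if (length(base_vals) == 0) empty_span_error("no baseline residues outside the C_Loops")
  peak <- max(profile$rmsf[in_loop1], na.rm = TRUE)
  baseline <- stats::median(base_vals)
  ratio <- if (baseline > 0) peak / baseline else if (peak > 0) Inf else 1
  list(peak = peak, baseline = baseline, ratio = ratio)
}

#' Tidy export of RMSF profiles
#'
#' Binds profiles into one long-format data frame (and optionally writes CSV)
#' with columns `couple_id`, `chain_id`, `scope`, `seq_index`, `aa`,
#' `rmsf_A` -- ready for replotting per-residue deviation panels.
#'
#' @param profiles List of [rmsf_profile()] objects.
#' @param path Optional CSV output path.
#' @return The combined data frame, invisibly when `path` is given.
#' @export
profiles_to_csv <- function(profiles, path = NULL) {
  rows <- lapply(profiles, function(p) {
    data.frame(couple_id = attr(p, "couple_id"), chain_id = attr(p, "chain_id"),
               scope = attr(p, "scope"), seq_index = p$seq_index, aa = p$aa,
               rmsf_A = p$rmsf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
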