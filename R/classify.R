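#' Classification thresholds
#'
#' Decision constants for the three-way class assignment. `tau_angle`
#' separates large domain reorientations (observed class-B1 couples change by
#' 16 degrees or more, B2/B3 couples by 4 or less; the default sits between).
#' `tau_loop_peak` and `tau_loop_ratio` decide whether the CH1 C_Loop1
#' deviation stands out from its domain baseline.
#'
#' @param tau_angle Degrees (default 10).
#' @param tau_loop_peak Angstrom (default 1.5).
#' @param tau_loop_ratio Dimensionless (default 2).
#' @return An object of class `class_thresholds`.
#' @export
class_thresholds <- function(tau_angle = 10, tau_loop_peak = 1.5, tau_loop_ratio = 2) {
  if (any(c(tau_angle, tau_loop_peak, tau_loop_ratio) <= 0))
    spec_error("classification thresholds must be positive")
  structure(list(tau_angle = tau_angle, tau_loop_peak = tau_loop_peak,
                 tau_loop_ratio = tau_loop_ratio),
            class = "class_thresholds")
}

#' Assign the binding conformational-change class
#'
#' B1: the Fab's diamond-like shape distorts -- the average hinge-angle
#' magnitude change reaches `tau_angle`. B2: the overall shape is preserved
#' but the CH1 C_Loop1 deviation is prominent (peak and ratio both at
#' threshold). B3: neither -- only local CDR changes.
#'
#' @param average_abs_change Average hinge-angle magnitude change, degrees.
#' @param loop_signal List with `peak` and `ratio` (see [c_loop1_signal()]).
#' @param thresholds A [class_thresholds()].
#' @return `"B1"`, `"B2"` or `"B3"`.
#' @export
classify_couple <- function(average_abs_change, loop_signal,
                            thresholds = class_thresholds()) {
  stopifnot(is.finite(average_abs_change))
  if (average_abs_change >= thresholds$tau_angle) return("B1")
  if (loop_signal$peak >= thresholds$tau_loop_peak &&
      loop_signal$ratio >= thresholds$tau_loop_ratio) return("B2")
  "B3"
}

#' Region-by-chain RMSD table under a whole-Fab overlap
#'
#' Superposes the entire bound Fab (both chains' backbone atoms jointly) onto
#' the free Fab, then evaluates the RMSD of every region of every chain under
#' that single transform; the individual regions are not separately
#' optimised. Per-chain whole-chain fits are reported alongside, since
#' whole-chain deviation profiles use per-chain overlap.
#'
#' @param free,bound Lists with elements `heavy` and `light` (`fab_chain`).
#' @param scheme A [region_scheme()].
#' @param atom_set Backbone atom names.
#' @return Data frame with columns `chain`, `region`, `rmsd` (regions
#'   `entire`, `variable`, `linker`, `constant` under the whole-Fab fit) plus
#'   attribute `chain_fit_rmsd` (per-chain whole-chain fitted RMSDs).
#' @export
rmsd_table <- function(free, bound, scheme = region_scheme(),
                       atom_set = backbone_atoms) {
  ent <- scheme$entire
  mh <- matched_backbone(free$heavy, bound$heavy, ent, atom_set)
  ml <- matched_backbone(free$light, bound$light, ent, atom_set)
  fit <- superpose_fit(rbind(mh$b, ml$b), rbind(mh$a, ml$a), scope = "whole-Fab")

  cells <- expand.grid(chain = c("heavy", "light"),
                       region = c("entire", "variable", "linker", "constant"),
                       stringsAsFactors = FALSE)
  cells$rmsd <- NA_real_
  for (k in seq_len(nrow(cells))) {
    mb <- if (cells$chain[k] == "heavy") mh else ml
    sp <- scheme[[cells$region[k]]]
    sel <- mb$seq_index >= sp[1] & mb$seq_index <= sp[2]
    if (!any(sel)) next
    cells$rmsd[k] <- rmsd_raw(apply_transform(mb$b[sel, , drop = FALSE], fit),
                              mb$a[sel, , drop = FALSE])
  }
  structure(cells,
            chain_fit_rmsd = c(
              heavy = fit_scope(free$heavy, bound$heavy, ent, "whole-chain", atom_set)$rmsd,
              light = fit_scope(free$light, bound$light, ent, "whole-chain", atom_set)$rmsd),
            fab_fit_rmsd = fit$rmsd)
}

rmsd_cell <- function(tab, chain, region) {
  tab$rmsd[tab$chain == chain & tab$region == region]
}

#' Tally RMSD trends across couples
#'
#' Counts, over a set of couple reports, how many couples satisfy each
#' inequality among the whole-chain and domain RMSDs under the whole-Fab
#' overlap: heavy versus light chain, CL versus VL, and CH versus VH. Exact
#' ties are tallied as `none`.
#'
#' @param reports List of couple reports (see [analyze_fab_couple()]).
#' @return Data frame with columns `comparison`, `greater`, `less`, `none`.
#' @export
trend_summary <- function(reports) {
  if (length(reports) == 0) spec_error("need at least one report")
  cnt <- function(a, b) {
    g <- sum(a > b); l <- sum(a < b); data.frame(greater = g, less = l,
                                                 none = length(a) - g - l)
  }
  g <- function(chain, region) vapply(reports, function(r)
    rmsd_cell(r$rmsd_table, chain, region), numeric(1))
  rbind(
    cbind(comparison = "heavy_vs_light", cnt(g("heavy", "entire"), g("light", "entire"))),
    cbind(comparison = "CL_vs_VL", cnt(g("light", "constant"), g("light", "variable"))),
    cbind(comparison = "CH_vs_VH", cnt(g("heavy", "constant"), g("heavy", "variable")))
  )
}
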