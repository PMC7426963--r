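#' Region scheme for a Fab chain
#'
#' Sequential-numbering boundaries of the variable domain, the inter-domain
#' linker (elbow), and the constant domain of a Fab chain. Defaults follow the
#' convention used throughout the analysis: variable 1-105, linker 106-113,
#' constant 114-218, entire chain 1-218. Residues beyond the entire span are
#' treated as tail and excluded from all metrics.
#'
#' @param variable,linker,constant,entire Integer vectors `c(start, end)`
#'   (inclusive, sequential numbering).
#' @return An object of class `region_scheme`.
#' @export
region_scheme <- function(variable = c(1L, 105L), linker = c(106L, 113L),
                          constant = c(114L, 218L), entire = c(1L, 218L)) {
  sp <- list(variable = as.integer(variable), linker = as.integer(linker),
             constant = as.integer(constant), entire = as.integer(entire))
  for (nm in names(sp)) {
    if (length(sp[[nm]]) != 2 || any(sp[[nm]] < 1) || sp[[nm]][1] > sp[[nm]][2])
      span_error(sprintf("invalid %s span", nm))
  }
  if (sp$variable[2] >= sp$linker[1] || sp$linker[2] >= sp$constant[1])
    span_error("variable/linker/constant spans must be disjoint and ordered")
  if (sp$entire[1] > sp$variable[1] || sp$entire[2] < sp$constant[2])
    span_error("entire span must contain the three region spans")
  structure(sp, class = "region_scheme")
}

span_seq <- function(span) seq.int(span[1], span[2])

#' Assign every residue of a chain to a region
#'
#' Partitions a chain into variable / linker / constant under a region scheme.
#' Residues past the end of the entire span are flagged `"tail"` and excluded
#' from downstream metrics.
#'
#' @param chain A `fab_chain`.
#' @param scheme A [region_scheme()].
#' @return Character vector (one element per residue, names = seq_index) with
#'   values `"variable"`, `"linker"`, `"constant"` or `"tail"`.
#' @export
assign_regions <- function(chain, scheme = region_scheme()) {
  n <- nrow(chain$residues)
  if (n < scheme$linker[2])
    span_error(sprintf("chain has %d residues; scheme requires at least %d",
                       n, scheme$linker[2]))
  idx <- chain$residues$seq_index
  out <- rep("tail", n)
  out[idx >= scheme$variable[1] & idx <= scheme$variable[2]] <- "variable"
  out[idx >= scheme$linker[1] & idx <= scheme$linker[2]] <- "linker"
  out[idx >= scheme$constant[1] & idx <= scheme$constant[2]] <- "constant"
  names(out) <- idx
  out
}

#' Default CDR and constant-loop boundary tables
#'
#' Kabat CDR definitions mapped through an identity offset onto sequential
#' numbering, and the default constant-domain loop windows. Both are plain
#' defaults, overridable per analysis; every report records the spans
#' actually used.
#'
#' @return Per-chain-type list of three named integer spans.
#' @export
default_cdr_table <- function() {
  list(
    heavy        = list(CDR1 = c(31L, 35L), CDR2 = c(50L, 65L), CDR3 = c(95L, 102L)),
    light_kappa  = list(CDR1 = c(24L, 34L), CDR2 = c(50L, 56L), CDR3 = c(89L, 97L)),
    light_lambda = list(CDR1 = c(24L, 34L), CDR2 = c(50L, 56L), CDR3 = c(89L, 97L))
  )
}

#' @rdname default_cdr_table
#' @export
default_c_loop_table <- function() {
  list(
    heavy        = list(C_Loop1 = c(131L, 141L), C_Loop2 = c(157L, 166L), C_Loop3 = c(186L, 196L)),
    light_kappa  = list(C_Loop1 = c(134L, 144L), C_Loop2 = c(158L, 167L), C_Loop3 = c(187L, 197L)),
    light_lambda = list(C_Loop1 = c(134L, 144L), C_Loop2 = c(158L, 167L), C_Loop3 = c(187L, 197L))
  )
}

validate_loop_spans <- function(spans, container, what) {
  if (length(spans) != 3) span_error(sprintf("%s table must define three spans", what))
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2 || sp[1] > sp[2]) span_error(sprintf("invalid %s span %s", what, nm))
    if (sp[1] < container[1] || sp[2] > container[2])
      span_error(sprintf("%s span %s (%d-%d) outside %d-%d",
                         what, nm, sp[1], sp[2], container[1], container[2]))
  }
  starts <- vapply(spans, `[`, integer(1), 1)
  ends <- vapply(spans, `[`, integer(1), 2)
  if (any(diff(order(starts)) != 1) || any(starts[-1] <= ends[-3]))
    span_error(sprintf("%s spans must be disjoint and N- to C-terminal ordered", what))
  lapply(spans, as.integer)
}

#' Annotate CDR spans on the variable domain
#'
#' Looks up the three complementarity-determining-region windows for the
#' chain's type and validates that they fall inside the variable domain in
#' ascending, disjoint order.
#'
#' @param chain A `fab_chain`.
#' @param scheme A [region_scheme()].
#' @param boundary_table Per-chain-type list of `CDR1`/`CDR2`/`CDR3` spans;
#'   defaults to the canonical Kabat definitions.
#' @return Named list of three integer spans.
#' @export
annotate_cdrs <- function(chain, scheme = region_scheme(),
                          boundary_table = default_cdr_table()) {
  spans <- boundary_table[[chain$chain_type]]
  if (is.null(spans)) span_error(sprintf("no CDR table for chain type '%s'", chain$chain_type))
  validate_loop_spans(spans, scheme$variable, "CDR")
}

#' Annotate constant-domain loop spans (C_Loop1-3)
#'
#' As [annotate_cdrs()], but the three loop windows must lie inside the
#' constant domain. C_Loop1 of the heavy chain (CH1) is the candidate carrier
#' of the allosteric signal scored by [c_loop1_signal()].
#'
#' @inheritParams annotate_cdrs
#' @param loop_table Per-chain-type list of `C_Loop1`/`C_Loop2`/`C_Loop3`
#'   spans.
#' @return Named list of three integer spans.
#' @export
annotate_c_loops <- function(chain, scheme = region_scheme(),
                             loop_table = default_c_loop_table()) {
  spans <- loop_table[[chain$chain_type]]
  if (is.null(spans)) span_error(sprintf("no C_Loop table for chain type '%s'", chain$chain_type))
  validate_loop_spans(spans, scheme$constant, "C_Loop")
}

#' Full region annotation for one chain
#'
#' Bundles the region partition, CDR spans and C_Loop spans used everywhere
#' downstream.
#'
#' @inheritParams annotate_cdrs
#' @param c_loop_table Per-chain-type constant-loop windows.
#' @return An object of class `region_annotation`: list with `scheme`,
#'   `regions` (per-residue labels), `cdr_spans`, `c_loop_spans`,
#'   `chain_type`.
#' @export
annotate_chain <- function(chain, scheme = region_scheme(),
                           boundary_table = default_cdr_table(),
                           c_loop_table = default_c_loop_table()) {
  structure(list(
    scheme = scheme,
    regions = assign_regions(chain, scheme),
    cdr_spans = annotate_cdrs(chain, scheme, boundary_table),
    c_loop_spans = annotate_c_loops(chain, scheme, c_loop_table),
    chain_type = chain$chain_type
  ), class = "region_annotation")
}
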