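#' Analyse one free/bound Fab couple
#'
#' Runs the full comparison for a couple of Fabs already loaded as chains:
#' sequence pairing check (100 percent identity required), region and loop
#' annotation, conserved-anchor angles and distances in both forms, the
#' whole-Fab region RMSD table, per-residue deviation profiles under
#' whole-chain and per-domain overlap, the CH1 C_Loop1 signal, and the final
#' B1/B2/B3 class.
#'
#' @param free,bound Lists with `heavy` and `light` `fab_chain` objects.
#' @param couple_id Label, conventionally `"FREE/BOUND"`.
#' @param scheme A [region_scheme()].
#' @param cdr_table,c_loop_table Boundary tables (see [annotate_cdrs()],
#'   [annotate_c_loops()]).
#' @param thresholds A [class_thresholds()].
#' @param anchor_overrides Optional list with `heavy` and `light` override
#'   lists for [find_anchors()].
#' @param keep_profiles Keep the full RMSF profiles on the report (default
#'   `TRUE`).
#' @return An object of class `couple_report`; see the package vignette for
#'   the field-by-field description.
#' @export
analyze_fab_couple <- function(free, bound, couple_id = "FREE/BOUND",
                               scheme = region_scheme(),
                               cdr_table = default_cdr_table(),
                               c_loop_table = default_c_loop_table(),
                               thresholds = class_thresholds(),
                               anchor_overrides = NULL,
                               keep_profiles = TRUE) {
  for (ch in c("heavy", "light")) {
    idy <- sequence_identity(free[[ch]], bound[[ch]])
    if (idy < 1)
      pairing_error(sprintf("%s: %s chains of free and bound forms share %.1f%% identity; 100%% required",
                            couple_id, ch, 100 * idy))
  }

  ann <- list(heavy = annotate_chain(free$heavy, scheme, cdr_table, c_loop_table),
              light = annotate_chain(free$light, scheme, cdr_table, c_loop_table))

  m_free <- fab_angle_metrics(free$heavy, free$light, ann$heavy, ann$light,
                              anchor_overrides$heavy, anchor_overrides$light)
  m_bound <- fab_angle_metrics(bound$heavy, bound$light, ann$heavy, ann$light,
                               anchor_overrides$heavy, anchor_overrides$light)
  ac <- angle_change(m_free, m_bound)

  tab <- rmsd_table(free, bound, scheme)

  scopes <- list(`whole-chain` = NULL, variable = scheme$variable,
                 constant = scheme$constant)
  profiles <- list()
  summaries <- list()
  for (ch in c("heavy", "light")) {
    for (sc in names(scopes)) {
      p <- rmsf_profile(free[[ch]], bound[[ch]], span = scopes[[sc]], scope = sc,
                        couple_id = couple_id, chain_id = ch)
      profiles[[paste(ch, sc, sep = ".")]] <- p
      summaries[[paste(ch, sc, sep = ".")]] <-
        list(fit_rmsd = attr(p, "fit_rmsd"),
             mean = mean(p$rmsf, na.rm = TRUE), max = max(p$rmsf, na.rm = TRUE))
    }
  }
  loop_sig <- c_loop1_signal(profiles[["heavy.constant"]],
                             ann$heavy$c_loop_spans)

  label <- classify_couple(ac$average_abs_change, loop_sig, thresholds)

  dropped <- vapply(profiles, function(p) attr(p, "fit")$n_dropped, numeric(1))
  rep <- structure(list(
    couple_id = couple_id,
    class_label = label,
    angle_metrics_free = m_free,
    angle_metrics_bound = m_bound,
    angle_change = ac,
    rmsd_table = tab,
    rmsf_summaries = summaries,
    c_loop1_signal = loop_sig,
    thresholds_used = thresholds,
    provenance = list(
      scheme = unclass(scheme),
      cdr_spans = ann$heavy$cdr_spans,
      cdr_spans_light = ann$light$cdr_spans,
      c_loop_spans = ann$heavy$c_loop_spans,
      c_loop_spans_light = ann$light$c_loop_spans,
      anchors = list(
        heavy = vapply(m_free$anchors_heavy[c("v_cys", "linker", "c_cys")],
                       function(a) a$seq_index, integer(1)),
        light = vapply(m_free$anchors_light[c("v_cys", "linker", "c_cys")],
                       function(a) a$seq_index, integer(1))),
      anchor_atoms = list(
        heavy = vapply(m_free$anchors_heavy[c("v_cys", "linker", "c_cys")],
                       function(a) a$atom, character(1)),
        light = vapply(m_free$anchors_light[c("v_cys", "linker", "c_cys")],
                       function(a) a$atom, character(1))),
      dropped_atoms = dropped)
  ), class = "couple_report")
  if (keep_profiles) rep$profiles <- profiles
  rep
}

#' @export
print.couple_report <- function(x, ...) {
  cat(sprintf("<couple_report> %s  class %s\n", x$couple_id, x$class_label))
  cat(sprintf("  hinge-angle change: heavy %+.1f deg, light %+.1f deg, average |change| %.1f deg\n",
              x$angle_change$delta_heavy, x$angle_change$delta_light,
              x$angle_change$average_abs_change))
  cat(sprintf("  C_Loop1 (CH1 overlap): peak %.2f A, baseline %.2f A, ratio %.2f\n",
              x$c_loop1_signal$peak, x$c_loop1_signal$baseline,
              x$c_loop1_signal$ratio))
  cat(sprintf("  whole-Fab RMSD %.2f A (heavy %.2f, light %.2f under per-chain overlap)\n",
              attr(x$rmsd_table, "fab_fit_rmsd"),
              attr(x$rmsd_table, "chain_fit_rmsd")[["heavy"]],
              attr(x$rmsd_table, "chain_fit_rmsd")[["light"]]))
  invisible(x)
}

#' Re-derive the class label from a stored report
#'
#' The decision is reproducible from the stored metrics and thresholds alone;
#' this also accepts a report deserialised from JSON.
#'
#' @param report A `couple_report` or the list form read back from JSON.
#' @return `"B1"`, `"B2"` or `"B3"`.
#' @export
classify_report <- function(report) {
  th <- report$thresholds_used
  classify_couple(report$angle_change$average_abs_change,
                  report$c_loop1_signal,
                  class_thresholds(th$tau_angle, th$tau_loop_peak, th$tau_loop_ratio))
}

#' Serialise a couple report to JSON
#'
#' Profiles are written separately (see [profiles_to_csv()]); everything else,
#' including thresholds, spans and anchor indices, is embedded so the class
#' label can be re-derived from the file alone.
#'
#' @param report A `couple_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  strip <- report
  strip$profiles <- NULL
  strip$angle_metrics_free[c("anchors_heavy", "anchors_light")] <-
    lapply(strip$angle_metrics_free[c("anchors_heavy", "anchors_light")],
           function(a) a[c("v_cys", "linker", "c_cys")])
  strip$angle_metrics_bound[c("anchors_heavy", "anchors_light")] <-
    lapply(strip$angle_metrics_bound[c("anchors_heavy", "anchors_light")],
           function(a) a[c("v_cys", "linker", "c_cys")])
  jsonlite::write_json(lapply(strip, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration listing the couples to analyse and
#' any overrides of the region scheme, CDR / C_Loop tables and thresholds.
#'
#' @param path Configuration file path.
#' @return List with `couples` and resolved `scheme`, `cdr_table`,
#'   `c_loop_table`, `thresholds`, `output_dir`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$couples) || length(cfg$couples) == 0)
    spec_error("config lists no couples")
  scheme <- if (is.null(cfg$region_scheme)) region_scheme() else
    do.call(region_scheme, cfg$region_scheme)
  th <- if (is.null(cfg$thresholds)) class_thresholds() else
    do.call(class_thresholds, cfg$thresholds)
  list(couples = cfg$couples, scheme = scheme,
       cdr_table = if (is.null(cfg$cdr_table)) default_cdr_table() else cfg$cdr_table,
       c_loop_table = if (is.null(cfg$c_loop_table)) default_c_loop_table() else cfg$c_loop_table,
       thresholds = th,
       output_dir = cfg$output_dir)
}

#' Analyse one configured couple from files
#'
#' Reads the free and bound PDB files, enforces the resolution filter and
#' chain continuity, extracts the configured chains (optionally windowed to
#' one Fab copy, which is logged), and runs [analyze_fab_couple()].
#'
#' @param entry List with `free`, `bound` (paths), `heavy_chain_id`,
#'   `light_chain_id`, `chain_type_light` (default `"light_kappa"`), and
#'   optional `span_free_heavy` / `span_free_light` / `span_bound_heavy` /
#'   `span_bound_light` residue windows and `anchor_overrides`.
#' @param scheme,cdr_table,c_loop_table,thresholds As in
#'   [analyze_fab_couple()].
#' @param max_resolution Resolution cutoff in Angstrom.
#' @return A `couple_report`.
#' @export
run_couple <- function(entry, scheme = region_scheme(),
                       cdr_table = default_cdr_table(),
                       c_loop_table = default_c_loop_table(),
                       thresholds = class_thresholds(),
                       max_resolution = 3.0) {
  light_type <- if (is.null(entry$chain_type_light)) "light_kappa" else entry$chain_type_light
  load_form <- function(path, tag) {
    rec <- read_structure(path)
    v <- check_resolution(rec, max_resolution)
    if (!v$pass)
      fab_abort("resolution_error",
                sprintf("%s: resolution %.2f A exceeds the %.1f A cutoff",
                        rec$entry_id, v$resolution, max_resolution))
    if (v$warning)
      message(sprintf("%s: no resolution recorded; accepted with warning", rec$entry_id))
    list(heavy = extract_chain(rec, entry$heavy_chain_id, "heavy",
                               entry[[paste0("span_", tag, "_heavy")]]),
         light = extract_chain(rec, entry$light_chain_id, light_type,
                               entry[[paste0("span_", tag, "_light")]]),
         entry_id = rec$entry_id)
  }
  free <- load_form(entry$free, "free")
  bound <- load_form(entry$bound, "bound")
  analyze_fab_couple(free[c("heavy", "light")], bound[c("heavy", "light")],
                     couple_id = paste0(free$entry_id, "/", bound$entry_id),
                     scheme = scheme, cdr_table = cdr_table,
                     c_loop_table = c_loop_table, thresholds = thresholds,
                     anchor_overrides = entry$anchor_overrides)
}

#' Run a batch of couples
#'
#' Analyses every configured couple, collecting one summary row per couple
#' (angle changes, class, C_Loop1 signal, key RMSD cells). Failures are
#' reported per couple without aborting the batch. When `output_dir` is set,
#' the summary CSV, per-couple JSON reports, RMSF profile CSVs and the trend
#' tallies are written there.
#'
#' @param config A list as returned by [load_run_config()], or a path to a
#'   config file.
#' @return List with `summary` (data frame, config order), `trends`
#'   (see [trend_summary()]), `reports`, and `failures` (named list of error
#'   messages).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  reports <- list()
  failures <- list()
  rows <- list()
  for (k in seq_along(config$couples)) {
    entry <- config$couples[[k]]
    cid <- if (!is.null(entry$id)) entry$id else
      paste0(basename(as.character(entry$free)), "/", basename(as.character(entry$bound)))
    res <- tryCatch(
      run_couple(entry, config$scheme, config$cdr_table, config$c_loop_table,
                 config$thresholds),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[cid]] <- conditionMessage(res)
      next
    }
    reports[[res$couple_id]] <- res
    rows[[res$couple_id]] <- data.frame(
      couple_id = res$couple_id,
      delta_heavy_deg = res$angle_change$delta_heavy,
      delta_light_deg = res$angle_change$delta_light,
      average_abs_change_deg = res$angle_change$average_abs_change,
      class = res$class_label,
      c_loop1_peak_A = res$c_loop1_signal$peak,
      c_loop1_ratio = res$c_loop1_signal$ratio,
      rmsd_heavy_entire_A = rmsd_cell(res$rmsd_table, "heavy", "entire"),
      rmsd_light_entire_A = rmsd_cell(res$rmsd_table, "light", "entire"),
      delta_linker_linker_A = res$angle_change$delta_linker_linker,
      stringsAsFactors = FALSE)
  }
  if (length(reports) == 0 && length(failures) > 0)
    fab_abort("batch_error", paste("all couples failed:",
                                   paste(names(failures), collapse = ", ")))
  out <- list(summary = do.call(rbind, rows), trends = trend_summary(reports),
              reports = reports, failures = failures)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$trends, file.path(config$output_dir, "trends.csv"),
                     row.names = FALSE)
    for (cid in names(reports)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", cid)
      report_to_json(reports[[cid]], file.path(config$output_dir, paste0(safe, ".json")))
      profiles_to_csv(reports[[cid]]$profiles,
                      file.path(config$output_dir, paste0(safe, "_rmsf.csv")))
    }
  }
  out
}

#' Fetch a PDB entry from the RCSB
#'
#' Network convenience only; every analysis and test in the package runs on
#' local files. Downloads are cached in `destdir`.
#'
#' @param accession 4-character PDB code.
#' @param destdir Cache directory.
#' @return Path to the downloaded (or cached) file.
#' @export
pdb_fetch <- function(accession, destdir = tempdir()) {
  accession <- toupper(accession)
  if (!grepl("^[0-9][A-Z0-9]{3}$", accession))
    spec_error(sprintf("'%s' is not a well-formed PDB accession", accession))
  dest <- file.path(destdir, paste0(accession, ".pdb"))
  if (!file.exists(dest)) {
    dir.create(destdir, showWarnings = FALSE, recursive = TRUE)
    utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb", accession),
                         dest, quiet = TRUE, mode = "wb")
  }
  dest
}
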