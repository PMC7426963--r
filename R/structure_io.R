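#' Parse a PDB-format structure
#'
#' Reads PDB-format text into a structure record holding the first model's
#' ATOM records. Heteroatoms and waters are dropped; where alternate locations
#' are present, only the highest-occupancy altloc is kept (ties broken
#' alphabetically, so altloc `A` wins). The crystallographic resolution is
#' taken from the `REMARK 2` header when present.
#'
#' @param pdb_text Character vector (one element per line, or a single string
#'   with embedded newlines) of PDB-format text.
#' @param entry_id Label for the entry, typically the 4-character PDB code.
#' @return An object of class `fab_structure`: a list with `entry_id`,
#'   `resolution` (Angstrom, `NA` if not recorded), `model_index` (always 1)
#'   and `atom`, a data frame of atom records (bio3d column layout).
#' @export
parse_structure <- function(pdb_text, entry_id = "XXXX") {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  if (!any(grepl("^ATOM  ", lines)))
    parse_error(sprintf("no ATOM records found in '%s'", entry_id))

  resolution <- NA_real_
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem) > 0) {
    m <- regmatches(rem[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s+ANGSTROM)", rem[1], perl = TRUE))
    if (length(m) == 1) resolution <- as.numeric(m)
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- tryCatch(
    bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE),
    error = function(e) parse_error(sprintf("malformed PDB text in '%s': %s",
                                            entry_id, conditionMessage(e)))
  )
  atom <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$resid != "HOH", , drop = FALSE]
  if (nrow(atom) == 0) parse_error(sprintf("no usable ATOM records in '%s'", entry_id))
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)))
    parse_error(sprintf("malformed coordinates in '%s'", entry_id))

  # altloc: keep highest occupancy per (chain, residue, atom name); tie -> 'A'
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "|")
  ord <- order(match(key, unique(key)), -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(paste(atom$chain, atom$resno,
                                 ifelse(is.na(atom$insert), "", atom$insert),
                                 atom$elety, sep = "|")), , drop = FALSE]
  # restore file order
  atom <- atom[order(atom$eleno), , drop = FALSE]
  rownames(atom) <- NULL

  if (!is.na(resolution) && resolution <= 0)
    parse_error(sprintf("non-positive resolution in '%s'", entry_id))

  structure(list(entry_id = entry_id, resolution = resolution,
                 model_index = 1L, atom = atom),
            class = "fab_structure")
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB-format file.
#' @param entry_id Entry label; defaults to the file name without extension.
#' @return A `fab_structure`; see [parse_structure()].
#' @export
read_structure <- function(path, entry_id = NULL) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  if (is.null(entry_id))
    entry_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
  parse_structure(readLines(path, warn = FALSE), entry_id = entry_id)
}

#' Resolution filter
#'
#' Checks an entry against the resolution cutoff used for structure selection
#' (better than about 3 Angstrom). Entries with no recorded resolution pass
#' with a warning flag, since the header may simply be absent.
#'
#' @param record A `fab_structure`.
#' @param max_resolution Cutoff in Angstrom (default 3.0).
#' @return A list with `pass` (logical), `resolution` (numeric, possibly `NA`)
#'   and `warning` (logical; `TRUE` when resolution was absent).
#' @export
check_resolution <- function(record, max_resolution = 3.0) {
  res <- record$resolution
  if (is.na(res)) {
    return(list(pass = TRUE, resolution = NA_real_, warning = TRUE))
  }
  list(pass = res <= max_resolution, resolution = res, warning = FALSE)
}

#' Chain IDs present in a structure
#' @param record A `fab_structure`.
#' @return Character vector of chain identifiers.
#' @export
structure_chains <- function(record) unique(record$atom$chain)

# peptide-bond continuity cutoff: bonded C-N is ~1.33 A, broken chains are
# well above 2.5 A
.continuity_cutoff <- 2.5

#' Extract and renumber one antibody chain
#'
#' Pulls a single chain out of a parsed structure, orders residues as authored
#' (respecting insertion codes), optionally restricts to a residue window, and
#' renumbers sequentially 1..n. Residues missing any of the N, CA, C backbone
#' atoms are dropped with a warning. The chain must be continuous: every
#' C(i)-N(i+1) distance must be below 2.5 Angstrom, mirroring the exclusion of
#' structures whose deposited chains are broken.
#'
#' @param record A `fab_structure`.
#' @param chain_id Chain identifier within the record.
#' @param chain_type One of `"heavy"`, `"light_kappa"`, `"light_lambda"`.
#' @param span Optional integer vector of residue positions (1-based, in
#'   author order) retained before renumbering; used to select one Fab copy
#'   when the asymmetric unit carries several.
#' @return An object of class `fab_chain`: a list with `chain_id`,
#'   `chain_type`, `source_entry`, `residues` (data frame: `seq_index`,
#'   `author_number`, `aa`) and `atoms` (data frame: `seq_index`, `elety`,
#'   `x`, `y`, `z`).
#' @export
extract_chain <- function(record, chain_id, chain_type = "heavy", span = NULL) {
  chain_type <- match.arg(chain_type, c("heavy", "light_kappa", "light_lambda"))
  atom <- record$atom[record$atom$chain %in% chain_id, , drop = FALSE]
  if (nrow(atom) == 0)
    missing_chain_error(sprintf("chain '%s' not found in '%s'", chain_id, record$entry_id))

  ins <- ifelse(is.na(atom$insert), "", atom$insert)
  rkey <- paste0(atom$resno, ins)
  keys <- unique(rkey)                      # author order
  if (!is.null(span)) {
    span <- as.integer(span)
    if (any(span < 1 | span > length(keys)))
      span_error(sprintf("span outside 1..%d for chain '%s'", length(keys), chain_id))
    keys <- keys[sort(unique(span))]
  }

  res_list <- vector("list", length(keys))
  keep <- logical(length(keys))
  for (i in seq_along(keys)) {
    sub <- atom[rkey == keys[i], , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% sub$elety)) next
    keep[i] <- TRUE
    res_list[[i]] <- sub
  }
  if (any(!keep))
    warning(sprintf("chain '%s': dropped %d residue(s) missing N/CA/C backbone atoms",
                    chain_id, sum(!keep)))
  res_list <- res_list[keep]
  keys <- keys[keep]
  n <- length(keys)
  if (n == 0) missing_chain_error(sprintf("chain '%s' has no complete residues", chain_id))

  residues <- data.frame(
    seq_index = seq_len(n),
    author_number = keys,
    aa = vapply(res_list, function(s) {
      a <- suppressWarnings(bio3d::aa321(s$resid[1]))
      if (is.na(a) || !a %in% LETTERS) "X" else a
    }, character(1)),
    stringsAsFactors = FALSE
  )
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- res_list[[i]]
    data.frame(seq_index = i, elety = s$elety, x = s$x, y = s$y, z = s$z,
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL

  chain <- structure(list(chain_id = chain_id, chain_type = chain_type,
                          source_entry = record$entry_id,
                          residues = residues, atoms = atoms),
                     class = "fab_chain")
  gaps <- chain_gaps(chain)
  if (nrow(gaps) > 0)
    discontinuity_error(
      sprintf("chain '%s' in '%s' is discontinuous at %d position(s) (first break after residue %d, C-N distance %.2f A)",
              chain_id, record$entry_id, nrow(gaps), gaps$seq_index[1], gaps$distance[1]),
      gaps = gaps)
  chain
}

# C(i)-N(i+1) distances above the continuity cutoff
chain_gaps <- function(chain) {
  n <- nrow(chain$residues)
  if (n < 2) return(data.frame(seq_index = integer(), distance = numeric()))
  cc <- atom_coords(chain, "C")
  nn <- atom_coords(chain, "N")
  d <- sqrt(rowSums((cc[-n, , drop = FALSE] - nn[-1, , drop = FALSE])^2))
  bad <- which(d > .continuity_cutoff)
  data.frame(seq_index = bad, distance = d[bad])
}

# n x 3 matrix of one named atom per residue (NA rows where absent)
atom_coords <- function(chain, elety) {
  n <- nrow(chain$residues)
  out <- matrix(NA_real_, n, 3)
  sel <- chain$atoms[chain$atoms$elety == elety, , drop = FALSE]
  out[sel$seq_index, ] <- as.matrix(sel[, c("x", "y", "z")])
  out
}

#' One-letter sequence of a chain
#' @param chain A `fab_chain`.
#' @return Single string of one-letter codes.
#' @export
chain_sequence <- function(chain) paste(chain$residues$aa, collapse = "")

#' Percent identity between two chain sequences
#'
#' Global alignment with match score 1 and zero mismatch/gap scores, used only
#' to compute the fraction of identical aligned positions. The pipeline
#' requires 1.0 (100 percent identity) for a valid free/bound couple.
#'
#' @param a,b `fab_chain` objects (or plain sequence strings).
#' @return Fraction in `[0, 1]`: identical columns / aligned columns.
#' @export
sequence_identity <- function(a, b) {
  sa <- if (inherits(a, "fab_chain")) chain_sequence(a) else as.character(a)
  sb <- if (inherits(b, "fab_chain")) chain_sequence(b) else as.character(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) shape_error("empty sequence")
  x <- strsplit(sa, "")[[1]]
  y <- strsplit(sb, "")[[1]]
  n <- length(x); m <- length(y)
  # Needleman-Wunsch on match count (mismatch/gap score 0); traceback prefers
  # the diagonal so optimal alignments take the shortest form.
  S <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    match_row <- as.integer(x[i] == y)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + match_row[j], S[i, j + 1], S[i + 1, j])
    }
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  cols <- cols + i + j
  matches / cols
}

#' Write a prepared chain as a minimal PDB file
#'
#' Residues are written with their sequential numbering, preserving all stored
#' atoms to standard PDB coordinate precision (0.001 Angstrom).
#'
#' @param chain A `fab_chain`.
#' @param path Output file path.
#' @param chain_id Single-character chain ID to write (defaults to the first
#'   character of the stored ID).
#' @return Invisibly, `path`.
#' @export
write_chain_pdb <- function(chain, path, chain_id = NULL) {
  if (is.null(chain_id)) chain_id <- substr(as.character(chain$chain_id)[1], 1, 1)
  at <- chain$atoms
  resid3 <- vapply(chain$residues$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r)) "UNK" else r
  }, character(1))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = chain$residues$seq_index[at$seq_index],
                   resid = resid3[at$seq_index],
                   eleno = seq_len(nrow(at)),
                   elety = at$elety,
                   chain = rep(chain_id, nrow(at)),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' @export
print.fab_chain <- function(x, ...) {
  cat(sprintf("<fab_chain> %s chain '%s' from %s: %d residues, %d atoms\n",
              x$chain_type, x$chain_id, x$source_entry,
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' @export
print.fab_structure <- function(x, ...) {
  cat(sprintf("<fab_structure> %s: chains %s; resolution %s A\n",
              x$entry_id, paste(structure_chains(x), collapse = ","),
              ifelse(is.na(x$resolution), "n/a", format(x$resolution))))
  invisible(x)
}
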