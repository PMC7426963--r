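# Shared fixtures and independent oracles, all built in code.

pdb_atom_line <- function(serial, name, resn, chain, resno, xyz,
                          icode = " ", alt = " ", occ = 1.0) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt, resn,
          chain, resno, icode, xyz[1], xyz[2], xyz[3], occ, 0.0,
          substr(name, 1, 1))
}

# continuous zig-zag backbone: residue i spans x in [3i, 3i+2]; C(i)-N(i+1)
# distance ~1.25 A
toy_backbone_xyz <- function(i) {
  list(N = c(3 * i, 0, 0), CA = c(3 * i + 1, 0.6, 0),
       C = c(3 * i + 2, 0, 0.3), O = c(3 * i + 2, -0.7, 1.2))
}

toy_pdb_text <- function(n = 3, chain = "A", resns = NULL, resnos = NULL,
                         icodes = NULL, resolution = NULL, skip = integer(0)) {
  if (is.null(resns)) resns <- rep("ALA", n)
  if (is.null(resnos)) resnos <- seq_len(n)
  if (is.null(icodes)) icodes <- rep(" ", n)
  lines <- character(0)
  if (!is.null(resolution))
    lines <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution)
  serial <- 0L
  for (i in seq_len(n)) {
    if (i %in% skip) next
    at <- toy_backbone_xyz(i)
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, nm, resns[i], chain, resnos[i],
                                      at[[nm]], icode = icodes[i]))
    }
  }
  c(lines, "END")
}

# stub chain bypassing file parsing, for annotation/geometry tests
stub_chain <- function(aa, chain_type = "heavy", chain_id = "A") {
  n <- length(aa)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    at <- toy_backbone_xyz(i)
    data.frame(seq_index = i, elety = c("N", "CA", "C", "O"),
               x = c(at$N[1], at$CA[1], at$C[1], at$O[1]),
               y = c(at$N[2], at$CA[2], at$C[2], at$O[2]),
               z = c(at$N[3], at$CA[3], at$C[3], at$O[3]),
               stringsAsFactors = FALSE)
  }))
  structure(list(chain_id = chain_id, chain_type = chain_type,
                 source_entry = "STUB",
                 residues = data.frame(seq_index = seq_len(n),
                                       author_number = as.character(seq_len(n)),
                                       aa = aa, stringsAsFactors = FALSE),
                 atoms = atoms),
            class = "fab_chain")
}

# ---- independent oracles -------------------------------------------------

# double-loop evaluation of the per-atom mean-square deviation
oracle_rmsd <- function(a, b) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    for (k in 1:3) total <- total + (a[i, k] - b[i, k])^2
  }
  as.numeric(sqrt(total / nrow(a)))
}

# exhaustive alignment enumeration: maximum matches, then minimum aligned
# columns among maximal alignments (tiny sequences only)
oracle_identity <- function(sa, sb) {
  x <- strsplit(sa, "")[[1]]; y <- strsplit(sb, "")[[1]]
  best <- new.env(); best$m <- -1L; best$cols <- Inf
  rec <- function(i, j, m, cols) {
    if (i > length(x) && j > length(y)) {
      if (m > best$m || (m == best$m && cols < best$cols)) {
        best$m <- m; best$cols <- cols
      }
      return(invisible())
    }
    if (i <= length(x) && j <= length(y))
      rec(i + 1, j + 1, m + (x[i] == y[j]), cols + 1)
    if (i <= length(x)) rec(i + 1, j, m, cols + 1)
    if (j <= length(y)) rec(i, j + 1, m, cols + 1)
  }
  rec(1L, 1L, 0L, 0L)
  best$m / best$cols
}

# Euler-angle rotation matrix, used only by the grid-search oracle
oracle_rotmat <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

# coarse-to-fine exhaustive rotation search (final step 1 degree); both sets
# are centred, translation handled by centroid alignment
oracle_grid_rmsd <- function(mobile, ref) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(ref, 2, colMeans(ref))
  eval_rmsd <- function(R) sqrt(mean(rowSums((m %*% t(R) - r)^2)))
  best <- c(0, 0, 0); best_val <- Inf
  steps <- c(9, 3, 1) * pi / 180
  half <- c(pi, 9 * pi / 180, 3 * pi / 180)
  for (lvl in 1:3) {
    gr_a <- seq(best[1] - half[lvl], best[1] + half[lvl], by = steps[lvl])
    gr_b <- seq(max(0, best[2] - half[lvl]), min(pi, best[2] + half[lvl]), by = steps[lvl])
    gr_c <- seq(best[3] - half[lvl], best[3] + half[lvl], by = steps[lvl])
    for (a in gr_a) for (b in gr_b) for (cc in gr_c) {
      v <- eval_rmsd(oracle_rotmat(a, b, cc))
      if (v < best_val) { best_val <- v; best <- c(a, b, cc) }
    }
  }
  best_val
}

# angle at vertex B between BA and BC, via the cosine rule
oracle_angle <- function(A, B, C) {
  ab <- sqrt(sum((A - B)^2)); cb <- sqrt(sum((C - B)^2)); ac <- sqrt(sum((A - C)^2))
  acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
}

random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 360)
  t <- ang * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  list(R = diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K), t = rnorm(3, sd = 10))
}

transform_chain <- function(chain, rigid) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")]) %*% t(rigid$R) +
    matrix(rigid$t, nrow(chain$atoms), 3, byrow = TRUE)
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]; chain$atoms$z <- xyz[, 3]
  chain
}

# quick components for classification without the full report
measure_couple <- function(cp) {
  sch <- synthetic_region_scheme(cp$spec)
  annH <- annotate_chain(cp$free$heavy, sch)
  annL <- annotate_chain(cp$free$light, sch)
  ac <- angle_change(
    fab_angle_metrics(cp$free$heavy, cp$free$light, annH, annL),
    fab_angle_metrics(cp$bound$heavy, cp$bound$light, annH, annL))
  p <- rmsf_profile(cp$free$heavy, cp$bound$heavy, span = sch$constant,
                    scope = "constant")
  list(angle_change = ac, loop = c_loop1_signal(p, annH$c_loop_spans))
}
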