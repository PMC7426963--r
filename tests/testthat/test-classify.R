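test_that("the class decision rule follows the angle-then-loop cascade", {
  th <- class_thresholds()
  expect_equal(classify_couple(37, list(peak = 0.1, ratio = 1.0), th), "B1")
  expect_equal(classify_couple(2, list(peak = 2.5, ratio = 6), th), "B2")
  expect_equal(classify_couple(3, list(peak = 0.3, ratio = 1.1), th), "B3")
  # peak and ratio must both clear their thresholds for B2
  expect_equal(classify_couple(3, list(peak = 2.5, ratio = 1.5), th), "B3")
  expect_equal(classify_couple(3, list(peak = 1.0, ratio = 6), th), "B3")
  expect_error(class_thresholds(tau_angle = -1), class = "spec_error")
})

test_that("classification is monotone in its inputs", {
  th <- class_thresholds()
  rank <- c(B3 = 1, B2 = 2, B1 = 3)
  angles <- c(0, 5, 9.99, 10, 25, 40)
  peaks <- c(0.2, 1.4, 1.6, 3)
  ratios <- c(0.8, 1.9, 2.1, 8)
  for (p in peaks) for (r in ratios) {
    labs <- rank[vapply(angles, function(a)
      classify_couple(a, list(peak = p, ratio = r), th), character(1))]
    expect_true(all(diff(labs) >= 0))        # raising angle never demotes
  }
  for (a in angles) for (r in ratios) {
    labs <- rank[vapply(peaks, function(p)
      classify_couple(a, list(peak = p, ratio = r), th), character(1))]
    expect_true(all(diff(labs) >= 0))        # raising peak never demotes
  }
})

test_that("identical Fabs give an all-zero RMSD table", {
  fab <- build_free_fab(synthetic_spec(noise_sigma = 0, seed = 14))
  tab <- rmsd_table(fab, fab)
  expect_true(all(tab$rmsd < 1e-9))
})

test_that("a hinged couple shows larger constant- than variable-domain RMSD", {
  cp <- synthetic_couple(synthetic_spec(hinge_angle_heavy = 25, hinge_angle_light = 25,
                                        seed = 15))
  tab <- rmsd_table(cp$free, cp$bound)
  for (ch in c("heavy", "light"))
    expect_gt(rmsd_cell(tab, ch, "constant"), rmsd_cell(tab, ch, "variable"))
})

test_that("every table cell matches a brute-force evaluation under the joint fit", {
  rec <- parse_structure(toy_pdb_text(218), "TOYBIG")
  heavy <- extract_chain(rec, "A", "heavy")
  light <- extract_chain(rec, "A", "light_kappa")
  set.seed(16)
  jiggle <- function(ch, sd) {
    ch$atoms$x <- ch$atoms$x + rnorm(nrow(ch$atoms), sd = sd)
    ch$atoms$y <- ch$atoms$y + rnorm(nrow(ch$atoms), sd = sd)
    ch$atoms$z <- ch$atoms$z + rnorm(nrow(ch$atoms), sd = sd)
    ch
  }
  free <- list(heavy = heavy, light = jiggle(light, 0.05))
  bound <- list(heavy = jiggle(heavy, 0.3), light = jiggle(light, 0.4))
  sch <- region_scheme()
  tab <- rmsd_table(free, bound, sch)

  mh <- matched_backbone(free$heavy, bound$heavy, sch$entire)
  ml <- matched_backbone(free$light, bound$light, sch$entire)
  fit <- superpose_fit(rbind(mh$b, ml$b), rbind(mh$a, ml$a))
  for (k in seq_len(nrow(tab))) {
    mb <- if (tab$chain[k] == "heavy") mh else ml
    sp <- sch[[tab$region[k]]]
    sel <- mb$seq_index >= sp[1] & mb$seq_index <= sp[2]
    expect_equal(tab$rmsd[k],
                 oracle_rmsd(apply_transform(mb$b[sel, ], fit), mb$a[sel, ]),
                 tolerance = 1e-12, info = paste(tab$chain[k], tab$region[k]))
  }
})

test_that("trend tallies count inequalities with ties as none", {
  cp <- synthetic_couple(synthetic_spec(hinge_angle_heavy = 25, hinge_angle_light = 10,
                                        seed = 17))
  r <- analyze_fab_couple(cp$free, cp$bound, "S1")
  tr <- trend_summary(list(r))
  expect_equal(tr$greater[tr$comparison == "heavy_vs_light"], 1)

  # a hand-made tied report lands in the none column
  tied <- r
  tied$rmsd_table$rmsd <- 1.0
  tr2 <- trend_summary(list(tied))
  expect_equal(tr2$none, c(1, 1, 1))
})

test_that("eight constructed couples reproduce the observed trend pattern", {
  hinged <- list(c(30, 15), c(30, 15), c(4, 2), c(4, 2), c(4, 2))
  reports <- list()
  for (k in seq_along(hinged)) {
    cp <- synthetic_couple(synthetic_spec(
      hinge_angle_heavy = hinged[[k]][1], hinge_angle_light = hinged[[k]][2],
      c_loop1_displacement = 2, cdr_displacement = 1, seed = 500 + k))
    reports[[k]] <- analyze_fab_couple(cp$free, cp$bound, paste0("H", k),
                                       keep_profiles = FALSE)
  }
  # two couples whose binding moves the heavy C_Loop1 strongly plus the light
  # CDRs, leaving both constant-domain hinges closed
  for (k in 6:7) {
    cp <- synthetic_couple(synthetic_spec(c_loop1_displacement = 6, seed = 500 + k))
    sch <- synthetic_region_scheme(cp$spec)
    for (sp in default_cdr_table()[["light_kappa"]])
      cp$bound$light <- fabshift:::apply_displacement(cp$bound$light, sp, 2.5,
                                                      sch$variable)
    reports[[k]] <- analyze_fab_couple(cp$free, cp$bound, paste0("C", k),
                                       keep_profiles = FALSE)
  }
  # one CDR-only couple
  cp <- synthetic_couple(canonical_couple_spec("B3", seed = 508))
  reports[[8]] <- analyze_fab_couple(cp$free, cp$bound, "B3", keep_profiles = FALSE)

  tr <- trend_summary(reports)
  expect_equal(tr$greater[tr$comparison == "heavy_vs_light"], 8)
  expect_equal(tr$greater[tr$comparison == "CL_vs_VL"], 5)
  expect_equal(tr$less[tr$comparison == "CL_vs_VL"], 3)
  expect_equal(tr$greater[tr$comparison == "CH_vs_VH"], 7)
  expect_equal(tr$less[tr$comparison == "CH_vs_VH"], 1)
})
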