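make_anchor_set <- function(v, a, c, type = "heavy") {
  structure(list(v_cys = list(seq_index = 1L, aa = "C", atom = "SG", xyz = v),
                 linker = list(seq_index = 2L, aa = "S", atom = "OG", xyz = a),
                 c_cys = list(seq_index = 3L, aa = "C", atom = "SG", xyz = c),
                 chain_type = type),
            class = "anchor_set")
}

test_that("planted anchors are found at their planted positions", {
  spec <- synthetic_spec(noise_sigma = 0, seed = 1,
                         anchor_plan = list(v_cys = 92L, linker = 108L, c_cys = 140L))
  fab <- build_free_fab(spec)
  ann <- annotate_chain(fab$heavy, synthetic_region_scheme(spec))
  anc <- find_anchors(fab$heavy, ann)
  expect_equal(anc$v_cys$seq_index, 92L)
  expect_equal(anc$linker$seq_index, 108L)
  expect_equal(anc$c_cys$seq_index, 140L)
  expect_equal(anc$v_cys$atom, "SG")
  expect_equal(anc$linker$atom, "OG")     # serine side-chain anchor
})

test_that("anchor search fails informatively and validates overrides", {
  aa <- rep("A", 218)
  aa[92] <- "C"; aa[140] <- "C"           # kappa chain but no Arg in linker
  ch <- stub_chain(aa, "light_kappa")
  ann <- annotate_chain(ch)
  expect_error(find_anchors(ch, ann), class = "anchor_not_found_error")

  aa[108] <- "R"
  ch2 <- stub_chain(aa, "light_kappa")
  withCallingHandlers(
    anc <- find_anchors(ch2, annotate_chain(ch2)),
    warning = function(w) {
      expect_match(conditionMessage(w), "falling back to CA")
      invokeRestart("muffleWarning")
    })
  expect_equal(anc$linker$seq_index, 108L)
  expect_equal(anc$linker$atom, "CA")     # stub has no CZ: CA fallback

  expect_error(find_anchors(ch2, annotate_chain(ch2),
                            overrides = list(v_cys = 50L)),
               class = "anchor_identity_error")
})

test_that("default cysteine picks are last-in-variable and first-in-constant", {
  aa <- rep("A", 218)
  aa[c(22, 92)] <- "C"; aa[c(140, 200)] <- "C"; aa[108] <- "S"
  ch <- stub_chain(aa, "heavy")
  anc <- suppressWarnings(find_anchors(ch, annotate_chain(ch)))
  expect_equal(anc$v_cys$seq_index, 92L)
  expect_equal(anc$c_cys$seq_index, 140L)
})

test_that("hinge angle matches vector algebra, including degenerate layouts", {
  expect_equal(hinge_angle(make_anchor_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 180)
  expect_equal(hinge_angle(make_anchor_set(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))), 90)
  set.seed(7)
  for (k in 1:20) {
    v <- rnorm(3, sd = 10); a <- rnorm(3, sd = 10); c <- rnorm(3, sd = 10)
    expect_equal(hinge_angle(make_anchor_set(v, a, c)), oracle_angle(v, a, c),
                 tolerance = 1e-9)
  }
  expect_error(hinge_angle(make_anchor_set(c(1, 1, 1), c(1, 1, 1), c(0, 1, 0))),
               class = "degenerate_error")
})

test_that("hinge angle is invariant under a global rigid transform", {
  set.seed(11)
  v <- rnorm(3, sd = 10); a <- rnorm(3, sd = 10); c <- rnorm(3, sd = 10)
  base <- hinge_angle(make_anchor_set(v, a, c))
  for (k in 1:5) {
    rg <- random_rigid()
    mv <- function(x) as.numeric(rg$R %*% x + rg$t)
    expect_equal(hinge_angle(make_anchor_set(mv(v), mv(a), mv(c))), base,
                 tolerance = 1e-9)
  }
})

test_that("anchor distances are Euclidean norms", {
  h <- make_anchor_set(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3))
  l <- make_anchor_set(c(5, 0, 0), c(2, 1, 1), c(9, 9, 9), type = "light_kappa")
  d <- anchor_distances(h, l)
  expect_equal(d$cys_cys_heavy, sqrt(27))      # (3,3,3) apart on each axis
  expect_equal(d$linker_linker, 1)
  set.seed(13)
  p <- rnorm(3); q <- rnorm(3)
  d2 <- anchor_distances(make_anchor_set(p, c(9, 9, 9), q),
                         make_anchor_set(p + 1, c(0, 0, 0), q + 1))
  expect_equal(d2$cys_cys_heavy, sqrt(sum((p - q)^2)))
})

test_that("angle changes are signed, averaged as magnitudes, and antisymmetric", {
  mk <- function(hv, lt) {
    structure(list(heavy_angle = hv, light_angle = lt,
                   cys_cys_heavy = 30, cys_cys_light = 31, linker_linker = 14,
                   anchors_heavy = make_anchor_set(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
                   anchors_light = make_anchor_set(c(0, 0, 1), c(1, 0, 1), c(2, 1, 1))),
              class = "angle_metrics")
  }
  ac <- angle_change(mk(120, 110), mk(110, 120))
  expect_equal(ac$delta_heavy, -10)
  expect_equal(ac$delta_light, 10)
  expect_equal(ac$average_abs_change, 10)

  z <- angle_change(mk(120, 110), mk(120, 110))
  expect_equal(z$average_abs_change, 0)

  fwd <- angle_change(mk(120, 110), mk(100, 125))
  rev <- angle_change(mk(100, 125), mk(120, 110))
  expect_equal(rev$delta_heavy, -fwd$delta_heavy)
  expect_equal(rev$delta_light, -fwd$delta_light)
  expect_equal(rev$average_abs_change, fwd$average_abs_change)

  bad <- mk(100, 125)
  bad$anchors_heavy$v_cys$seq_index <- 99L
  expect_error(angle_change(mk(120, 110), bad), class = "anchor_mismatch_error")
})

test_that("an applied hinge rotation is recovered as the measured angle change", {
  spec <- synthetic_spec(hinge_angle_heavy = 15, noise_sigma = 0.1, seed = 21)
  cp <- synthetic_couple(spec)
  sch <- synthetic_region_scheme(spec)
  annH <- annotate_chain(cp$free$heavy, sch)
  annL <- annotate_chain(cp$free$light, sch)
  ac <- angle_change(
    fab_angle_metrics(cp$free$heavy, cp$free$light, annH, annL),
    fab_angle_metrics(cp$bound$heavy, cp$bound$light, annH, annL))
  expect_equal(ac$delta_heavy, -15, tolerance = 1 / 15)   # heavy angle closes
  expect_equal(abs(ac$delta_light), 0, tolerance = 1)     # light untouched
  expect_equal(ac$average_abs_change, 7.5, tolerance = 1 / 7.5)
})
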