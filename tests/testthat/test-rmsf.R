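test_that("identical chains give an all-zero profile under any scope", {
  fab <- build_free_fab(synthetic_spec(noise_sigma = 0, seed = 2))
  sch <- region_scheme()
  for (span in list(NULL, sch$variable, sch$constant)) {
    p <- rmsf_profile(fab$heavy, fab$heavy, span)
    expect_true(all(p$rmsf < 1e-9, na.rm = TRUE))
  }
})

test_that("per-residue values match a brute-force per-residue evaluation", {
  rec_a <- parse_structure(toy_pdb_text(4), "TOYA")
  a <- extract_chain(rec_a, "A")
  b <- a
  b$atoms$x <- b$atoms$x + c(rep(0, 8), rep(0.9, 4), rep(0, 4))  # residue 3 shifted
  b$atoms$y <- b$atoms$y + 0.2
  p <- rmsf_profile(a, b, span = NULL)
  fit <- attr(p, "fit")
  for (i in 1:4) {
    sel_a <- a$atoms[a$atoms$seq_index == i, c("x", "y", "z")]
    sel_b <- b$atoms[b$atoms$seq_index == i, c("x", "y", "z")]
    moved <- apply_transform(as.matrix(sel_b), fit)
    expect_equal(p$rmsf[p$seq_index == i],
                 as.numeric(oracle_rmsd(moved, as.matrix(sel_a))),
                 tolerance = 1e-12)
  }
})

test_that("atom-weighted RMS of the profile reproduces the scope RMSD exactly", {
  for (cl in c("B1", "B2", "B3")) {
    cp <- synthetic_couple(canonical_couple_spec(cl, seed = 6))
    sch <- synthetic_region_scheme(cp$spec)
    for (ch in c("heavy", "light")) {
      for (span in list(NULL, sch$variable, sch$constant)) {
        p <- rmsf_profile(cp$free[[ch]], cp$bound[[ch]], span)
        rms <- sqrt(sum(p$n_atoms * p$rmsf^2, na.rm = TRUE) / sum(p$n_atoms))
        expect_equal(rms, attr(p, "fit_rmsd"), tolerance = 1e-9)
      }
    }
  }
})

test_that("a single displaced loop peaks at its displacement under whole-chain overlap", {
  spec <- synthetic_spec(c_loop1_displacement = 3, noise_sigma = 0.05, seed = 8)
  cp <- synthetic_couple(spec)
  p <- rmsf_profile(cp$free$heavy, cp$bound$heavy, span = NULL)
  sm <- region_summary(p, cp$truth$c_loop1_span)
  expect_gt(sm$max, 2.5)
  expect_lt(sm$max, 3.5)
  expect_true(sm$argmax >= cp$truth$c_loop1_span[1] &&
                sm$argmax <= cp$truth$c_loop1_span[2])
  # remainder of the chain stays near-rigid
  out <- p$rmsf[p$seq_index < cp$truth$c_loop1_span[1] - 2 |
                  p$seq_index > cp$truth$c_loop1_span[2] + 2]
  expect_lt(stats::median(out, na.rm = TRUE), 0.5)
})

test_that("profiles are invariant to rigid pre-transforms of either input", {
  cp <- synthetic_couple(canonical_couple_spec("B1", seed = 10))
  p0 <- rmsf_profile(cp$free$heavy, cp$bound$heavy, span = NULL)
  set.seed(99)
  p1 <- rmsf_profile(transform_chain(cp$free$heavy, random_rigid()),
                     transform_chain(cp$bound$heavy, random_rigid()), span = NULL)
  expect_equal(p1$rmsf, p0$rmsf, tolerance = 1e-8)
})

test_that("per-domain overlap flattens rigid domains relative to whole-chain overlap", {
  spec <- synthetic_spec(hinge_angle_heavy = 25, hinge_angle_light = 25,
                         noise_sigma = 0.1, seed = 4)
  cp <- synthetic_couple(spec)
  sch <- synthetic_region_scheme(spec)
  for (ch in c("heavy", "light")) {
    whole <- rmsf_profile(cp$free[[ch]], cp$bound[[ch]], span = NULL)
    for (dom in list(sch$variable, sch$constant)) {
      dm <- rmsf_profile(cp$free[[ch]], cp$bound[[ch]], dom)
      in_dom <- whole$seq_index >= dom[1] & whole$seq_index <= dom[2]
      expect_lt(mean(dm$rmsf, na.rm = TRUE),
                mean(whole$rmsf[in_dom], na.rm = TRUE))
    }
  }
})

test_that("region summaries and the loop signal handle flat, spiked and empty spans", {
  prof <- structure(
    data.frame(seq_index = 114:218, aa = "A", n_atoms = 4L, rmsf = 1.0),
    class = c("rmsf_profile", "data.frame"), scope = "constant")
  expect_equal(region_summary(prof, c(120, 130)), list(mean = 1, max = 1, argmax = 120))

  prof$rmsf[prof$seq_index == 135] <- 5
  sm <- region_summary(prof, c(131, 141))
  expect_equal(sm$max, 5)
  expect_equal(sm$argmax, 135)
  expect_error(region_summary(prof, c(300, 310)), class = "empty_span_error")

  loops <- default_c_loop_table()$heavy
  flat <- prof; flat$rmsf <- 0.2
  sig <- c_loop1_signal(flat, loops)
  expect_equal(sig$ratio, 1.0)
  expect_equal(sig$peak, 0.2)

  spiked <- c_loop1_signal(prof, loops)    # 5 A spike at 135 inside C_Loop1
  expect_equal(spiked$peak, 5)
  expect_equal(spiked$ratio, 5)
})

test_that("missing residues are marked NA, never zero", {
  rec <- parse_structure(toy_pdb_text(6), "TOY6")
  a <- extract_chain(rec, "A")
  b <- a
  b$atoms <- b$atoms[b$atoms$seq_index != 4, ]   # residue 4 absent in bound
  p <- rmsf_profile(a, b, span = NULL)
  expect_true(is.na(p$rmsf[p$seq_index == 4]))
  expect_true(all(!is.na(p$rmsf[p$seq_index != 4])))
})
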