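test_that("exact and saturated linear fits behave as OLS dictates", {
  # noiseless no-intercept line is recovered exactly
  rec <- substitution_records(as.character(1:6), 1:6,
                              delta_s = c(-9, -4, -1, 2, 5, 8))
  rec$observed_delta <- 0.2 * rec$delta_s
  m <- fit_field_model(rec, use_intercept = FALSE)
  expect_equal(m$slope, 0.2, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-12)

  # two points + intercept: perfect fit, zero residual df, warned rsd 0
  rec2 <- substitution_records(c("a", "b"), 1:2, delta_s = c(-1, 3),
                               observed_delta = c(0.5, 2.1))
  expect_warning(m2 <- fit_field_model(rec2, use_intercept = TRUE),
                 "saturated")
  expect_equal(m2$residual_sd, 0)
  expect_equal(m2$n_used, 2L)

  # degenerate design and insufficient data are refused
  rec3 <- substitution_records(c("a", "b", "c"), 1:3, delta_s = c(2, 2, 2),
                               observed_delta = c(1, 2, 3))
  expect_error(fit_field_model(rec3), "zero variance")
  expect_error(fit_field_model(rec2[1, ]), "at least 2")
})

test_that("OLS matches the closed-form normal equations to 1e-10", {
  d <- make_linear_dataset(n_sites = 30, slope = -0.4, intercept = 1.2,
                           noise_sd = 0.8, seed = 5)
  for (ic in c(TRUE, FALSE)) {
    m <- fit_field_model(d, use_intercept = ic)
    o <- ols_direct(d$delta_s, d$observed_delta, intercept = ic)
    expect_equal(m$slope, o$slope, tolerance = 1e-10)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(m$residual_sd, o$residual_sd, tolerance = 1e-10)
  }
})

test_that("simulated slope/noise are recovered within sampling error", {
  d <- make_linear_dataset(n_sites = 50, slope = 0.15, intercept = 0.5,
                           noise_sd = 1.0, seed = 42)
  m <- fit_field_model(d, use_intercept = TRUE)
  se <- summary(m$fit)$coefficients["delta_s", "Std. Error"]
  expect_lt(abs(m$slope - 0.15), 3 * se)
  expect_gt(m$residual_sd, 0.7)
  expect_lt(m$residual_sd, 1.3)
})

test_that("predictions fill every record and satisfy the OLS identity", {
  d <- make_linear_dataset(n_sites = 40, slope = 0.3, intercept = -0.5,
                           noise_sd = 0.6, seed = 9)
  m <- fit_field_model(d)
  out <- predict_substituent_effects(m, d)
  expect_true(all(is.finite(out$predicted_delta)))
  expect_equal(out$predicted_delta, m$slope * d$delta_s + m$intercept)

  # RMS of training residuals equals residual_sd * sqrt((n-p)/n)
  r <- out$observed_delta - out$predicted_delta
  n <- nrow(d); p <- 2
  expect_equal(sqrt(mean(r^2)), m$residual_sd * sqrt((n - p) / n),
               tolerance = 1e-10)

  # slope 0 edge: all predictions equal the intercept
  m0 <- m; m0$slope <- 0; m0$intercept <- 1.7
  expect_true(all(predict_substituent_effects(m0, d)$predicted_delta == 1.7))

  # serialization round trip
  p1 <- withr::local_tempfile(fileext = ".json")
  write_field_model(m, p1)
  back <- read_field_model(p1)
  expect_equal(back$slope, m$slope, tolerance = 1e-12)
  expect_equal(back$residual_sd, m$residual_sd, tolerance = 1e-12)
  expect_identical(back$n_used, m$n_used)
})

test_that("near-reaction flags follow the distance cutoff and gate fitting", {
  # H1 is bonded to the "reacting" carbon, H2 is remote
  mol <- molecule(c("C", "H", "C", "H"),
                  rbind(c(0, 0, 0), c(1.09, 0, 0),
                        c(8, 0, 0), c(9.09, 0, 0)))
  rec <- substitution_records(c("1", "2"), c(2L, 4L), delta_s = c(-2, 3),
                              observed_delta = c(-1, 1))
  out <- flag_near_reaction_sites(rec, mol, reacting_atoms = 1, cutoff = 3.0)
  expect_identical(out$near_reaction, c(TRUE, FALSE))
  expect_identical(flag_near_reaction_sites(rec, mol, 1, cutoff = 0)$near_reaction,
                   c(FALSE, FALSE))
  expect_identical(flag_near_reaction_sites(rec, mol, 1, cutoff = 1e6)$near_reaction,
                   c(TRUE, TRUE))

  # flagged sites are excluded from fitting by default, like explicit labels
  d <- make_linear_dataset(n_sites = 20, seed = 13)
  d$near_reaction[c(3, 11)] <- TRUE
  m_flag <- fit_field_model(d)
  m_manual <- fit_field_model(d[-c(3, 11), ])
  expect_equal(m_flag$slope, m_manual$slope, tolerance = 1e-12)
  expect_equal(m_flag$n_used, 18L)

  # label exclusion equals fitting the manually filtered subset
  m_excl <- fit_field_model(d, exclude = c("3", "11"))
  expect_equal(m_excl$slope, m_manual$slope, tolerance = 1e-12)
  expect_identical(m_excl$excluded_labels, c("3", "11"))
})

test_that("site ranking derives its sign from the single-charge identity", {
  vals <- data.frame(site_label = c("A", "B", "C"), site_index = c(1L, 2L, 3L),
                     delta_s = c(-5, 2, 0), kind = "bond_directed")
  # Delta for a q=-1 substituent is +delta_s: most negative delta_s lowers most
  expect_identical(rank_sites(vals, "lower"), c("A", "C", "B"))
  expect_identical(rank_sites(vals, "raise"), rev(rank_sites(vals, "lower")))
  # a positive substituent reverses the preference
  expect_identical(rank_sites(vals, "lower", substituent_charge = 1),
                   c("B", "C", "A"))
  # ties break by ascending site index
  tied <- data.frame(site_label = c("x", "y", "z"), site_index = c(3L, 1L, 2L),
                     delta_s = c(1, 1, 1), kind = "bond_directed")
  expect_identical(rank_sites(tied, "lower"), c("y", "z", "x"))
  # surface probes are refused
  surf <- vals; surf$kind <- "surface"
  expect_error(rank_sites(surf), "bond-directed")

  # consistency with the field itself: ranking agrees with directly computed
  # barrier changes for a -1 e charge at each probe
  pair <- make_proton_shift_pair()
  pr <- place_bond_probes(pair$substrate$mol, 1, distance = 1.0)
  pr <- rbind(pr, transform(pr, x = x + 2, site_index = 2L, site_label = "2"),
              transform(pr, y = y + 3, site_index = 3L, site_label = "3"))
  fv <- compute_catalytic_field(pair, pr)
  deltas <- vapply(seq_len(3), function(i)
    environment_barrier_change(pair, data.frame(x = fv$x[i], y = fv$y[i],
                                                z = fv$z[i], q = -1)),
    numeric(1))
  expect_identical(rank_sites(fv, "lower"),
                   fv$site_label[order(deltas, fv$site_index)])
})
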