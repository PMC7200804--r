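comp_cols <- c("f_neutral_lipid", "f_phospholipid", "f_water")

test_that("Poulin-Theil partition coefficient behaves structurally", {
  plasma <- c(f_neutral_lipid = 0.0023, f_phospholipid = 0.0013,
              f_water = 0.945)
  # tissue identical to plasma with fu_t = fu_p gives R = 1
  r <- poulin_theil_partition(3.3, 0.012, plasma, plasma, fu_t = 0.012)
  expect_equal(r$R_t, 1)
  # higher neutral-lipid fraction and a lipophilic drug raise R
  comp <- chronotac:::ref_table("tissue_composition")
  rownames(comp) <- comp$tissue
  r_fat <- poulin_theil_partition(3.3, 0.012, comp["adipose", comp_cols],
                                  comp["plasma", comp_cols], adipose = TRUE)
  r_kid <- poulin_theil_partition(3.3, 0.012, comp["kidney", comp_cols],
                                  comp["plasma", comp_cols])
  expect_gt(r_fat$R_t, r_kid$R_t)
  # R is linear in the fu_p/fu_t ratio
  a <- poulin_theil_partition(3.3, 0.012, comp["liver", comp_cols],
                              comp["plasma", comp_cols], fu_t = 0.02)
  b <- poulin_theil_partition(3.3, 0.012, comp["liver", comp_cols],
                              comp["plasma", comp_cols], fu_t = 0.01)
  expect_equal(b$R_t / a$R_t, 2, tolerance = 1e-12)
  # simultaneous rescaling of both compositions leaves R unchanged
  sc <- lapply(comp["liver", comp_cols], function(x) 0.5 * x)
  sp <- lapply(comp["plasma", comp_cols], function(x) 0.5 * x)
  r1 <- poulin_theil_partition(3.3, 0.012, comp["liver", comp_cols],
                               comp["plasma", comp_cols])
  r2 <- poulin_theil_partition(3.3, 0.012, sc, sp)
  expect_equal(r2$R_t, r1$R_t, tolerance = 1e-12)
  expect_error(poulin_theil_partition(3.3, 0.012,
                                      list(f_neutral_lipid = 0,
                                           f_phospholipid = 0, f_water = 0),
                                      comp["plasma", comp_cols]),
               "degenerate")
})

test_that("the gut-lumen loss constant scales linearly with LibT", {
  expect_equal(k_elib(100, 0.5), 0.5)
  expect_equal(k_elib(200, 0.5), 1.0)
  expect_equal(k_elib(276, 0.5), 2.76 * 0.5)
  expect_error(k_elib(0, 0.5), "positive")
})

test_that("red-blood-cell binding saturates as specified", {
  # half saturation at C_u = K_d with the fitted means
  bp <- blood_partition(1.6, B_max = 11.0, K_d = 1.6,
                        haematocrit = 0.35, fu_p = 0.012)
  expect_equal(bp$rbc_bound, 5.5)
  expect_equal(bp$plasma_total, 1.6 / 0.012)
  expect_equal(bp$whole_blood,
               0.65 * 1.6 / 0.012 + 0.35 * 5.5)
  # saturation limit
  bp_inf <- blood_partition(1e9, 11.0, 1.6, 0.35, 0.012)
  expect_equal(bp_inf$rbc_bound, 11.0, tolerance = 1e-6)
  expect_error(blood_partition(1, -1, 1.6, 0.35, 0.012))
})

test_that("physiology scales from the reference table", {
  ref <- chronotac:::ref_table("reference_physiology")
  adult <- subject("ad", "M", 35, 70, 170, 0.43)
  ph <- scale_physiology(adult)
  for (i in seq_len(nrow(ref)))
    expect_equal(ph$volumes[[ref$tissue[i]]], 70 * ref$volume_frac_bw[i])
  expect_equal(ph$cardiac_output, 336)
  expect_equal(ph$flows[["kidney"]], 0.19 * 336)
  # volumes are linear in body weight
  half <- scale_physiology(subject("h", "M", 35, 35, 170, 0.43))
  expect_equal(unname(half$volumes[names(half$volumes) != "others"]),
               unname(ph$volumes[names(ph$volumes) != "others"]) / 2)
  # cohort-mean subject: modelled volumes stay inside the body volume
  child <- subject("c", "F", 12.9, 42.85, 143.4, 0.35)
  phc <- scale_physiology(child)
  expect_lt(sum(phc$volumes), 42.85 / 1.05 + 1e-9)
  expect_true(all(phc$volumes > 0))
  expect_warning(scale_physiology(subject("i", "M", 1, 10, 75, 0.35)),
                 "age")
})

test_that("mass is conserved through the PBPK simulation", {
  s <- typical_subject()
  sim <- simulate_pbpk(s, pbpk_params(), seq(0, 72, 0.5))
  expect_lt(attr(sim, "ledger")["balance_rel_error"], 1e-6)
})

test_that("with no lumen loss and fast absorption everything is absorbed", {
  p <- pbpk_params(K_elib_ref = 1e-9, Kabs = 500,
                   circadian = circadian_profile(1, 0))
  s <- subject("f", "M", 12, 40, 140, 0.35,
               doses = data.frame(time = 0, amt = 2,
                                  formulation = "fast_release"))
  sim <- simulate_pbpk(s, p, c(0, 48))
  led <- attr(sim, "ledger")
  expect_equal(led[["absorbed"]] / led[["input"]], 1, tolerance = 1e-3)
})

test_that("zero dose gives zero everywhere", {
  s <- subject("g", "M", 12, 40, 140, 0.35)
  sim <- simulate_pbpk(s, pbpk_params(), c(0, 24))
  expect_true(all(sim$conc == 0))
  expect_true(all(is.na(sim$F)))
})

test_that("steady state under constant infusion balances elimination", {
  # one very long zero-order input with r_chr = 1: at late times the
  # hepatic elimination rate must equal the infusion rate
  p <- pbpk_params(circadian = circadian_profile(1, 0))
  p$LibT <- c(fast_release = 400 * 60, prolonged_release = 400 * 60)
  s <- subject("inf", "M", 12.9, 42.85, 143.4, 0.35,
               doses = data.frame(time = 0, amt = 400,  # 1 mg/h for 400 h
                                  formulation = "fast_release"))
  sim <- simulate_pbpk(s, p, c(0, 300, 320))
  st1 <- attr(simulate_pbpk(s, p, c(0, 300)), "states")
  st2 <- attr(sim, "states")
  elim_rate <- (st2[["eliminated"]] - st1[["eliminated"]]) / 20
  absorbed_rate <- (st2[["absorbed"]] - st1[["absorbed"]]) / 20
  expect_equal(elim_rate, absorbed_rate, tolerance = 0.01)
})

test_that("typical-subject bioavailability sits in the reported range", {
  # 2.5 mg q12h over the run-in and monitoring day at the fitted
  # population means; the cohort estimate was 15.0 +/- 1.6 %
  s <- typical_subject(doses_until = 60, amt = 2.5)
  sim <- simulate_pbpk(s, pbpk_params(), seq(0, 72, 0.5))
  Fend <- attr(sim, "ledger")[["F_end"]]
  expect_gt(Fend, 0.150 - 0.016)
  expect_lt(Fend, 0.150 + 0.016)
})

test_that("bioavailability accumulator tracks the ledger at late times", {
  s <- subject("h", "M", 12, 40, 140, 0.35,
               doses = data.frame(time = 0, amt = 2.5,
                                  formulation = "fast_release"))
  sim <- simulate_pbpk(s, pbpk_params(), c(0, 200))
  led <- attr(sim, "ledger")
  # all absorbed drug is eventually cleared by the liver
  expect_equal(led[["eliminated"]], led[["absorbed"]], tolerance = 0.01)
})

test_that("liberation time follows the formulation being dosed", {
  # prolonged release with a much longer LibT flattens the day-8 peak
  p <- pbpk_params(LibT = c(fast_release = 100, prolonged_release = 100))
  p2 <- pbpk_params(LibT = c(fast_release = 100, prolonged_release = 500))
  s <- protocol_subject()
  tms <- seq(215, 240, 0.25)
  c1 <- simulate_pbpk(s, p, c(0, tms))
  c2 <- simulate_pbpk(s, p2, c(0, tms))
  expect_lt(max(c2$conc[c2$time > 215]), max(c1$conc[c1$time > 215]))
})
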