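test_that("chamber elastance follows the activation profile", {
  # activation peak: E(t) = E_A; diastole: E(t) = E_B
  expect_equal(chamber_elastance(0.15, 300, 8, onset = 0, duration = 0.3),
               300)
  expect_equal(chamber_elastance(0.7, 300, 8, onset = 0, duration = 0.3), 8)
  # periodicity
  expect_equal(chamber_elastance(0.12, 300, 8),
               chamber_elastance(3.12, 300, 8))
  # integral over one period against a quadrature oracle
  num <- stats::integrate(function(t) chamber_elastance(t, 300, 8,
                                                        duration = 0.3),
                          0, 1, subdivisions = 1000L, rel.tol = 1e-10)$value
  analytic <- (300 - 8) * 0.3 / 2 + 8  # sin^2 pulse integrates to dur/2
  expect_equal(num, analytic, tolerance = 1e-8)
  expect_error(chamber_elastance(0.1, -5, 8), "non-negative")
  expect_error(chamber_elastance(-1, 300, 8), "non-negative")
})

test_that("nominal simulation is physiological, periodic, and conservative", {
  out <- nominal_run()
  expect_true(out$solver_ok)
  expect_true(out$converged)
  s <- out$summaries

  # pumping heart and diode valves
  expect_gt(s[["max(q_lv)"]], s[["min(q_lv)"]])
  expect_gt(s[["max(q_la)"]], s[["min(q_la)"]])
  expect_gt(s[["max(p_BR)"]], s[["min(p_BR)"]])
  for (v in c("v_trv", "v_puv", "v_miv", "v_aov")) {
    expect_true(all(out$waveforms[[v]] >= 0), info = v)
  }
  # arterial pressures positive
  expect_true(all(out$waveforms$p_BR > 0))
  expect_true(all(out$waveforms$p_MC > 0))

  # closed-loop volume conservation to well within 10x solver tolerance
  cfg <- cvs_sim_config()
  expect_lt(out$volume_drift, 10 * cfg$rtol)
  total <- rowSums(out$waveforms[, cvs_state_names()])
  expect_lt(max(abs(total - total[1])) / total[1], 10 * cfg$rtol)

  # periodicity of the final cycle
  y_start <- as.numeric(out$waveforms[1, cvs_state_names()])
  y_end <- as.numeric(out$waveforms[nrow(out$waveforms), cvs_state_names()])
  expect_lt(max(abs(y_end - y_start) / pmax(abs(y_start), 1e-12)),
            10 * cfg$periodicity_tol)
})

test_that("mean flows satisfy the resistive-network balance", {
  # oracle: with compartment means carrying no net capacitive flow over a
  # periodic cycle, the mean flows solve the pure resistance network
  # between the mean aortic and venous/atrial node pressures
  out <- nominal_run()
  wf <- out$waveforms
  pt <- cvs_parameters()
  v <- stats::setNames(pt$value, pt$name)
  mean_over <- function(x) cvscalib:::trapz_mean(wf$time, x)

  p_ao <- mean_over(wf$p_AO) / 1000  # MPa
  p_cer <- mean_over(wf$p_MC) / 1000
  p_vub <- mean_over(wf$p_vub) / 1000
  p_vlb <- mean_over(wf$p_vlb) / 1000

  beds <- c("LE", "BR", "AC", "EC", "MC", "PC", "TR")
  seg <- c(LE = v[["R_seg_LE"]], BR = v[["R_seg_BR"]], AC = 0, EC = 0,
           MC = 0, PC = 0, TR = v[["R_seg_TR"]])
  src <- c(LE = p_ao, BR = p_ao, AC = p_cer, EC = p_cer, MC = p_cer,
           PC = p_cer, TR = p_ao)
  ven <- c(LE = p_vlb, BR = p_vub, AC = p_vub, EC = p_vub, MC = p_vub,
           PC = p_vub, TR = p_vlb)
  for (b in beds) {
    chain_r <- seg[[b]] + v[[paste0("R_", b, "_T")]] + v[[paste0("R_", b, "_V")]]
    oracle_flow <- (src[[b]] - ven[[b]]) / chain_r
    sim_flow <- out$summaries[[paste0("mean(v_", b, "_T)")]]
    expect_equal(sim_flow, oracle_flow, tolerance = 5e-3,
                 info = paste("terminal", b))
  }

  # aortic valve mean outflow equals the summed terminal inflows
  co <- sum(out$summaries[paste0("mean(v_", beds, "_T)")])
  expect_equal(mean_over(wf$v_aov), co, tolerance = 5e-3)

  # and the overall pressure drop equals CO times the network resistance
  p_ra <- mean_over(wf$p_RA) / 1000
  r_total <- (p_ao - p_ra) / co
  expect_gt(r_total, 0)
  cond <- sum(1 / vapply(beds, function(b) {
    seg[[b]] + v[[paste0("R_", b, "_T")]] + v[[paste0("R_", b, "_V")]] +
      if (b %in% c("LE", "TR")) v[["R_ivc"]] else v[["R_svc"]]
  }, numeric(1)))
  # parallel-combination estimate ignores the shared venous nodes, so
  # agreement is approximate but must hold to ~10%
  expect_equal(r_total, 1 / cond, tolerance = 0.1)
})

test_that("raising a terminal resistance does not raise its bed's flow", {
  base <- nominal_run()$summaries[["mean(v_MC_T)"]]
  up <- simulate_cvs(c(R_MC_T = 4500 * 1.5))$summaries[["mean(v_MC_T)"]]
  expect_lt(up, base)
})

test_that("total stressed volume follows q_sbv", {
  out <- simulate_cvs(c(q_sbv = 1.2e-3))
  pt <- set_parameters(cvs_parameters(), c(q_sbv = 1.2e-3))
  v <- stats::setNames(pt$value, pt$name)
  q_un_tot <- v[["q_RA_un"]] + v[["q_RV_un"]] + v[["q_LA_un"]] + v[["q_LV_un"]]
  total <- sum(out$final_state)
  expect_equal(total, 1.2e-3 + q_un_tot, tolerance = 1e-8)
})

test_that("non-finite or negative parameters error; solver failure is a flag", {
  expect_error(simulate_cvs(c(E_LVa = NaN)), "non-finite")
  expect_error(simulate_cvs(c(E_LVa = -10)), "negative")
  # a wildly non-physiological but finite configuration that breaks the
  # integrator must come back as solver_ok = FALSE, not an exception
  out <- simulate_cvs(set_parameters(cvs_parameters(),
                                     c(k_valve = 1e6, R_aov = 0.05,
                                       C_AO = 0.002)),
                      cvs_sim_config(max_cycles = 3, rtol = 1e-13,
                                     atol = 1e-30))
  expect_type(out$solver_ok, "logical")
})

test_that("extract_observables applies max/min/mean over one period", {
  tm <- seq(0, 1, length.out = 501)
  wf <- tibble::tibble(time = tm, const = rep(3.5, 501),
                       wave = 2.0 + sin(2 * pi * tm))
  got <- extract_observables(wf, c("max(const)", "min(const)",
                                   "mean(const)", "mean(wave)"))
  expect_equal(unname(got[1:3]), rep(3.5, 3))
  expect_equal(got[["mean(wave)"]], 2.0, tolerance = 1e-10)
  expect_error(extract_observables(wf, "mean(nope)"), "valid variables")
  expect_error(extract_observables(wf, "median(wave)"), "malformed")

  # grid-refinement oracle: halved step changes the LV volume extrema
  # by less than the sampling error bound
  coarse <- nominal_run()
  fine <- simulate_cvs(cvs_parameters(),
                       cvs_sim_config(sample_hz = 1000),
                       init = coarse$final_state)
  for (nm in c("max(q_lv)", "min(q_lv)", "mean(p_BR)")) {
    expect_equal(coarse$summaries[[nm]], fine$summaries[[nm]],
                 tolerance = 1e-4, info = nm)
  }
})

test_that("the packaged topology is a single closed loop", {
  topo <- cvs_topology()
  expect_s3_class(topo, "cvs_topology")
  expect_setequal(
    topo$compartments$name[topo$compartments$kind == "terminal"],
    paste0(c("LE", "BR", "AC", "EC", "MC", "PC", "TR"), "_T"))
  # breaking the loop is caught
  broken <- topo
  broken$connections <- broken$connections[-1, ]
  expect_error(validate_topology(broken), "closed loop")
  # unknown compartment is caught
  bad <- topo
  bad$connections$to[1] <- "nowhere"
  expect_error(validate_topology(bad), "unknown compartment")
})

test_that("parameter table round-trips through CSV", {
  pt <- cvs_parameters()
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_csv(pt, path)
  back <- read_parameter_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(pt), tolerance = 1e-12)
  expect_error(set_parameters(pt, c(nope = 1)), "unknown parameter")
})
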