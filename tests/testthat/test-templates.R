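test_that("waiting times are exponential with the requested rate", {
  set.seed(1)
  w <- draw_waiting_times(1e5, lambda1 = 2)
  expect_length(w, 1e5)
  expect_true(all(w > 0))
  expect_equal(mean(w), 0.5, tolerance = 0.01)

  expect_length(draw_waiting_times(1, 3), 1)
  set.seed(42); a <- draw_waiting_times(5, 1)
  set.seed(42); b <- draw_waiting_times(5, 1)
  expect_identical(a, b)

  expect_error(draw_waiting_times(0, 1), "positive")
  expect_error(draw_waiting_times(5, -1), "positive")
})

test_that("establishment probability scenarios match their closed forms", {
  null <- toy_assembly(scenario = "null", max_events = 10L)
  expect_equal(establishment_probabilities(null), rep(1, 10))

  ed0 <- toy_assembly(scenario = "exp_decay", Es = 2, lambda2 = 0,
                      max_events = 10L)
  expect_equal(establishment_probabilities(ed0), rep(1, 10))

  ed <- toy_assembly(scenario = "exp_decay", Es = 1, lambda2 = log(2),
                     max_events = 50L)
  s <- establishment_probabilities(ed)
  expect_equal(s[1], 0.75)           # (1 + 1/2) / 2
  expect_true(all(diff(s) <= 0))     # decreasing towards Es / (1 + Es)
  expect_equal(s[50], 1 / 2, tolerance = 1e-10)
  expect_true(all(s > 0 & s <= 1))
})

test_that("hump probabilities are normalised, floored and peak in-horizon", {
  hp <- toy_assembly(scenario = "hump", a = -1, b = 0, c = 0, p = 5,
                     Hs = 0.25, Hm = 0.3, max_events = 40L)
  s <- establishment_probabilities(hp)
  expect_equal(which.max(s), 5)
  expect_equal(max(s), 1)            # (Hs + 1) / (1 + Hs) at the peak
  expect_true(all(s >= 0.3))         # the floor Hm binds far from the peak
  expect_true(all(s <= 1))

  flat <- toy_assembly(scenario = "hump", a = 0, b = 0, c = 1, max_events = 5L)
  expect_error(establishment_probabilities(flat), "degenerate")
})

test_that("waiting times are scaled by inverse establishment probability", {
  sched <- scale_waiting_times(c(1, 2, 3), c(1, 1, 1))
  expect_equal(sched$final_waits, c(1, 2, 3))

  expect_equal(scale_waiting_times(1, 0.25)$final_waits, 4)

  raw <- c(0.5, 1.5, 2)
  probs <- c(0.8, 0.4, 1)
  doubled <- scale_waiting_times(raw, probs / 2)
  expect_equal(doubled$final_waits, 2 * scale_waiting_times(raw, probs)$final_waits)

  expect_error(scale_waiting_times(c(1, 2), c(0.5)), "lengths")
  expect_error(scale_waiting_times(1, 0), "probabilities")
})

test_that("logistic growth has the right midpoint, bound and values", {
  expect_equal(logistic_abundance(5, Cs = 1000, k = 1, m = 5), 500)
  expect_equal(logistic_abundance(5 + log(3), Cs = 1000, k = 1, m = 5), 750)
  expect_equal(logistic_abundance(1e4, Cs = 1000, k = 1, m = 5), 1000)
  el <- seq(0, 20, by = 0.5)
  ab <- logistic_abundance(el, Cs = 80, k = 0.7, m = 6)
  expect_true(all(diff(ab) > 0) && all(ab < 80))
  expect_error(logistic_abundance(-1, 10, 1, 1), "non-negative")
})

test_that("template generation matches a step-by-step grid simulation", {
  set.seed(101)
  for (rep in 1:20) {
    params <- toy_assembly(Cs = runif(1, 30, 80), k = runif(1, 0.5, 2),
                           m = runif(1, 1, 4))
    params$Cg <- params$Cs * runif(1, 2, 5)
    waits <- rexp(50, rate = 1)
    got <- generate_template(params, final_waits = waits)
    want <- grid_template_oracle(waits, params, dt = 1e-3)
    expect_length(got, length(want))
    expect_equal(got, want, tolerance = 1e-2)
  }
})

test_that("templates stop exactly at the global capacity", {
  set.seed(7)
  for (preset in c("species_rich", "species_poor")) {
    params <- template_preset(preset)
    for (i in 1:5) {
      tpl <- generate_template(params)
      expect_true(all(tpl > 0))
      expect_gte(sum(tpl), params$Cg)
      expect_lt(sum(tpl) - tpl[length(tpl)], params$Cg)
      # older taxa have grown for longer, so earlier slots are larger
      expect_true(all(diff(tpl) <= 0))
    }
  }
})

test_that("a taxon saturating at Cs = Cg yields a one-to-two slot template", {
  set.seed(3)
  params <- toy_assembly(Cs = 100, Cg = 100, k = 10, m = 0.1, lambda1 = 0.2)
  counts <- replicate(20, length(generate_template(params)))
  expect_true(all(counts <= 2))
})

test_that("unreachable capacity raises a non-termination error", {
  params <- toy_assembly(Cs = 1, Cg = 1000, max_events = 20L)
  expect_error(generate_template(params), "not reached")
})

test_that("template banks are sized, seeded and serialisable", {
  params <- template_preset("species_poor")
  set.seed(5); bank1 <- generate_template_bank(10, params)
  set.seed(5); bank2 <- generate_template_bank(10, params)
  expect_length(bank1, 10)
  expect_identical(unclass(bank1)[], unclass(bank2)[])

  path <- tempfile(fileext = ".tsv")
  write_template_bank(bank1, path)
  back <- read_template_bank(path)
  expect_equal(lengths(back), lengths(bank1), ignore_attr = TRUE)
  expect_equal(unname(unlist(back)), unname(unlist(bank1)), tolerance = 1e-8)
})

test_that("presets reproduce the two microbiome regimes", {
  set.seed(11)
  rich <- generate_template_bank(30, template_preset("species_rich"))
  expect_true(all(lengths(rich) >= 200 & lengths(rich) <= 300))
  # graded abundances: prevalent to rare within one host
  ratios <- vapply(rich, function(t) max(t) / min(t), 1)
  expect_gt(median(ratios), 5)
  expect_true(all(ratios > 1.5))

  poor <- generate_template_bank(50, template_preset("species_poor"))
  expect_true(all(lengths(poor) <= 8))
  # the dominant symbiont holds the majority of the biomass on average
  expect_gt(mean(vapply(poor, function(t) max(t) / sum(t), 1)), 0.5)
})
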