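test_that("fitness is a presence/absence sum of contributions", {
  cv <- c(0.2, 0.7, 0.05)
  m <- microbiome(c(1L, 2L), c(1, 999))
  expect_equal(host_fitness(m, cv), 0.9)
  # abundances are dismissed entirely
  m10 <- microbiome(m$taxa, m$abundance * 10)
  expect_equal(host_fitness(m10, cv), host_fitness(m, cv))
  expect_equal(host_fitness(microbiome(integer(0), numeric(0)), cv), 0)
  expect_error(host_fitness(microbiome(9L, 1), cv), "outside")
})

test_that("population fitness is normalised by the generation maximum", {
  expect_equal(normalize_population_fitness(c(2, 1)), c(1, 0.5))
  expect_equal(normalize_population_fitness(rep(3, 4)), rep(1, 4))
  set.seed(41)
  out <- normalize_population_fitness(runif(50))
  expect_equal(max(out), 1)
  expect_message(zeros <- normalize_population_fitness(c(0, 0)), "neutral")
  expect_equal(zeros, c(1, 1))
})

test_that("parents are chosen in proportion to fitness", {
  set.seed(42)
  expect_true(all(select_parents(c(1, 0), 50) == 1L))
  draws <- select_parents(c(2, 1), 1e5)
  expect_equal(mean(draws == 1), 2 / 3, tolerance = 0.01)
  uniform <- select_parents(rep(0.7, 4), 4e4)
  expect_gt(stats::chisq.test(table(factor(uniform, levels = 1:4)))$p.value,
            0.001)
})

test_that("ancestor counting matches exhaustive genealogy tracing", {
  expect_equal(ancestor_count(1:20), 20)
  expect_equal(ancestor_count(rep(7L, 5)), 1)

  set.seed(43)
  for (rep in 1:20) {
    N <- sample(3:8, 1)
    parent_vectors <- lapply(1:3, function(g) sample.int(N, N, replace = TRUE))
    founder <- seq_len(N)
    for (pv in parent_vectors) founder <- founder[pv]
    expect_equal(ancestor_count(founder), trace_founders_oracle(parent_vectors))
  }
})

test_that("advance_generation preserves size, ancestry and vertical support", {
  set.seed(44)
  cfg <- scenario_config(N = 12, B = 200, Tv = 1, Th = 0, bank_size = 20,
                         assembly = "species_poor", AC_threshold = 1)
  bank <- generate_template_bank(cfg$bank_size, cfg$assembly)
  cv <- draw_contributions(cfg$B, cfg$contributions)
  pop <- init_population(cfg, bank, cv)
  for (g in 1:5) {
    nxt <- advance_generation(pop, cfg, bank, cv)
    expect_length(nxt$microbiomes, cfg$N)
    expect_equal(nxt$founder, pop$founder[nxt$parent])
    for (i in seq_len(cfg$N))
      expect_true(all(nxt$microbiomes[[i]]$taxa %in%
                        pop$microbiomes[[nxt$parent[i]]]$taxa))
    expect_equal(max(nxt$fitness), 1)
    pop <- nxt
  }
})

test_that("one neutral generation of two hosts matches enumeration", {
  # with equal fitness each of the two offspring picks a parent uniformly:
  # P(both pick the same parent) = 1/2, so the expected ancestor count
  # after one generation is 1.5
  set.seed(45)
  cfg <- scenario_config(N = 2, B = 50, Tv = 1, Th = 0, bank_size = 5,
                         assembly = "species_poor", AC_threshold = 1,
                         neutral = TRUE)
  acs <- replicate(4000, {
    founder <- c(1L, 2L)[select_parents(c(1, 1), 2)]
    ancestor_count(founder)
  })
  expect_equal(mean(acs == 1), 0.5, tolerance = 0.05)
})

test_that("simulations are reproducible and properly censored", {
  cfg <- scenario_config(N = 10, B = 300, bank_size = 20, AC_threshold = 1,
                         assembly = "species_poor", seed = 9)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$coalescence_generation, r2$coalescence_generation)

  # ancestor count never increases and every generation is recorded
  expect_true(all(diff(r1$trajectory$ancestor_count) <= 0))
  expect_equal(r1$trajectory$generation,
               0:(nrow(r1$trajectory) - 1))
  expect_false(r1$censored)

  short <- scenario_config(N = 30, B = 300, bank_size = 20, AC_threshold = 1,
                           assembly = "species_poor", seed = 9,
                           max_generations = 3, neutral = TRUE)
  rc <- run_simulation(short)
  expect_true(rc$censored)
  expect_true(is.na(rc$coalescence_generation))
})

test_that("a single-host population is coalesced at generation zero", {
  cfg <- scenario_config(N = 1, B = 100, bank_size = 5, AC_threshold = 1,
                         assembly = "species_poor", seed = 2)
  r <- run_simulation(cfg)
  expect_equal(r$coalescence_generation, 0L)
  expect_false(r$censored)
})

test_that("pure horizontal transmission decouples offspring from parents", {
  set.seed(46)
  cfg <- scenario_config(N = 8, B = 100, Tv = 0, Th = 1, bank_size = 10,
                         assembly = "species_poor", AC_threshold = 1)
  bank <- generate_template_bank(cfg$bank_size, cfg$assembly)
  cv <- draw_contributions(cfg$B, cfg$contributions)
  pop <- init_population(cfg, bank, cv)
  # the sampling pool is the same for every parent choice, so offspring can
  # carry taxa absent from their own parent
  nxt <- advance_generation(pop, cfg, bank, cv)
  gained <- vapply(seq_len(cfg$N), function(i)
    any(!nxt$microbiomes[[i]]$taxa %in%
          pop$microbiomes[[nxt$parent[i]]]$taxa), logical(1))
  expect_true(any(gained))
})

test_that("replicate sets share a bank but draw fresh contributions", {
  cfg <- scenario_config(N = 6, B = 100, bank_size = 10, AC_threshold = 1,
                         assembly = "species_poor", seed = 12, replicates = 3)
  e <- simulate_replicates(cfg)
  expect_equal(nrow(e$summary), 3)
  expect_equal(dim(e$first_gen_fitness), c(3, 6))
  expect_false(any(e$summary$censored))
  # re-running reproduces everything
  e2 <- simulate_replicates(cfg)
  expect_identical(e$summary, e2$summary)
})
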