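test_that("replacement follows the 25/25/50 rule by fitness rank", {
  land <- make_landscape(L = 30, seed = 1)
  pop <- trio_population(land)
  cfg <- reproduction_config(mutation_rate = 0)
  trials <- 20000
  set.seed(31)
  replaced <- vapply(seq_len(trials), function(i) {
    tournament_replace(pop, 1:3, cfg)$replaced
  }, integer(1))
  freq <- tabulate(replaced, 3) / trials
  se <- sqrt(c(.25, .25, .5) * c(.75, .75, .5) / trials)
  expect_lt(abs(freq[1] - 0.25), 3 * se[1]) # fittest (15)
  expect_lt(abs(freq[2] - 0.25), 3 * se[2]) # middle (10)
  expect_lt(abs(freq[3] - 0.50), 3 * se[3]) # least fit (0)
})

test_that("a trio of identical individuals is unchanged without mutation", {
  land <- make_landscape(L = 30, seed = 2)
  set.seed(5)
  pop <- initialize_population(3, land)
  pop$maternal[] <- as.vector(land$t0)
  pop$paternal[] <- as.vector(land$t0)
  out <- tournament_replace(pop, 1:3, reproduction_config())$population
  expect_identical(out$maternal, pop$maternal)
  expect_identical(out$paternal, pop$paternal)
})

test_that("the child is assembled from the two surviving parents", {
  land <- make_landscape(L = 30, seed = 3)
  pop <- trio_population(land)
  cfg <- reproduction_config(mutation_rate = 0)
  set.seed(7)
  seen_least_fit <- FALSE
  for (i in 1:100) {
    res <- tournament_replace(pop, 1:3, cfg)
    r <- res$replaced
    parents <- setdiff(1:3, r)
    strands <- cbind(pop$maternal[, parents], pop$paternal[, parents])
    child_m <- res$population$maternal[, r]
    child_p <- res$population$paternal[, r]
    ok <- vapply(seq_len(30), function(j) {
      child_m[j] %in% strands[j, ] && child_p[j] %in% strands[j, ]
    }, logical(1))
    expect_true(all(ok))
    if (r == 3) seen_least_fit <- TRUE
  }
  expect_true(seen_least_fit)
})

test_that("a generation partitions the population into disjoint trios", {
  land <- make_landscape(L = 30, seed = 4)
  cfg <- reproduction_config(mutation_rate = 0.5)
  for (N in c(9, 10, 11)) {
    set.seed(40 + N)
    pop <- initialize_population(N, land)
    out <- run_generation(pop, cfg)
    expect_equal(population_size(out), N)
    changed <- vapply(seq_len(N), function(i) {
      !all(out$maternal[, i] == pop$maternal[, i] &
             out$paternal[, i] == pop$paternal[, i])
    }, logical(1))
    expect_lte(sum(changed), N %/% 3) # at most one replacement per trio
  }
  # without mutation a monomorphic population is invariant
  set.seed(50)
  pop <- initialize_population(9, land)
  pop$maternal[] <- as.vector(land$t0)
  pop$paternal[] <- pop$maternal
  out <- run_generation(pop, reproduction_config())
  expect_identical(out$maternal, pop$maternal)
})

test_that("peak0_present tracks carriers gene by gene", {
  land <- make_landscape(n = 2, L = 30, seed = 5)
  set.seed(6)
  pop <- initialize_population(6, land)
  expect_equal(peak0_present(pop), c(TRUE, TRUE))
  # push every gene-2 segment outside the peak-0 radius on both strands
  rows <- 31:60
  pop$maternal[rows, ] <- (land$t1[, 2] + 2L) %% 4L
  pop$paternal[rows, ] <- pop$maternal[rows, ]
  expect_equal(peak0_present(pop), c(TRUE, FALSE))
  # a single strand at distance r0 - 1 keeps the peak present...
  seg <- land$t0[, 2]
  seg[1] <- 1L # distance 1 < r0 = 2
  pop$paternal[rows, 4] <- seg
  expect_true(peak0_present(pop, gene = 2))
  # ...but distance exactly r0 does not (the radius has zero fitness)
  seg[2] <- 1L
  pop$paternal[rows, 4] <- seg
  expect_false(peak0_present(pop, gene = 2))
})

test_that("runs are reproducible and both engines agree", {
  land <- make_landscape(L = 30, seed = 6)
  cfg <- run_config(land, population_size = 10,
                    reproduction = reproduction_config(mutation_rate = 0.02),
                    max_generations = 500, seed = 99)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1, r2)
  r3 <- run_simulation(cfg, engine = "r")
  expect_identical(r1[, 1:4], r3[, 1:4])
  expect_true(r1$lost_peak0 || r1$generations_run == 500)
  if (r1$lost_peak0) {
    expect_lte(r1$loss_generation, 500)
    expect_false(is.na(r1$lost_gene))
  }
})

test_that("the per-generation trace records carriers and fitness", {
  land <- make_landscape(L = 30, seed = 6)
  cfg <- run_config(land, 9, reproduction_config(mutation_rate = 0.05),
                    max_generations = 100, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  res <- run_simulation(cfg, engine = "r", trace = path)
  tr <- read.csv(path)
  expect_equal(nrow(tr), res$generations_run)
  expect_true(all(tr$carriers_gene1 >= 0 & tr$carriers_gene1 <= 9))
  expect_true(all(tr$max_fitness >= tr$mean_fitness))
  if (res$lost_peak0) expect_equal(tr$carriers_gene1[nrow(tr)], 0)
})

test_that("peak 0 survives without mutation and dies far above the threshold", {
  # Without mutation the only loss channel is drift plus recombination
  # (heterozygote gametes are peak-target mosaics that can fall off both
  # peaks). That channel weakens quickly with population size: most runs
  # keep peak 0 even at N = 10 and nearly all at N = 30.
  land <- make_landscape(L = 30, seed = 7)
  kept <- function(N) {
    sum(vapply(1:40, function(s) {
      cfg <- run_config(land, N, reproduction_config(mutation_rate = 0),
                        max_generations = 400, seed = 5000 + s)
      !run_simulation(cfg)$lost_peak0
    }, logical(1)))
  }
  k10 <- kept(10)
  k30 <- kept(30)
  expect_gte(k10, 24) # clear majority survive at N = 10
  expect_gte(k30, 33) # near-certain survival at N = 30
  expect_gte(k30, k10 - 5) # survival does not degrade with N

  lost <- 0
  for (s in 1:40) {
    cfg <- run_config(land, 10, reproduction_config(mutation_rate = 0.5),
                      max_generations = 500, seed = 2000 + s)
    r <- run_simulation(cfg)
    if (r$lost_peak0) lost <- lost + 1
  }
  expect_gte(lost, 38) # far above any plausible CMR
})

test_that("the peak-0 loss fraction is monotone in the mutation rate", {
  land <- make_landscape(L = 30, seed = 8)
  rates <- c(1e-3, 3e-3, 1e-2)
  runs <- 500
  frac <- vapply(seq_along(rates), function(j) {
    lost <- 0
    for (s in seq_len(runs)) {
      cfg <- run_config(land, 10,
                        reproduction_config(mutation_rate = rates[j]),
                        max_generations = 300, seed = 3000 * j + s)
      if (run_simulation(cfg)$lost_peak0) lost <- lost + 1
    }
    lost / runs
  }, numeric(1))
  eps <- 3 * sqrt(0.25 / runs)
  expect_true(all(diff(frac) > -eps))
  expect_gt(frac[3], frac[1]) # the trend itself is visible at this span
})
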