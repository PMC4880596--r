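small_net <- function(...) build_two_population(scale = 0.05, nu_scale = 10, ...)

test_that("a zero-length run is the identity on the network state", {
  net <- small_net()
  r <- run_simulation(net, t_total = 0, seed = 1)
  expect_equal(r$network$ca, net$ca)
  expect_equal(store_count(r$network$store), 0L)
  expect_equal(r$network$t_now, 0)
  expect_equal(nrow(r$calcium), 0L)
})

test_that("schedule validation enforces the timescale contract", {
  net <- small_net()
  expect_error(run_simulation(net, 100, dt = 0.3, structural_interval = 10),
               "integer multiple")
  expect_error(run_simulation(net, 105, structural_interval = 10),
               "multiple of 'structural_interval'")
  expect_warning(run_simulation(net, 10, structural_interval = 1),
                 "100x")
})

test_that("identical seeds give bitwise-identical rasters and edge lists", {
  go <- function() {
    net <- small_net()
    r <- run_simulation(net, t_total = 30000, seed = 99, record_spikes = TRUE)
    list(spikes = r$spikes, edges = store_edges(r$network$store),
         ca = r$network$ca)
  }
  a <- go(); b <- go()
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$ca, b$ca)
})

test_that("conservation holds at every structural interval of a long run", {
  net <- build_two_population(scale = 0.1, nu_scale = 10)
  # check_invariants = TRUE asserts element-synapse conservation after
  # every one of the 6000 structural intervals
  r <- run_simulation(net, t_total = 60000, seed = 4, check_invariants = TRUE)
  expect_gt(store_count(r$network$store), 0L)
  check_conservation(r$network)
})

test_that("disabling plasticity freezes the edge set but not calcium", {
  net <- small_net()
  r1 <- run_simulation(net, t_total = 20000, seed = 12)
  n_edges <- store_count(r1$network$store)
  expect_gt(n_edges, 0L)
  net2 <- disable_plasticity(r1$network)
  r2 <- run_simulation(net2, t_total = 20000, seed = 13)
  expect_equal(store_count(r2$network$store), n_edges)
  expect_identical(store_edges(r2$network$store),
                   store_edges(r1$network$store))
  expect_false(identical(r2$network$ca, r1$network$ca)) # calcium tracked
  # re-enabling resumes structural change; element pools were preserved
  expect_identical(r2$network$elem$z, r1$network$elem$z)
  net3 <- enable_plasticity(r2$network)
  r3 <- run_simulation(net3, t_total = 20000, seed = 14)
  expect_gt(store_count(r3$network$store), n_edges)
})

test_that("plasticity windows control when structural updates happen", {
  net <- small_net()
  r <- run_simulation(net, t_total = 20000, seed = 3,
                      enable_plasticity_at = 10000)
  first_half <- r$connections[r$connections$time_ms <= 9990, "count"]
  expect_true(all(first_half == 0))
  expect_gt(store_count(r$network$store), 0L)
})

test_that("growth-rate/interval rescaling leaves element trajectories near-invariant", {
  # with frozen electrical input (zero drive -> silent network, calcium 0),
  # z grows at the full rate nu: scaling nu by k and the interval by 1/k
  # must give the same trajectory to first order
  gc_fast <- growth_curve("linear", nu = 2e-4, eps = 0.05)
  gc_slow <- growth_curve("linear", nu = 1e-4, eps = 0.05)
  mk <- function(gc) {
    pops <- list(population_spec("P", 4,
                                 elements = list(Axon_ex = gc, Den_ex = gc),
                                 drive = external_drive(0, 0)))
    sp_network(pops, list(synapse_rule("s", "Axon_ex", "Den_ex", 1.0)))
  }
  suppressWarnings({
    r_fast <- run_simulation(mk(gc_fast), 20000, structural_interval = 5,
                             seed = 8)
    r_slow <- run_simulation(mk(gc_slow), 20000, structural_interval = 10,
                             seed = 8)
  })
  # nu * t equal in the fast run at half the time: compare z at t where
  # nu*t matches: fast at 20000 ms with nu 2e-4 == slow would need 40000;
  # instead compare fast(t) vs slow(2t) via totals at the end of each run
  z_fast <- sum(r_fast$network$elem$z) # 8 pools * nu*t = 8*4
  z_slow <- sum(r_slow$network$elem$z)
  expect_equal(z_fast, 2 * z_slow, tolerance = 1e-6)
})

test_that("per-neuron calcium sampling matches the population means", {
  net <- small_net()
  r <- run_simulation(net, 5000, seed = 6, record_neuron_calcium = TRUE,
                      calcium_sampling = 1000)
  cn <- r$calcium_neuron
  expect_equal(sort(unique(cn$time_ms)), seq(1000, 5000, 1000))
  expect_equal(nrow(cn), 5 * net$n)
  # averaging the per-neuron samples per population recovers the recorded
  # population means
  for (tt in unique(cn$time_ms)) {
    x <- cn[cn$time_ms == tt, ]
    exc <- mean(x$ca[x$neuron <= net$pop$last[1]])
    expect_equal(exc, r$calcium$ca_mean[r$calcium$time_ms == tt &
                                        r$calcium$population == "excitatory"])
  }
})

test_that("time is cumulative across successive runs of the same network", {
  net <- small_net()
  r1 <- run_simulation(net, 10000, seed = 2)
  r2 <- run_simulation(r1$network, 10000, seed = 2)
  expect_equal(r2$network$t_now, 20000)
  expect_equal(min(r2$calcium$time_ms), 10010)
})
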