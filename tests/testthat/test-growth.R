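test_that("linear growth rate is nu at zero calcium and crosses zero at eps", {
  gc <- growth_curve("linear", nu = 2e-4, eps = 0.05)
  expect_equal(growth_rate(gc, 0), 2e-4)
  expect_equal(growth_rate(gc, 0.05), 0)
  # strictly decreasing in calcium
  ca <- seq(0, 0.2, length.out = 50)
  expect_true(all(diff(growth_rate(gc, ca)) < 0))
})

test_that("gaussian growth rate has roots at eta and eps and peak nu at xi", {
  gc <- growth_curve("gaussian", nu = 1e-4, eps = 0.05, eta = 0.01)
  xi <- (0.01 + 0.05) / 2
  expect_equal(growth_rate(gc, xi), 1e-4)
  expect_equal(growth_rate(gc, 0.05), 0, tolerance = 1e-16)
  expect_equal(growth_rate(gc, 0.01), 0, tolerance = 1e-16)
  expect_equal(growth_rate(gc, 5), -1e-4, tolerance = 1e-9) # far asymptote

  # symmetric about xi; positive strictly inside (eta, eps), negative outside
  d <- seq(0, 0.019, length.out = 25)
  expect_equal(growth_rate(gc, xi + d), growth_rate(gc, xi - d))
  inside <- seq(0.0105, 0.0495, length.out = 20)
  expect_true(all(growth_rate(gc, inside) > 0))
  outside <- c(seq(0, 0.0095, length.out = 10), seq(0.0505, 0.3, length.out = 10))
  expect_true(all(growth_rate(gc, outside) < 0))
  # bounded in [-nu, nu]
  expect_true(all(abs(growth_rate(gc, seq(0, 1, 0.01))) <= 1e-4 + 1e-18))
})

test_that("growth curve validates its parameters", {
  expect_error(growth_curve("gaussian", nu = 1e-4, eps = 0.05, eta = 0.05),
               "eta < eps")
  expect_error(growth_curve("gaussian", nu = -1, eps = 0.05))
  expect_error(growth_rate(growth_curve("linear", nu = 1, eps = 1), -0.1))
})

test_that("element integration detects floor crossings and clamps vacancies", {
  cal <- calcium_params(tau = 10000, beta = 0.001)
  # engineered linear curves so that delta z over the interval is exact and
  # easy to control: at ca_start = 0 the linear rule gives dz = nu * dt
  up <- function(z0, dz, connected = 0L) {
    gc <- growth_curve("linear", nu = dz / 1000, eps = 0.05)
    p <- element_pool("Axon_ex", z = z0, connected = connected)
    integrate_elements(p, gc, ca_start = 0, dt = 1000, cal = cal)
  }
  r <- up(2.9, 0.2)
  expect_equal(r$pool$z, 3.1)
  expect_equal(r$n_new_vacant, 1L)
  expect_equal(r$n_deleted, 0L)

  # downward crossing into the connected range must release one element;
  # exact linear integration with ca_start at the setpoint gives dz < 0
  gc <- growth_curve("linear", nu = 1e-3, eps = 0.01)
  p <- element_pool("Axon_ex", z = 3.05, connected = 3L)
  r2 <- integrate_elements(p, gc, ca_start = 0.05, dt = 100, cal = cal)
  expect_lt(r2$pool$z, 3)
  expect_equal(r2$n_deleted, 1L)

  # z may go negative; the vacant count clamps at zero, so recovery must
  # first regrow the deficit across zero
  p3 <- element_pool("Axon_ex", z = 0.3, connected = 0L)
  r3 <- integrate_elements(p3, gc, ca_start = 0.05, dt = 100, cal = cal)
  expect_lt(r3$pool$z, 0)
  expect_equal(r3$n_new_vacant, 0L)
  expect_equal(r3$n_deleted, 0L)
  expect_equal(vacant_count(r3$pool), 0L)
})

test_that("linear exact integration matches fine-step Euler of the coupled ODE", {
  # dz/dt = nu (1 - Ca(t)/eps) with Ca(t) = Ca0 exp(-t/tau)
  cal <- calcium_params(tau = 10000, beta = 0.001)
  gc <- growth_curve("linear", nu = 1e-4, eps = 0.05)
  ca0 <- 0.08
  dt_struct <- 1000
  p <- element_pool("Axon_ex", z = 0)
  r <- integrate_elements(p, gc, ca_start = ca0, dt = dt_struct, cal = cal)
  z_euler <- 0; h <- 0.01
  for (k in seq_len(dt_struct / h)) {
    ca_t <- ca0 * exp(-((k - 1) * h) / cal$tau)
    z_euler <- z_euler + gc$nu * (1 - ca_t / gc$eps) * h
  }
  expect_equal(r$pool$z, z_euler, tolerance = 1e-5)
})

test_that("calcium held at the setpoint is a fixed point of element growth", {
  cal <- calcium_params(tau = 1e12, beta = 0.001) # negligible decay
  for (kind in c("linear", "gaussian")) {
    gc <- growth_curve(kind, nu = 1e-4, eps = 0.05, eta = 0)
    p <- element_pool("Den_ex", z = 4.2, connected = 4L)
    r <- integrate_elements(p, gc, ca_start = 0.05, dt = 10, cal = cal)
    expect_equal(r$pool$z, 4.2, tolerance = 1e-9)
    expect_equal(r$n_new_vacant, 0L)
    expect_equal(r$n_deleted, 0L)
  }
})

test_that("pruning removes a fraction of vacant elements only", {
  p <- element_pool("Den_ex", z = 5.0, connected = 3L)
  expect_equal(vacant_count(p), 2L)
  expect_equal(prune_vacant(p, 0)$z, 5.0)          # identity
  expect_equal(prune_vacant(p, 1)$z, 3.0)          # full pruning -> connected
  expect_equal(prune_vacant(p, 0.1)$z, 4.8)        # fractional reduction
  expect_error(prune_vacant(p, 1.5), "\\[0, 1\\]")
  expect_error(prune_vacant(p, -0.1), "\\[0, 1\\]")
  # connected is never touched
  expect_equal(prune_vacant(p, 1)$connected, 3L)
})

test_that("reported element counts honor the continuous flag", {
  gc_d <- growth_curve("gaussian", nu = 1e-4, eps = 0.05, continuous = FALSE)
  gc_c <- growth_curve("gaussian", nu = 1e-4, eps = 0.05, continuous = TRUE)
  p <- element_pool("Axon_ex", z = 2.7)
  expect_equal(element_count(p, gc_d), 2)
  expect_equal(element_count(p, gc_c), 2.7)
})
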