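# Rigid-body inverse dynamics (pendulum chain and gait skeleton), smoothed
# compliant contact, and tape-recordability of the dynamics.

test_that("upright rest gives zero pendulum torques", {
  ch <- pendulum_chain(3)
  T0 <- pendulum_inverse_dynamics(ch, 0.5, list(q = rep(0, 3), v = rep(0, 3),
                                                udv = rep(0, 3)))
  expect_equal(T0, rep(0, 3), tolerance = 1e-14)
})

test_that("inverse dynamics is affine in accelerations with SPD mass matrix", {
  set.seed(3)
  for (nd in c(2, 5)) {
    ch <- pendulum_chain(nd)
    q <- stats::runif(nd, -1, 1); v <- stats::runif(nd, -2, 2)
    mm <- pendulum_mass_matrix(ch, 0.1, q, v)
    expect_lt(max(abs(mm$M - t(mm$M))), 1e-10 * max(abs(mm$M)))
    expect_true(all(eigen(mm$M, symmetric = TRUE)$values > 0))
    # affinity: T at a random udv equals M udv + bias
    udv <- stats::runif(nd, -5, 5)
    Tid <- pendulum_inverse_dynamics(ch, 0.1, list(q = q, v = v, udv = udv))
    expect_equal(Tid, as.numeric(mm$M %*% udv + mm$bias), tolerance = 1e-12)
    # unit-acceleration column at rest reproduces the mass-matrix column
    T1 <- pendulum_inverse_dynamics(ch, 0.5,
      list(q = rep(0, nd), v = rep(0, nd),
           udv = c(1, rep(0, nd - 1))))
    mm0 <- pendulum_mass_matrix(ch, 0.5, rep(0, nd), rep(0, nd))
    expect_equal(T1, mm0$M[, 1], tolerance = 1e-12)
  }
})

test_that("pendulum inverse dynamics matches the Lagrangian oracle", {
  set.seed(5)
  for (nd in c(2, 4, 7)) {
    ch <- pendulum_chain(nd)
    for (r in 1:35) {
      q <- stats::runif(nd, -1.5, 1.5)
      v <- stats::runif(nd, -3, 3)
      udv <- stats::runif(nd, -10, 10)
      t <- stats::runif(1, 0, 0.5)
      Tid <- pendulum_inverse_dynamics(ch, t, list(q = q, v = v, udv = udv))
      Tor <- pendulum_id_oracle(ch, t, q, v, udv)
      expect_lt(max(abs(Tid - Tor)), 1e-10 * max(1, max(abs(Tor))))
    }
  }
})

test_that("energy balance holds along a simulated pendulum trajectory", {
  ch <- pendulum_chain(2)
  torque_fn <- function(t) c(10 * sin(4 * t), -4 * cos(3 * t))
  # integrate the joint power as an extra state: E(t) - E(t0) must equal the
  # injected work W(t) - W(t0) once the base pulse has ended (the pulse makes
  # the pseudo-potential explicitly time-dependent)
  rhs <- function(t, y, parms) {
    q <- y[1:2]; v <- y[3:4]
    mm <- pendulum_mass_matrix(ch, t, q, v)
    acc <- solve(mm$M, torque_fn(t) - mm$bias)
    list(c(v, acc, sum(torque_fn(t) * v)))
  }
  out <- deSolve::ode(c(0.2, -0.1, 0, 0, 0), seq(0.21, 0.4, by = 0.01),
                      rhs, NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  tt <- out[, 1]
  en <- vapply(seq_len(nrow(out)), function(i) {
    e <- pendulum_energy(ch, tt[i], out[i, 2:3], out[i, 4:5])
    e$kinetic + e$potential
  }, 0)
  W <- out[, 6]
  expect_lt(max(abs((en - en[1]) - (W - W[1]))),
            1e-8 * max(1, max(abs(en))))
})

test_that("smoothed contact reproduces the compliant normal-force law", {
  sp <- contact_sphere(c(0, 0), radius = 0.035, stiffness = 2e6,
                       dissipation = 0)
  # static 5 mm penetration: within 1% of k * delta^1.5
  f <- contact_force_smooth(sp, c(0, sp$radius - 0.005), c(0, 0))
  expect_lt(abs(f[["fy"]] - 2e6 * 0.005^1.5), 0.01 * 2e6 * 0.005^1.5)
  # airborne by one radius: all components below 1e-6 N
  f0 <- contact_force_smooth(sp, c(0, 2 * sp$radius), c(0.4, -0.1))
  expect_lt(max(abs(c(f0[["fx"]], f0[["fy"]]))), 1e-6)
  # dissipation increases force during penetration-rate > 0
  spd <- contact_sphere(c(0, 0), radius = 0.035, stiffness = 2e6,
                        dissipation = 2)
  fd <- contact_force_smooth(spd, c(0, spd$radius - 0.005), c(0, -0.1))
  expect_gt(fd[["fy"]], f[["fy"]])
})

test_that("contact force is twice continuously differentiable across touch", {
  sp <- contact_sphere(c(0, 0), radius = 0.03)
  # continuity of the second derivative: the largest jump between adjacent
  # second differences is O(h) for a continuous f'' (it would stay O(1)
  # across a kink), so it must shrink proportionally when h is halved
  jump <- function(h) {
    ys <- seq(sp$radius - 40 * h, sp$radius + 40 * h, by = h)
    fy <- vapply(ys, function(y)
      contact_force_smooth(sp, c(0, y), c(0.05, -0.02))[["fy"]], 0)
    max(abs(diff(diff(fy, differences = 2) / h^2)))
  }
  j1 <- jump(4e-7)
  j2 <- jump(2e-7)
  expect_lt(j2, 0.7 * j1)
})

test_that("gait skeleton inverse dynamics matches the oracle", {
  fx <- gait_fixture()
  g <- fx$gait
  # zero gravity, zero contact, static: zero torques
  g0 <- g; g0$gravity <- 0
  T0 <- skeleton_inverse_dynamics(g0,
    list(q = c(0, 2, 0, rep(0.1, 7)), v = rep(0, 10), udv = rep(0, 10)),
    contact = NULL)
  expect_equal(T0, rep(0, 10), tolerance = 1e-12)
  set.seed(9)
  for (r in 1:100) {
    q <- c(stats::runif(1, -0.2, 0.2), stats::runif(1, 0.9, 1.05),
           stats::runif(1, -0.3, 0.3), stats::runif(6, -0.6, 0.05),
           stats::runif(1, -0.3, 0.3))
    v <- stats::runif(10, -2, 2)
    udv <- stats::runif(10, -10, 10)
    Tid <- skeleton_inverse_dynamics(g, list(q = q, v = v, udv = udv))
    Tor <- skeleton_id_oracle(g, q, v, udv)
    expect_lt(max(abs(Tid - Tor)), 1e-9 * max(1, max(abs(Tor))))
  }
})

test_that("static standing leaves near-zero pelvis residual", {
  fx <- gait_fixture()
  g <- fx$gait
  # find the pelvis height where the vertical contact forces carry the weight
  wt <- sum(vapply(g$model$bodies, function(b) b$seg$mass, 0)) * g$gravity
  f <- function(ty) {
    q <- c(0, ty, 0, rep(0, 7))
    sum(vapply(gait_contact_forces(g, q, rep(0, 10)),
               function(s) s$fy, 0)) - wt
  }
  ty <- stats::uniroot(f, c(0.95, 0.999), tol = 1e-12)$root
  q <- c(0, ty, 0, rep(0, 7))
  Tq <- skeleton_inverse_dynamics(g, list(q = q, v = rep(0, 10),
                                          udv = rep(0, 10)))
  expect_lt(abs(Tq[2]), 1e-6 * wt)        # vertical pelvis residual
  expect_lt(abs(Tq[1]), 1e-9 * wt)        # no horizontal force at rest
  # ankle torques balance the fore-aft offset between ankle and pressure
  # center: same magnitude both sides by symmetry
  expect_equal(Tq[6], Tq[9], tolerance = 1e-9)
})

test_that("dynamics are recordable and replay equals direct evaluation", {
  ch <- pendulum_chain(3)
  s0 <- c(0.2, -0.1, 0.3, 1, -2, 0.5, 3, -1, 2)
  tp <- record(function(z) pendulum_inverse_dynamics(ch, 0.1,
    list(q = z[1:3], v = z[4:6], udv = z[7:9])), s0)
  expect_length(tp$branch, 0L)
  set.seed(12)
  for (r in 1:5) {
    s <- stats::rnorm(9)
    expect_equal(replay(tp, s),
                 pendulum_inverse_dynamics(ch, 0.1,
                   list(q = s[1:3], v = s[4:6], udv = s[7:9])),
                 tolerance = 1e-13)
  }
  fx <- gait_fixture()
  g <- fx$gait
  st <- c(0, 0.99, 0, rep(0.05, 7), rep(0.2, 10), rep(1, 10))
  tps <- record(function(z) skeleton_inverse_dynamics(g,
    list(q = z[1:10], v = z[11:20], udv = z[21:30])), st)
  expect_length(tps$branch, 0L)
  s <- st + stats::rnorm(30, sd = 0.05)
  expect_equal(replay(tps, s),
               skeleton_inverse_dynamics(g, list(q = s[1:10], v = s[11:20],
                                                 udv = s[21:30])),
               tolerance = 1e-12)
})
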