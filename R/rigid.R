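# Planar rigid-body dynamics on a kinematic tree. The kinematic and
# inverse-dynamics passes are written against generic scalar arithmetic so the
# same code runs on plain doubles, on complex numbers (complex-step oracles in
# the tests) and on the taped AD type: only smooth closed-set operations are
# used and there are no branches on state.

# sparsity-aware scalar helpers: exact numeric zeros are pruned so that
# partial-velocity passes (unit velocity seeds) stay cheap on the tape
zadd <- function(a, b) {
  if (identical(a, 0)) return(b)
  if (identical(b, 0)) return(a)
  a + b
}
zsub <- function(a, b) {
  if (identical(b, 0)) return(a)
  if (identical(a, 0)) return(-b)
  a - b
}
zmul <- function(a, b) {
  if (identical(a, 0) || identical(b, 0)) return(0)
  a * b
}

## ---- model structure -------------------------------------------------------

#' Segment (body) parameters for planar models
#'
#' @param name segment name.
#' @param mass mass (kg).
#' @param inertia moment of inertia about the center of mass (kg m^2).
#' @param com 2-vector, center of mass in the segment frame (m).
#' @param length characteristic length (m), used for sanity checks only.
#' @return List of class `tt_segment`.
#' @export
segment_params <- function(name, mass, inertia, com, length) {
  stopifnot(mass > 0, inertia > 0, length > 0)
  if (inertia > mass * length^2)
    stop("inertia exceeds mass * length^2 for segment ", name)
  structure(list(name = name, mass = mass, inertia = inertia,
                 com = com, length = length), class = "tt_segment")
}

# body: list(name, parent (0 = world/base), jtype "rev"|"base",
#            coord (index) or coords (tx,ty,rz), jpos (2-vec in parent frame),
#            seg = tt_segment)
new_planar_model <- function(ncoord, bodies) {
  structure(list(ncoord = ncoord, bodies = bodies), class = "tt_planar_model")
}

#' @export
print.tt_planar_model <- function(x, ...) {
  cat("<tt_planar_model>", x$ncoord, "coordinates,",
      length(x$bodies), "bodies\n")
  invisible(x)
}

## ---- kinematic pass --------------------------------------------------------

# Computes, for each body, absolute angle/rate/acceleration and origin / com
# position, velocity, acceleration; and position/velocity/acceleration of the
# requested attached points. All quantities in the (possibly accelerating)
# base frame. q, v, a index into the model coordinates; entries may be
# numeric, complex, or taped scalars.
planar_pass <- function(model, q, v, a, points = list()) {
  nb <- length(model$bodies)
  th <- vector("list", nb); om <- vector("list", nb); al <- vector("list", nb)
  ox <- vector("list", nb); oy <- vector("list", nb)
  vx <- vector("list", nb); vy <- vector("list", nb)
  ax <- vector("list", nb); ay <- vector("list", nb)
  cth <- vector("list", nb); sth <- vector("list", nb)
  # attached-point kinematics for a point p (2-vec) on body b
  point_kin <- function(b, p) {
    # world offset R(theta) p and its theta-derivative R'(theta) p
    rx <- zsub(zmul(cth[[b]], p[1]), zmul(sth[[b]], p[2]))
    ry <- zadd(zmul(sth[[b]], p[1]), zmul(cth[[b]], p[2]))
    dx <- -ry; dy <- rx                     # R' p = rot90(R p)
    px <- zadd(ox[[b]], rx); py <- zadd(oy[[b]], ry)
    pvx <- zadd(vx[[b]], zmul(om[[b]], dx))
    pvy <- zadd(vy[[b]], zmul(om[[b]], dy))
    om2 <- zmul(om[[b]], om[[b]])
    pax <- zadd(ax[[b]], zsub(zmul(al[[b]], dx), zmul(om2, rx)))
    pay <- zadd(ay[[b]], zsub(zmul(al[[b]], dy), zmul(om2, ry)))
    list(x = px, y = py, vx = pvx, vy = pvy, ax = pax, ay = pay)
  }
  com <- vector("list", nb)
  for (b in seq_len(nb)) {
    body <- model$bodies[[b]]
    if (body$jtype == "base") {
      cs <- body$coords
      th[[b]] <- q[cs[3]]; om[[b]] <- v[cs[3]]; al[[b]] <- a[cs[3]]
      ox[[b]] <- q[cs[1]]; oy[[b]] <- q[cs[2]]
      vx[[b]] <- v[cs[1]]; vy[[b]] <- v[cs[2]]
      ax[[b]] <- a[cs[1]]; ay[[b]] <- a[cs[2]]
    } else {
      k <- body$coord
      if (body$parent == 0L) {
        th[[b]] <- q[k]; om[[b]] <- v[k]; al[[b]] <- a[k]
        ox[[b]] <- body$jpos[1]; oy[[b]] <- body$jpos[2]
        vx[[b]] <- 0; vy[[b]] <- 0; ax[[b]] <- 0; ay[[b]] <- 0
      } else {
        pb <- body$parent
        th[[b]] <- zadd(th[[pb]], q[k])
        om[[b]] <- zadd(om[[pb]], v[k])
        al[[b]] <- zadd(al[[pb]], a[k])
        jk <- point_kin(pb, body$jpos)
        ox[[b]] <- jk$x; oy[[b]] <- jk$y
        vx[[b]] <- jk$vx; vy[[b]] <- jk$vy
        ax[[b]] <- jk$ax; ay[[b]] <- jk$ay
      }
    }
    cth[[b]] <- cos(th[[b]]); sth[[b]] <- sin(th[[b]])
    com[[b]] <- point_kin(b, model$bodies[[b]]$seg$com)
  }
  pk <- lapply(points, function(p) point_kin(p$body, p$point))
  list(theta = th, omega = om, alpha = al, com = com, points = pk)
}

## ---- inverse dynamics ------------------------------------------------------

# Generalized torques by Jourdain's principle (virtual power): one
# acceleration pass with the actual (v, udv) plus one partial-velocity pass
# per coordinate with a unit velocity seed. accel_offset = c(A, g) adds the
# prescribed base acceleration A (pseudo-force) and gravity to every body's
# acceleration. point_forces: list of list(body, point, fx, fy).
planar_id_core <- function(model, q, v, udv, accel_offset = c(0, 9.81),
                           point_forces = list()) {
  n <- model$ncoord
  pts <- lapply(point_forces, function(f) list(body = f$body, point = f$point))
  main <- planar_pass(model, q, v, udv, pts)
  torques <- vector("list", n)
  zero <- rep(0, n)
  for (k in seq_len(n)) {
    ek <- as.list(zero); ek[[k]] <- 1
    ekv <- ek
    unit <- planar_pass(model, q, VecList(ekv), VecList(as.list(zero)), pts)
    tk <- 0
    for (b in seq_along(model$bodies)) {
      seg <- model$bodies[[b]]$seg
      cm <- main$com[[b]]; cu <- unit$com[[b]]
      tk <- zadd(tk, zmul(seg$mass,
             zadd(zmul(zadd(cm$ax, accel_offset[1]), cu$vx),
                  zmul(zadd(cm$ay, accel_offset[2]), cu$vy))))
      tk <- zadd(tk, zmul(seg$inertia, zmul(main$alpha[[b]], unit$omega[[b]])))
    }
    for (j in seq_along(point_forces)) {
      f <- point_forces[[j]]; pu <- unit$points[[j]]
      tk <- zsub(tk, zadd(zmul(f$fx, pu$vx), zmul(f$fy, pu$vy)))
    }
    torques[[k]] <- tk
  }
  torques
}

# wrap a plain list so that x[i] indexing works uniformly in planar_pass
VecList <- function(lst) structure(list(v = lst), class = "tt_veclist")
#' @export
`[.tt_veclist` <- function(x, i) x$v[[i]]

# kinetic and potential energy in the base frame; accel_offset = c(A, g)
# contributes the pseudo-potential m*A*x in addition to m*g*y.
planar_energies <- function(model, q, v, accel_offset = c(0, 9.81)) {
  zeros <- VecList(as.list(rep(0, model$ncoord)))
  pass <- planar_pass(model, q, v, zeros)
  ke <- 0; pe <- 0
  for (b in seq_along(model$bodies)) {
    seg <- model$bodies[[b]]$seg
    cm <- pass$com[[b]]
    ke <- ke + 0.5 * seg$mass * (zmul(cm$vx, cm$vx) + zmul(cm$vy, cm$vy)) +
      0.5 * seg$inertia * zmul(pass$omega[[b]], pass$omega[[b]])
    pe <- pe + seg$mass * (accel_offset[2] * cm$y + zmul(accel_offset[1], cm$x))
  }
  list(kinetic = ke, potential = pe)
}

## ---- pendulum chain --------------------------------------------------------

#' Planar inverted-pendulum chain on a translating base
#'
#' A serial chain of `ndof` uniform-rod segments standing upright on a base
#' whose horizontal acceleration is prescribed (the balance perturbation).
#' Defaults split 1.7 m and 70 kg equally among segments.
#'
#' @param ndof number of revolute joints (2-10).
#' @param total_height,total_mass chain totals (m, kg).
#' @param base_motion function of time returning the prescribed horizontal
#'   base acceleration (m/s^2); the default is a half-sine backward pulse.
#' @param gravity gravitational acceleration (m/s^2).
#' @return List of class `tt_pendulum` with the planar model and parameters.
#' @export
pendulum_chain <- function(ndof, total_height = 1.7, total_mass = 70,
                           base_motion = base_pulse(), gravity = 9.81) {
  stopifnot(ndof >= 1, ndof <= 10)
  L <- total_height / ndof
  m <- total_mass / ndof
  bodies <- lapply(seq_len(ndof), function(i) {
    list(name = paste0("link", i), parent = i - 1L, jtype = "rev",
         coord = i,
         jpos = if (i == 1L) c(0, 0) else c(0, L),
         seg = segment_params(paste0("link", i), m, m * L^2 / 12,
                              com = c(0, L / 2), length = L))
  })
  structure(list(model = new_planar_model(ndof, bodies),
                 ndof = ndof, gravity = gravity,
                 base_motion = base_motion),
            class = "tt_pendulum")
}

#' Half-sine backward base-acceleration pulse
#'
#' @param peak peak magnitude (m/s^2); the pulse is backward (negative x).
#' @param duration pulse duration (s).
#' @return Function of time returning the base acceleration.
#' @export
base_pulse <- function(peak = 2, duration = 0.2) {
  force(peak); force(duration)
  function(t) ifelse(t >= 0 & t <= duration,
                     -peak * sin(pi * t / duration), 0)
}

#' Inverse dynamics of the pendulum chain
#'
#' Net joint torques `T` such that the chain with joint angles `q`, velocities
#' `v` and accelerations `udv` (accelerations enter as controls in the
#' implicit formulation), under gravity and the prescribed base acceleration
#' at time `t`, satisfies the equations of motion:
#' `T = M(q) udv + c(q, v) + g(q) + base terms`.
#'
#' @param chain a `tt_pendulum`.
#' @param t time (s), used only to evaluate the prescribed base acceleration.
#' @param state list with numeric (or taped) `q`, `v`, `udv` of length `ndof`.
#' @return Torque vector of length `ndof` (same scalar type as the state).
#' @export
pendulum_inverse_dynamics <- function(chain, t, state) {
  stopifnot(length(state$q) == chain$ndof)
  A <- chain$base_motion(t)
  tl <- planar_id_core(chain$model, state$q, state$v, state$udv,
                       accel_offset = c(A, chain$gravity))
  collapse_scalars(tl)
}

# turn a list of like-typed scalars into a vector (adnum, complex or numeric)
collapse_scalars <- function(lst) {
  if (any(vapply(lst, inherits, TRUE, what = "adnum"))) {
    rec <- active_rec()
    ids <- unlist(lapply(lst, function(p) {
      if (inherits(p, "adnum")) p$ids
      else add_nodes(rec, "const", 0L, 0L, as.numeric(p))
    }))
    adnum(ids)
  } else if (any(vapply(lst, is.complex, TRUE))) {
    vapply(lst, function(p) as.complex(p), complex(1))
  } else {
    vapply(lst, function(p) as.numeric(p), 0)
  }
}

#' Kinetic and potential energy of the pendulum chain
#'
#' Energies in the base frame, including the pseudo-potential of the
#' prescribed base acceleration; used by the energy-balance checks.
#'
#' @param chain a `tt_pendulum`.
#' @param t time (s).
#' @param q,v coordinates and velocities.
#' @return List with `kinetic` and `potential`.
#' @export
pendulum_energy <- function(chain, t, q, v) {
  A <- chain$base_motion(t)
  planar_energies(chain$model, q, v, accel_offset = c(A, chain$gravity))
}

#' Pendulum mass matrix, Coriolis/gravity vector
#'
#' Assembles `M(q)` column-by-column from the affinity of the inverse dynamics
#' in the accelerations, plus the bias term `c(q, v) + g(q) + base`.
#'
#' @param chain a `tt_pendulum`.
#' @param t time (s).
#' @param q,v state.
#' @return List with `M` (n x n) and `bias` (length n), so that
#'   `T = M %*% udv + bias`.
#' @export
pendulum_mass_matrix <- function(chain, t, q, v) {
  n <- chain$ndof
  bias <- pendulum_inverse_dynamics(chain, t, list(q = q, v = v,
                                                   udv = rep(0, n)))
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    M[, j] <- pendulum_inverse_dynamics(chain, t,
                list(q = q, v = v, udv = e)) - bias
  }
  list(M = M, bias = bias)
}

## ---- smoothed compliant contact -------------------------------------------

#' Contact sphere parameters
#'
#' Compliant sphere-plane (Hunt-Crossley) contact, smoothed so that all force
#' components are twice continuously differentiable: the positive part of the
#' penetration is regularised with `sqrt(delta^2 + eps^2)` and the
#' velocity-dependent switches use hyperbolic tangents.
#'
#' @param location 2-vector, sphere center in the carrying segment frame (m).
#' @param radius sphere radius (m).
#' @param stiffness plane-strain stiffness k (N/m^1.5).
#' @param dissipation Hunt-Crossley dissipation c (s/m).
#' @param mu_d,mu_v dynamic and viscous friction coefficients.
#' @param b_d tanh sharpness of the dissipation gate (1/m).
#' @param b_v tanh sharpness of the friction switch (s/m).
#' @param eps smoothing width of the positive-part of penetration (m).
#' @return List of class `tt_contact_sphere`.
#' @export
contact_sphere <- function(location, radius, stiffness = 2e6,
                           dissipation = 2, mu_d = 0.8, mu_v = 0.5,
                           b_d = 300, b_v = 50, eps = 1e-5) {
  stopifnot(radius > 0, stiffness > 0, dissipation >= 0)
  structure(list(location = location, radius = radius, stiffness = stiffness,
                 dissipation = dissipation, mu_d = mu_d, mu_v = mu_v,
                 b_d = b_d, b_v = b_v, eps = eps),
            class = "tt_contact_sphere")
}

#' Smoothed Hunt-Crossley sphere-plane contact force
#'
#' Normal force `k * dp^1.5 * (1 + 1.5 c ddot)` where `dp` is the smooth
#' positive part of the penetration `delta = radius - y_center` and the
#' dissipation term is gated by `tanh(b_d * delta)`; the tangential force is
#' `-(mu_d tanh(b_v vx) + mu_v vx)` times the normal force. Defined (and
#' twice continuously differentiable) for all positions including airborne,
#' where the leakage is bounded far below body weight.
#'
#' @param sphere a `tt_contact_sphere`.
#' @param pos 2-vector, sphere-center position (m); the plane is y = 0.
#' @param vel 2-vector, sphere-center velocity (m/s).
#' @return Named vector/list `c(fx, fy)`: tangential and normal force on the
#'   sphere (N). Taped scalars in, taped scalars out.
#' @export
contact_force_smooth <- function(sphere, pos, vel) {
  comp <- function(v, i, nm) {
    if (inherits(v, "adnum")) v[i]
    else if (is.list(v)) v[[nm]]
    else v[i]
  }
  posy <- comp(pos, 2, "y")
  velx <- comp(vel, 1, "x")
  vely <- comp(vel, 2, "y")
  delta <- sphere$radius - posy
  ddot <- -vely
  dp <- 0.5 * (delta + sqrt(delta^2 + sphere$eps^2))
  gate <- 0.5 * (1 + tanh(sphere$b_d * delta))
  fn <- sphere$stiffness * dp^1.5 *
    (1 + 1.5 * sphere$dissipation * ddot * gate)
  fx <- -(sphere$mu_d * tanh(sphere$b_v * velx) + sphere$mu_v * velx) * fn
  if (is.numeric(fn) && is.numeric(fx)) c(fx = fx, fy = fn)
  else list(fx = fx, fy = fn)
}
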