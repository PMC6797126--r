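# Planar 10-dof, 18-muscle gait model. Anthropometry, muscle attachment
# points and contact constants are a synthetic fixture representative of
# generic adult models used in predictive gait studies; they are constructed
# here in code (documented, overridable) rather than read from data files.

.gait_coord_names <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
                       "hip_r", "knee_r", "ankle_r",
                       "hip_l", "knee_l", "ankle_l", "lumbar")

.gait_muscle_table <- function() {
  # per-leg roster: name, Fmax (N), lMopt (m), alpha_opt (rad),
  # path: list of (body, point) with bodies pelvis/thigh/shank/foot,
  # coords: spanned joints among hip/knee/ankle
  list(
    glut_max  = list(Fmax = 1944, lMopt = 0.142, alpha = 0.0,
                     path = list(c("pelvis", -0.150,  0.020),
                                 c("thigh",  -0.035, -0.180)),
                     joints = "hip"),
    iliopsoas = list(Fmax = 2186, lMopt = 0.102, alpha = 0.14,
                     path = list(c("pelvis",  0.040,  0.020),
                                 c("thigh",   0.020, -0.070)),
                     joints = "hip"),
    hamstrings = list(Fmax = 2594, lMopt = 0.104, alpha = 0.0,
                      path = list(c("pelvis", -0.125, -0.030),
                                  c("shank",  -0.035, -0.050)),
                      joints = c("hip", "knee")),
    rect_fem  = list(Fmax = 1169, lMopt = 0.075, alpha = 0.09,
                     path = list(c("pelvis",  0.045, -0.020),
                                 c("thigh",   0.045, -0.380),
                                 c("shank",   0.035, -0.070)),
                     joints = c("hip", "knee")),
    vasti     = list(Fmax = 4530, lMopt = 0.087, alpha = 0.05,
                     path = list(c("thigh",   0.030, -0.150),
                                 c("thigh",   0.045, -0.380),
                                 c("shank",   0.035, -0.070)),
                     joints = "knee"),
    bifemsh   = list(Fmax = 804, lMopt = 0.173, alpha = 0.40,
                     path = list(c("thigh",  -0.020, -0.260),
                                 c("shank",  -0.035, -0.060)),
                     joints = "knee"),
    gastroc   = list(Fmax = 2241, lMopt = 0.060, alpha = 0.30,
                     path = list(c("thigh",  -0.020, -0.360),
                                 c("shank",  -0.032, -0.400),
                                 c("foot",   -0.055, -0.020)),
                     joints = c("knee", "ankle")),
    soleus    = list(Fmax = 3549, lMopt = 0.050, alpha = 0.44,
                     path = list(c("shank",  -0.025, -0.150),
                                 c("shank",  -0.032, -0.400),
                                 c("foot",   -0.055, -0.020)),
                     joints = "ankle"),
    tib_ant   = list(Fmax = 1579, lMopt = 0.098, alpha = 0.09,
                     path = list(c("shank",   0.026, -0.180),
                                 c("shank",   0.034, -0.400),
                                 c("foot",    0.100, -0.015)),
                     joints = "ankle"))
}

#' Planar 10-dof, 18-muscle gait skeleton (synthetic fixture)
#'
#' Coordinates: pelvis translation (x, y) and tilt, right/left hip, knee and
#' ankle flexion, and lumbar (trunk) extension. Eight segments: pelvis,
#' torso (incl. head/arms), two thighs, two shanks, two feet. Nine muscles
#' per leg (hip flexor/extensor, biarticular hamstrings and rectus, vasti,
#' short biceps, gastrocnemius, soleus, tibialis anterior); the trunk is
#' driven by an ideal torque actuator. Two contact spheres per foot.
#'
#' Tendon slack lengths are calibrated so that at the neutral standing pose
#' each muscle-tendon unit length equals optimal fiber length (projected)
#' plus tendon slack.
#'
#' @param total_mass scales segment masses (kg).
#' @return Object of class `tt_gait_model`.
#' @export
planar_gait_skeleton <- function(total_mass = 75.337) {
  sc <- total_mass / 75.337
  seg <- function(name, m, I, com, len)
    segment_params(name, sc * m, sc * I, com, len)
  hip_in_pelvis <- c(0, -0.07)
  bodies <- list(
    list(name = "pelvis", parent = 0L, jtype = "base", coords = c(1L, 2L, 3L),
         jpos = c(0, 0),
         seg = seg("pelvis", 11.777, 0.1028, c(-0.07, 0), 0.20)),
    list(name = "torso", parent = 1L, jtype = "rev", coord = 10L,
         jpos = c(-0.10, 0.08),
         seg = seg("torso", 34.2366, 1.4745, c(0, 0.32), 0.60)),
    list(name = "thigh_r", parent = 1L, jtype = "rev", coord = 4L,
         jpos = hip_in_pelvis,
         seg = seg("thigh_r", 9.3014, 0.1339, c(0, -0.17), 0.40)),
    list(name = "shank_r", parent = 3L, jtype = "rev", coord = 5L,
         jpos = c(0, -0.40),
         seg = seg("shank_r", 3.7075, 0.0504, c(0, -0.1867), 0.43)),
    list(name = "foot_r", parent = 4L, jtype = "rev", coord = 6L,
         jpos = c(0, -0.43),
         seg = seg("foot_r", 1.250, 0.0041, c(0.05, -0.03), 0.22)),
    list(name = "thigh_l", parent = 1L, jtype = "rev", coord = 7L,
         jpos = hip_in_pelvis,
         seg = seg("thigh_l", 9.3014, 0.1339, c(0, -0.17), 0.40)),
    list(name = "shank_l", parent = 6L, jtype = "rev", coord = 8L,
         jpos = c(0, -0.40),
         seg = seg("shank_l", 3.7075, 0.0504, c(0, -0.1867), 0.43)),
    list(name = "foot_l", parent = 7L, jtype = "rev", coord = 9L,
         jpos = c(0, -0.43),
         seg = seg("foot_l", 1.250, 0.0041, c(0.05, -0.03), 0.22)))
  model <- new_planar_model(10L, bodies)

  spheres <- list(
    list(body = 5L, foot = "r",
         sphere = contact_sphere(c(-0.050, -0.060), 0.035)),
    list(body = 5L, foot = "r",
         sphere = contact_sphere(c(0.165, -0.060), 0.030)),
    list(body = 8L, foot = "l",
         sphere = contact_sphere(c(-0.050, -0.060), 0.035)),
    list(body = 8L, foot = "l",
         sphere = contact_sphere(c(0.165, -0.060), 0.030)))

  body_index <- c(pelvis = 1L, thigh = 3L, shank = 4L, foot = 5L)
  body_index_l <- c(pelvis = 1L, thigh = 6L, shank = 7L, foot = 8L)
  joint_index <- c(hip = 4L, knee = 5L, ankle = 6L)
  joint_index_l <- c(hip = 7L, knee = 8L, ankle = 9L)

  mt <- .gait_muscle_table()
  muscles <- list()
  for (side in c("r", "l")) {
    bi <- if (side == "r") body_index else body_index_l
    ji <- if (side == "r") joint_index else joint_index_l
    for (nm in names(mt)) {
      m <- mt[[nm]]
      path <- lapply(m$path, function(p)
        list(body = bi[[p[1]]], point = as.numeric(p[2:3])))
      muscles[[paste0(nm, "_", side)]] <- list(
        name = paste0(nm, "_", side),
        side = side, base = nm,
        path = path,
        coords = unname(ji[m$joints]),
        Fmax = m$Fmax, lMopt = m$lMopt, alpha = m$alpha)
    }
  }

  gait <- structure(list(model = model,
                         coord_names = .gait_coord_names,
                         ncoord = 10L,
                         muscles = muscles,
                         spheres = spheres,
                         activation = activation_constants(),
                         trunk = torque_actuator_params(),
                         gravity = 9.81,
                         standing_ty = 0.995),
                    class = "tt_gait_model")
  # calibrate tendon slack lengths at the neutral standing pose
  q0 <- c(0, gait$standing_ty, 0, rep(0, 7))
  for (nm in names(gait$muscles)) {
    mu <- gait$muscles[[nm]]
    l0 <- muscle_tendon_length(gait, mu, q0)
    lts <- l0 - mu$lMopt * cos(mu$alpha)
    if (lts <= 0) stop("non-positive calibrated tendon slack for ", nm)
    gait$muscles[[nm]]$params <- muscle_params(
      F_max = mu$Fmax, l_M_opt = mu$lMopt, l_T_slack = lts,
      alpha_opt = mu$alpha)
  }
  gait
}

#' @export
print.tt_gait_model <- function(x, ...) {
  cat("<tt_gait_model> 10 coordinates, 8 segments,",
      length(x$muscles), "muscles,", length(x$spheres),
      "contact spheres\n")
  invisible(x)
}

# exact muscle-tendon length of a via-point path at coordinates q
# (plain numeric or complex; used to generate fitting samples)
muscle_tendon_length <- function(gait, muscle, q) {
  n <- gait$ncoord
  zeros <- VecList(as.list(rep(0, n)))
  pts <- lapply(muscle$path, function(p) list(body = p$body, point = p$point))
  pass <- planar_pass(gait$model, q, zeros, zeros, pts)
  l <- 0
  for (j in seq_len(length(pts) - 1L)) {
    a <- pass$points[[j]]; b <- pass$points[[j + 1L]]
    l <- l + sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  }
  l
}

#' Sample synthetic muscle-tendon geometry for polynomial fitting
#'
#' Evaluates exact via-point muscle-tendon lengths on a dense grid over the
#' given joint ranges and computes reference moment arms by complex-step
#' differentiation (machine-precision derivatives of the exact geometry).
#'
#' @param gait a `tt_gait_model`.
#' @param muscle_name muscle to sample.
#' @param ranges named list mapping coordinate index to `c(lo, hi)` (rad);
#'   defaults to the gait problem's joint bounds.
#' @param n_per_dof grid resolution per spanned degree of freedom (default
#'   121 for 1-dof muscles, 26 for 2-dof).
#' @return List `(name, coords, Q, lmt, ma)` as consumed by
#'   [fit_polynomials()].
#' @export
sample_muscle_geometry <- function(gait, muscle_name, ranges = NULL,
                                   n_per_dof = NULL) {
  mu <- gait$muscles[[muscle_name]]
  if (is.null(mu)) stop("unknown muscle ", muscle_name)
  if (is.null(ranges)) ranges <- gait_joint_ranges()
  k <- length(mu$coords)
  if (is.null(n_per_dof)) n_per_dof <- if (k == 1) 121L else 26L
  grids <- lapply(mu$coords, function(ci) {
    r <- ranges[[gait$coord_names[ci]]]
    seq(r[1], r[2], length.out = n_per_dof)
  })
  Q <- as.matrix(do.call(expand.grid, grids))
  dimnames(Q) <- NULL
  q0 <- c(0, gait$standing_ty, 0, rep(0, 7))
  h <- 1e-30
  lmt <- numeric(nrow(Q))
  ma <- matrix(0, nrow(Q), k)
  for (i in seq_len(nrow(Q))) {
    q <- q0
    q[mu$coords] <- Q[i, ]
    lmt[i] <- muscle_tendon_length(gait, mu, q)
    for (v in seq_len(k)) {
      qc <- q + 0i
      qc[mu$coords[v]] <- qc[mu$coords[v]] + 1i * h
      ma[i, v] <- -Im(muscle_tendon_length(gait, mu, qc)) / h
    }
  }
  list(name = muscle_name, coords = mu$coords, Q = Q, lmt = lmt, ma = ma)
}

#' Joint ranges of the walking problem
#'
#' Manually set coordinate bounds (rad, m) also used as the polynomial
#' fitting ranges for the actuated joints.
#' @return Named list of `c(lo, hi)` per coordinate.
#' @export
gait_joint_ranges <- function() {
  list(pelvis_tx = c(-0.5, 2.0), pelvis_ty = c(0.80, 1.10),
       pelvis_tilt = c(-0.5, 0.5),
       hip_r = c(-0.8, 0.8), knee_r = c(-1.8, 0.05), ankle_r = c(-0.9, 0.7),
       hip_l = c(-0.8, 0.8), knee_l = c(-1.8, 0.05), ankle_l = c(-0.9, 0.7),
       lumbar = c(-0.5, 0.5))
}

#' Fit the polynomial geometry of all gait-model muscles
#'
#' Samples every muscle on a dense grid over the walking problem's joint
#' bounds and fits the lowest-order polynomials (capped at order 9) meeting
#' the 3 mm RMS length tolerance. Right- and left-leg muscles share the same
#' geometry, so right-side fits are cloned onto the left-side coordinates.
#'
#' @param gait a `tt_gait_model`.
#' @param max_order maximal polynomial order.
#' @return A `tt_polygeom` covering all 18 muscles.
#' @export
fit_gait_geometry <- function(gait, max_order = 9) {
  rnames <- names(gait$muscles)[vapply(gait$muscles, function(m)
    m$side == "r", TRUE)]
  samples <- lapply(rnames, function(nm) sample_muscle_geometry(gait, nm))
  geom_r <- fit_polynomials(samples, max_order = max_order)
  fits <- geom_r$muscles
  for (nm in rnames) {
    fit_l <- fits[[nm]]
    lnm <- sub("_r$", "_l", nm)
    fit_l$name <- lnm
    fit_l$coords <- gait$muscles[[lnm]]$coords
    fits[[lnm]] <- fit_l
  }
  structure(list(muscles = fits), class = "tt_polygeom")
}

## ---- skeleton inverse dynamics ---------------------------------------------

# sphere-center kinematics; returns list of per-sphere point kinematics
gait_sphere_kinematics <- function(gait, q, v) {
  n <- gait$ncoord
  zeros <- VecList(as.list(rep(0, n)))
  pts <- lapply(gait$spheres, function(s)
    list(body = s$body, point = s$sphere$location))
  pass <- planar_pass(gait$model, q, v, zeros, pts)
  pass$points
}

#' Foot-ground contact forces of the gait model
#'
#' @param gait a `tt_gait_model`.
#' @param q,v coordinates and velocities.
#' @return List per sphere: `list(fx, fy, px, py, foot)`.
#' @export
gait_contact_forces <- function(gait, q, v) {
  pk <- gait_sphere_kinematics(gait, q, v)
  lapply(seq_along(gait$spheres), function(j) {
    s <- gait$spheres[[j]]
    f <- contact_force_smooth(s$sphere, list(x = pk[[j]]$x, y = pk[[j]]$y),
                              list(x = pk[[j]]$vx, y = pk[[j]]$vy))
    list(fx = f[["fx"]], fy = f[["fy"]], px = pk[[j]]$x, py = pk[[j]]$y,
         foot = s$foot)
  })
}

#' Inverse dynamics of the planar gait skeleton
#'
#' Net generalized torques `T = f_s(q, v, u_dv)` including gravity, Coriolis
#' and the foot-ground contact wrenches mapped through the contact-point
#' Jacobians. The pelvis rows are the residual forces that the optimizer
#' drives to zero.
#'
#' @param gait a `tt_gait_model`.
#' @param state list with `q`, `v`, `udv` (length 10; numeric or taped).
#' @param contact `"auto"` (compute from the state), `NULL` (no contact), or
#'   a list of per-sphere forces `list(fx, fy)` applied at the sphere centers.
#' @return Generalized torque vector (length 10).
#' @export
skeleton_inverse_dynamics <- function(gait, state, contact = "auto") {
  q <- state$q; v <- state$v; udv <- state$udv
  pf <- list()
  if (identical(contact, "auto")) {
    pk <- gait_sphere_kinematics(gait, q, v)
    for (j in seq_along(gait$spheres)) {
      s <- gait$spheres[[j]]
      f <- contact_force_smooth(s$sphere, list(x = pk[[j]]$x, y = pk[[j]]$y),
                                list(x = pk[[j]]$vx, y = pk[[j]]$vy))
      pf[[j]] <- list(body = s$body, point = s$sphere$location,
                      fx = f[["fx"]], fy = f[["fy"]])
    }
  } else if (!is.null(contact)) {
    for (j in seq_along(contact)) {
      s <- gait$spheres[[j]]
      pf[[j]] <- list(body = s$body, point = s$sphere$location,
                      fx = contact[[j]]$fx, fy = contact[[j]]$fy)
    }
  }
  tl <- planar_id_core(gait$model, q, v, udv,
                       accel_offset = c(0, gait$gravity),
                       point_forces = pf)
  collapse_scalars(tl)
}

#' Kinetic and potential energy of the gait skeleton
#' @param gait a `tt_gait_model`.
#' @param q,v state.
#' @return List with `kinetic` and `potential`.
#' @export
gait_energy <- function(gait, q, v) {
  planar_energies(gait$model, q, v, accel_offset = c(0, gait$gravity))
}
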