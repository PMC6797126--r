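# 2D muscle-driven predictive walking: 18 muscles + 1 trunk torque actuator
# on the planar 10-dof skeleton. States: activations a, normalized tendon
# forces F_t, coordinates q, velocities v, trunk activation. Controls: the
# scaled state rates u_da, u_dFt, u_dv and the trunk excitation. The half
# gait cycle duration t_f is a free parameter; left-right symmetry maps the
# state at t_f back to the state at 0 and the average pelvis speed is
# prescribed (1.33 m/s). Only half a gait cycle is optimized.

gait_state_index <- function() {
  list(a = 1:18, ft = 19:36, q = 37:46, v = 47:56, atrunk = 57L,
       uda = 1:18, udft = 19:36, udv = 37:46, etrunk = 47L,
       tx = 37L)
}

# left-right state permutation (involution): leg blocks swap, the rest maps
# to itself; used for the periodicity/symmetry boundary rows
gait_symmetry_map <- function() {
  swap9 <- c(10:18, 1:9)
  qmap <- c(1:3, 7:9, 4:6, 10)
  as.integer(c(swap9, 18 + swap9, 36 + qmap, 46 + qmap, 57))
}

#' Build the 2D predictive walking optimal control problem
#'
#' Assembles all blocks of the half-gait-cycle problem: linear activation /
#' tendon-force / kinematic dynamics, Raasch activation-rate inequalities
#' (two per muscle per mesh interval), implicit Hill contraction equalities,
#' skeleton torque equalities (pelvis residual rows zero, muscle-driven rows
#' equal to the summed moment-arm times tendon-force contributions, trunk row
#' driven by the ideal actuator), left-right symmetric periodicity excluding
#' the pelvis forward position, and the prescribed-speed equality.
#'
#' @param gait a `tt_gait_model` (default fixture).
#' @param geom fitted polynomial geometry (default: [fit_gait_geometry()]).
#' @param speed prescribed average gait speed (m/s).
#' @param w1,w2,w3 objective weights on cubed activations, squared trunk
#'   excitations and squared scaled accelerations.
#' @param w_pen singular-arc penalty weight on the rate controls.
#' @return A `tt_ocp` with the model and geometry attached as attributes.
#' @export
build_gait2d <- function(gait = planar_gait_skeleton(),
                         geom = NULL, speed = 1.33,
                         w1 = 1, w2 = 1, w3 = 0.05, w_pen = 0.001) {
  if (is.null(geom)) geom <- fit_gait_geometry(gait)
  if (!all(names(gait$muscles) %in% names(geom$muscles)))
    stop("configuration error: missing fitted geometry for some muscles")
  ix <- gait_state_index()
  nm <- 18L; nq <- 10L
  nx <- 57L; nu <- 47L; np <- 1L
  mnames <- names(gait$muscles)
  act <- gait$activation; trunk <- gait$trunk
  jr <- gait_joint_ranges()
  q_lb <- vapply(gait$coord_names, function(cn) jr[[cn]][1], 0)
  q_ub <- vapply(gait$coord_names, function(cn) jr[[cn]][2], 0)
  v_lb <- c(-1, -2, -5, rep(-15, 6), -5)
  v_ub <- c(3, 2, 5, rep(15, 6), 5)
  udv_lb <- c(-50, -50, -150, rep(-300, 6), -150)
  udv_ub <- -udv_lb
  ft_ub <- 5

  x_lb <- c(rep(0, nm), rep(0, nm), q_lb, v_lb, -1)
  x_ub <- c(rep(1, nm), rep(ft_ub, nm), q_ub, v_ub, 1)
  u_lb <- c(rep(-act$tau_d * 10, nm), rep(-1, nm), udv_lb, -1)
  u_ub <- c(rep(act$tau_a * 10, nm), rep(1, nm), udv_ub, 1)
  p_lb <- 0.1; p_ub <- 1

  sx <- c(rep(1, nm), rep(ft_ub, nm), pmax(abs(q_lb), abs(q_ub)),
          pmax(abs(v_lb), abs(v_ub)), 1)
  sudv <- pmax(abs(udv_lb), abs(udv_ub))
  su <- c(rep(1, nm), rep(1, nm), sudv, 1)
  sp <- 1

  ## dynamics (affine): columns ordered (x, u, p)
  dyn_A <- matrix(0, nx, nx + nu + np)
  dyn_A[ix$a, nx + ix$uda] <- diag(nm) * act$s_da      # da/dt = s_da u_da
  dyn_A[ix$ft, nx + ix$udft] <- diag(nm) * 100         # dFt/dt = s_dFt u_dFt
  dyn_A[ix$q, ix$v] <- diag(nq)                        # dq/dt = v
  dyn_A[ix$v, nx + ix$udv] <- diag(nq)                 # dv/dt = u_dv
  dyn_A[ix$atrunk, ix$atrunk] <- -1 / trunk$tau
  dyn_A[ix$atrunk, nx + ix$etrunk] <- 1 / trunk$tau

  ## per-coordinate muscle torque index: which muscles span coordinate j
  mus_by_coord <- lapply(seq_len(nq), function(j) {
    hits <- which(vapply(mnames, function(n)
      j %in% gait$muscles[[n]]$coords, TRUE))
    hits
  })
  Fmax <- vapply(mnames, function(n) gait$muscles[[n]]$params$F_max, 0)

  pelvis_rows <- 1:3; leg_rows <- 4:9; lumbar_row <- 10L
  torque_scale <- c(rep(500, 3), rep(200, 6), trunk$scale)

  path_eq <- function(x, u, p, e) {
    a <- x[ix$a]; ft <- x[ix$ft]; q <- x[ix$q]; v <- x[ix$v]
    atr <- x[ix$atrunk]
    udft <- u[ix$udft]; udv <- u[ix$udv]
    res <- vector("list", nm + nq)
    # Hill contraction residuals, one per muscle
    mus_torque <- vector("list", nq)
    for (j in seq_len(nq)) mus_torque[[j]] <- 0
    for (m in seq_len(nm)) {
      mu <- gait$muscles[[mnames[m]]]
      fit <- geom$muscles[[mnames[m]]]
      qs <- lapply(fit$coords, function(c) q[c])
      vs <- lapply(fit$coords, function(c) v[c])
      ge <- muscle_geom_eval(fit, qs, vs)
      res[[m]] <- hill_residual(a[m], ge$lmt, ge$vmt, ft[m], udft[m],
                                mu$params, s_dFt = 100)
      for (kk in seq_along(fit$coords)) {
        j <- fit$coords[kk]
        mus_torque[[j]] <- zadd(mus_torque[[j]],
                                zmul(ge$ma[[kk]], ft[m] * mu$params$F_max))
      }
    }
    tq <- planar_id_core(gait$model, q, v, udv,
                         accel_offset = c(0, gait$gravity),
                         point_forces = gait_point_forces(gait, q, v))
    for (j in pelvis_rows) res[[nm + j]] <- tq[[j]]
    for (j in leg_rows) res[[nm + j]] <- tq[[j]] - mus_torque[[j]]
    res[[nm + lumbar_row]] <- tq[[lumbar_row]] - atr * trunk$scale
    res
  }

  ## Raasch inequalities: affine rows over (x, u, p)
  npi <- 2L * nm
  ineq_A <- matrix(0, npi, nx + nu + np)
  for (m in seq_len(nm)) {
    ineq_A[2 * m - 1, m] <- 1 / act$tau_d            # + a / tau_d
    ineq_A[2 * m - 1, nx + m] <- act$s_da            # + s_da u_da
    ineq_A[2 * m, m] <- 1 / act$tau_a
    ineq_A[2 * m, nx + m] <- act$s_da
  }
  ineq_b <- rep(0, npi)
  ineq_lb <- rep(c(0, -Inf), nm)
  ineq_ub <- rep(c(Inf, 1 / act$tau_a), nm)
  ineq_scale <- rep(act$s_da, npi)

  ## boundary rows: symmetry (56), prescribed speed (1), pelvis anchor (1)
  sym <- gait_symmetry_map()
  keep <- setdiff(seq_len(nx), ix$tx)
  nb <- length(keep) + 2L
  bnd_A <- matrix(0, nb, 2L * nx + np)
  for (r in seq_along(keep)) {
    j <- keep[r]
    bnd_A[r, j] <- -1                 # -x_j(0)
    bnd_A[r, nx + sym[j]] <- 1        # +x_sym(j)(tf)
  }
  bnd_A[nb - 1L, nx + ix$tx] <- 1     # speed row
  bnd_A[nb - 1L, ix$tx] <- -1
  bnd_A[nb - 1L, 2L * nx + 1L] <- -speed
  bnd_A[nb, ix$tx] <- 1               # anchor pelvis forward position at 0
  bnd_scale <- c(sx[keep], 1, 1)

  # The objective is normalized by the distance travelled d; the prescribed-
  # speed equality makes d = speed * t_f exactly on the feasible set, so the
  # normalisation is folded into the integrand (keeps the objective separable
  # per mesh interval, which the exact Hessian assembly exploits).
  integrand <- function(x, u, p, e) {
    a <- x[ix$a]
    uda <- u[ix$uda]; udft <- u[ix$udft]
    udv_s <- u[ix$udv] / sudv
    etr <- u[ix$etrunk]
    (w1 * sum(a^3) + w2 * etr^2 + w3 * sum(udv_s^2) +
       w_pen * (sum(uda^2) + sum(udft^2))) / (speed * p[1])
  }
  obj_post <- NULL

  ## nominal (tape recording point): mid-stance-like pose, all smooth
  q_nom <- c(0.3, gait$standing_ty - 0.02, 0, 0.15, -0.3, 0.02,
             -0.15, -0.3, 0.02, 0)
  v_nom <- c(1.33, 0, 0, rep(0, 7))
  x_nom <- c(rep(0.2, nm), rep(0.5, nm), q_nom, v_nom, 0)
  xf_nom <- x_nom
  xf_nom[ix$tx] <- x_nom[ix$tx] + speed * 0.55
  nominal <- list(
    x = x_nom, xf = xf_nom,
    u = c(rep(0.01, nm), rep(0.01, nm), rep(0, nq), 0),
    p = 0.55)

  ocp <- optimal_control_problem(
    nx = nx, nu = nu, np = np,
    x_names = c(paste0("a_", mnames), paste0("ft_", mnames),
                gait$coord_names, paste0("d", gait$coord_names), "a_trunk"),
    u_names = c(paste0("uda_", mnames), paste0("udft_", mnames),
                paste0("udv_", gait$coord_names), "e_trunk"),
    p_names = "t_f",
    x_lb = x_lb, x_ub = x_ub, u_lb = u_lb, u_ub = u_ub,
    p_lb = p_lb, p_ub = p_ub,
    scaling = scaling_set(sx, su, sp),
    horizon = "free",
    dyn_A = dyn_A,
    integrand = integrand, obj_post = obj_post,
    path_eq = path_eq,
    path_eq_scale = c(rep(1, nm), torque_scale),
    ineq_A = ineq_A, ineq_b = ineq_b,
    ineq_lb = ineq_lb, ineq_ub = ineq_ub, ineq_scale = ineq_scale,
    bnd_A = bnd_A, bnd_b = rep(0, nb), bnd_scale = bnd_scale,
    nominal = nominal)
  attr(ocp, "gait") <- gait
  attr(ocp, "geom") <- geom
  attr(ocp, "speed") <- speed
  attr(ocp, "canonical_guess") <- function(nlp)
    gait_canonical_guess(nlp, gait, geom, speed)
  attr(ocp, "problem_id") <- "gait2d"
  ocp
}

# taped point forces used inside the torque residual
gait_point_forces <- function(gait, q, v) {
  pk <- gait_sphere_kinematics(gait, q, v)
  lapply(seq_along(gait$spheres), function(j) {
    s <- gait$spheres[[j]]
    f <- contact_force_smooth(s$sphere, list(x = pk[[j]]$x, y = pk[[j]]$y),
                              list(x = pk[[j]]$vx, y = pk[[j]]$vy))
    list(body = s$body, point = s$sphere$location,
         fx = f[["fx"]], fy = f[["fy"]])
  })
}

# kinematic walking initial guess for the half gait cycle: the pelvis
# advances at the prescribed speed, the stance (right) foot stays flat and
# stationary on the ground, the swing (left) foot travels one stride with a
# small lift; leg joint angles by two-link inverse kinematics. Activations
# constant 0.1, tendon forces at static equilibrium, all rate controls zero.
gait_canonical_guess <- function(nlp, gait, geom, speed) {
  N <- nlp$N
  tf0 <- 0.55
  stride <- speed * tf0
  L1 <- 0.40; L2 <- 0.43
  ankle_h <- 0.095                      # standing ankle height
  ty <- 0.885                           # slightly crouched (IK reach margin)
  hip_off <- 0.07                       # hip center below pelvis origin
  leg_ik <- function(dx, dy) {
    # absolute thigh angle (from downward vertical) and knee angle for an
    # ankle at (dx, dy) relative to the hip, knee bending backward
    r <- min(sqrt(dx^2 + dy^2), 0.999 * (L1 + L2))
    kint <- acos(pmin(1, pmax(-1, (L1^2 + L2^2 - r^2) / (2 * L1 * L2))))
    knee <- -(pi - kint)
    a1 <- acos(pmin(1, pmax(-1, (L1^2 + r^2 - L2^2) / (2 * L1 * r))))
    hip <- atan2(dx, -dy) + a1
    c(hip, knee)
  }
  mnames <- names(gait$muscles)
  q_mid <- c(0, ty, 0, rep(0, 7))
  ge <- eval_lmt_vmt_ma(geom, q_mid, rep(0, 10))
  a0 <- 0.1
  ft0 <- vapply(mnames, function(nmm) {
    p <- gait$muscles[[nmm]]$params
    f <- function(ft) hill_residual(a0, ge$lmt[[nmm]], 0, ft, 0, p)
    tryCatch(stats::uniroot(f, c(1e-4, 4.9))$root, error = function(e) 0.05)
  }, 0)
  Q <- matrix(0, 10, N + 1L)
  for (i in 0:N) {
    s <- i / N
    px <- speed * tf0 * s
    hipx <- px; hipy <- ty - hip_off
    # stance (right) ankle fixed mid-stride on the ground, foot flat
    ax_r <- stride / 2
    ikr <- leg_ik(ax_r - hipx, ankle_h - hipy)
    # swing (left) ankle travels -stride/2 -> 3 stride/2 with a lift
    ax_l <- -stride / 2 + 2 * stride * s
    ay_l <- ankle_h + 0.03 * sin(pi * s)
    ikl <- leg_ik(ax_l - hipx, ay_l - hipy)
    qi <- c(px, ty, 0,
            ikr[1], ikr[2], -(ikr[1] + ikr[2]),    # flat stance foot
            ikl[1], ikl[2], -(ikl[1] + ikl[2]),
            0)
    # keep the guess strictly inside the joint bounds (the flat-foot ankle
    # angle can otherwise touch its limit during swing)
    jr <- gait_joint_ranges()
    for (j in 3:10) {
      r <- jr[[.gait_coord_names[j]]]
      qi[j] <- min(max(qi[j], r[1] + 0.01 * diff(r)), r[2] - 0.01 * diff(r))
    }
    Q[, i + 1L] <- qi
  }
  # velocities by finite differences of the mesh coordinates
  V <- matrix(0, 10, N + 1L)
  h <- tf0 / N
  V[, 2:N] <- (Q[, 3:(N + 1)] - Q[, 1:(N - 1)]) / (2 * h)
  V[, 1] <- (Q[, 2] - Q[, 1]) / h
  V[, N + 1L] <- (Q[, N + 1L] - Q[, N]) / h
  X <- rbind(matrix(a0, 18, N + 1L), matrix(ft0, 18, N + 1L), Q, V,
             matrix(0, 1, N + 1L))
  U <- matrix(0, 47L, N)
  nlp_pack(nlp, X = X, U = U, P = tf0)
}

#' Solve the 2D predictive walking problem
#'
#' @param N mesh intervals for the half gait cycle.
#' @param derivative `"ad"` or `"fd"`.
#' @param hessian Hessian mode; the distance-normalized objective requires
#'   `"lbfgs"` (the default).
#' @param gait,geom model and fitted geometry (defaults are built on the
#'   fly; pass them in to reuse across solves).
#' @param guess initial decision vector (default canonical).
#' @param ... passed to [solve_ocp()].
#' @return A `tt_solution` with gait extras (`gait`, `geom` attributes).
#' @export
predictive_gait <- function(N = 20, derivative = "ad", hessian = "lbfgs",
                            gait = planar_gait_skeleton(), geom = NULL,
                            guess = NULL, ...) {
  ocp <- build_gait2d(gait = gait, geom = geom)
  solve_ocp(ocp, N, derivative = derivative, hessian = hessian,
            guess = guess, ...)
}
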