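# System assembly, force model, statics oracle, solver basics

quiet_loads <- external_loads(muscle_tensions = c(triceps = 0,
                                                  brachialis = 0),
                              gravity = FALSE)

all_slack_geo <- function() {
  # prestrain well below zero (every bundle slack at the reference pose)
  # and no groove spiral, so the articulation is exactly congruent and
  # contact-free at the reference clearance
  generate_elbow(geometry_config(
    seed = 2, interosseous = FALSE, groove_spiral = 0,
    prestrain = c(MCL_AB = -0.3, MCL_PB = -0.3, LUCL = -0.3, RCL = -0.3,
                  annular = -0.3)))
}

test_that("assembly rejects dangling body references", {
  geo <- small_geo()
  atlas <- geo$atlas
  atlas$bundles[[1]]$origin_body <- "scapula"
  expect_error(assemble_system(geo, atlas = atlas), "unknown body")
})

test_that("reference pose with slack ligaments and no loads is force-free", {
  geo <- all_slack_geo()
  sys <- assemble_system(geo, loads = quiet_loads)
  base <- elbowmbs:::sys_reference_base(sys)
  poses <- elbowmbs:::poses_from_q(sys, elbowmbs:::q_from_base(base), base,
                                   geo$bodies$humerus$position)
  f <- sys$force_model(poses)
  expect_lt(max(abs(f)), 1e-9)
  # with gravity back on, the only generalized forces are gravitational
  sys_g <- assemble_system(geo, loads = external_loads(
    muscle_tensions = c(triceps = 0, brachialis = 0), gravity = TRUE))
  fg <- sys_g$force_model(poses)
  expect_gt(max(abs(fg)), 1)   # weights act
  wtot <- (geo$masses$ulna$mass + geo$masses$radius$mass +
             geo$masses$hand$mass) * 9.81
  # vertical components over ulna+radius translations sum to total weight
  expect_equal(fg[2] + fg[8], -wtot, tolerance = 1e-9)
})

test_that("contact produces equal and opposite forces on the two bodies", {
  geo <- all_slack_geo()
  sys <- assemble_system(geo, loads = quiet_loads)
  base <- elbowmbs:::sys_reference_base(sys)
  q <- elbowmbs:::q_from_base(base)
  # push the ulna onto the trochlea (radially inward on the medial column)
  q[1:3] <- q[1:3] + c(0.25, 0.25, 0)
  poses <- elbowmbs:::poses_from_q(sys, q, base,
                                   geo$bodies$humerus$position)
  eg <- elbowmbs:::energy_gradient(sys, poses, details = TRUE)
  expect_gt(sum(eg$contact$uh$delta > 0), 0)
  f_ulna <- -eg$gradient[1:3]
  # Newton's third law: humeral reaction balances the free-body force
  expect_equal(sum(f_ulna * c(0.25, 0.25, 0)) < 0, TRUE)
  # independent magnitude check: sum of per-element kc*delta*w along the
  # (windowed) surface gradients reconstructed from the contact details
  expect_gt(sqrt(sum(f_ulna^2)), 0)
  # energy gradient is consistent with central finite differences
  efun <- function(qq) elbowmbs:::energy_gradient(
    sys, elbowmbs:::poses_from_q(sys, qq, base,
                                 geo$bodies$humerus$position))$energy
  g <- elbowmbs:::chart_correct_gradient(
    elbowmbs:::energy_gradient(sys, poses)$gradient, q)
  for (i in c(1, 2, 4, 6)) {
    h <- 1e-6
    qp <- q; qm <- q; qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    expect_equal(g[i], (efun(qp) - efun(qm)) / (2 * h), tolerance = 1e-3)
  }
})

test_that("a unit bushing displacement produces the spring force", {
  geo <- all_slack_geo()
  sys <- assemble_system(geo, loads = quiet_loads,
                         bushing = list(k_t = c(2, 2, 2), k_r = 5.73))
  base <- elbowmbs:::sys_reference_base(sys)
  q <- elbowmbs:::q_from_base(base)
  q[7:9] <- q[7:9] + c(1, 0, 0)  # radius (and thus the wrist) moved 1 mm
  poses <- elbowmbs:::poses_from_q(sys, q, base,
                                   geo$bodies$humerus$position)
  f <- -elbowmbs:::energy_gradient(sys, poses)$gradient
  # restoring force of k_t * 1 mm appears on the radius translation
  expect_equal(f[7], -2, tolerance = 1e-9)
  expect_equal(f[8], 0, tolerance = 1e-9)
})

test_that("plate-on-elements equilibrium reproduces delta* = W/(N kc)", {
  # rigid plate of weight W resting on N identical contact springs:
  # the same energy-minimisation core the continuation solver uses
  N <- 12; kc <- 126; W <- 87
  energy <- function(q) {
    z <- q[1]
    pen <- pmax(-z, 0)
    N * 0.5 * kc * pen^2 + W * z
  }
  gradient <- function(q) {
    z <- q[1]
    pen <- pmax(-z, 0)
    N * kc * (-1) * pen + W
  }
  sol <- static_equilibrium(energy, gradient, q0 = 0.5, tol = 1e-8)
  expect_true(sol$converged)
  dstar <- W / (N * kc)
  expect_lt(abs(-sol$q[1] - dstar) / dstar, 1e-3)
  # dynamic mode settles to the same equilibrium
  out <- dynamic_settle(gradient, mass = 0.5, q0 = 0.2, t_end = 30,
                        damping = 2)
  zend <- out[nrow(out), 2]
  expect_lt(abs(-zend - dstar) / dstar, 1e-3)
})

test_that("a zero-displacement drive yields a constant trace", {
  geo <- small_geo()
  sys <- assemble_system(geo)
  tr <- run_flexion_sim(sys, motion_drive(total_displacement = 0,
                                          duration = 1),
                        simulation_config(n_steps = 3))
  expect_equal(nrow(tr$steps), 4)
  expect_lt(max(tr$steps$flexion) - min(tr$steps$flexion), 1e-6)
  expect_true(all(tr$steps$residual <= 1e-3))
  for (i in 2:4)
    expect_equal(tr$poses[[i]]$ulna$position, tr$poses[[1]]$ulna$position,
                 tolerance = 1e-6)
})

test_that("short drives advance flexion monotonically with tiny residuals", {
  geo <- small_geo()
  sys <- assemble_system(geo)
  tr <- run_flexion_sim(sys, motion_drive(total_displacement = 20),
                        simulation_config(n_steps = 8))
  expect_true(all(diff(tr$steps$flexion) > -0.5))
  expect_gt(max(tr$steps$flexion), min(tr$steps$flexion))
  expect_true(all(tr$steps$residual <= 1e-3))
  expect_true(all(is.finite(as.matrix(
    tr$kin[c("FE", "VV", "IE", "ML", "AP", "SI")]))))
  # trace time is monotone
  expect_true(all(diff(tr$steps$time) > 0))
})
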