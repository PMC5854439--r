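# Tissue domains, the monodomain stepper, and conduction velocity.

test_that("domain construction counts nodes and flags holes correctly", {
  dom <- tissue_domain("sheet", c(60, 60), dx = 0.3)
  expect_equal(dom$nx, 201L)
  expect_equal(dom$ny, 201L)
  expect_equal(dom$n_nodes, 201L * 201L)
  expect_true(all(dom$region == "RA_PM"))
  ann <- tissue_domain("annulus", c(30, 30), dx = 1, hole_radius = 5)
  inside <- basketmap:::wrap_dx(ann$surf[, "x"] - 15, Inf)^2 +
    (ann$surf[, "z"] - 15)^2 <= 25
  expect_true(all(ann$obstacle[inside]))
  expect_false(any(ann$obstacle[!inside]))
  expect_error(tissue_domain("sheet", c(10, 10), dx = -1), "dx")
})

test_that("a two-region sheet assigns every node deterministically and symmetrically", {
  half <- function(x, z) ifelse(x < 15, "RA_PM", "CT_BBRA")
  dom <- tissue_domain("sheet", c(30, 10), dx = 1, region = half)
  expect_setequal(unique(dom$region), c("RA_PM", "CT_BBRA"))
  expect_equal(sum(dom$region == "RA_PM"),
               sum(dom$surf[, "x"] < 15))
  expect_error(tissue_domain("sheet", c(10, 10), dx = 1, region = "NOPE"),
               "unknown region")
})

test_that("the diffusion operator conserves charge and respects no-flux boundaries", {
  dom <- tissue_domain("cylinder", c(20, 10), dx = 1,
                       holes = list(list(center = c(5, 5), radius = 2)))
  L <- basketmap:::build_laplacian(dom, 1)
  set.seed(1)
  V <- matrix(rnorm(dom$n_nodes), ncol = 1)
  s <- basketmap:::csr_mult(L, V)
  expect_lt(abs(sum(s)), 1e-9)          # conservative stencil
  expect_true(all(s[dom$obstacle] == 0))  # obstacles carry zero flux
  # uniform potential has zero Laplacian
  expect_lt(max(abs(basketmap:::csr_mult(L, matrix(1, dom$n_nodes)))), 1e-12)
})

test_that("a uniform resting sheet stays at rest", {
  dom <- tissue_domain("sheet", c(5, 5), dx = 0.5)
  states <- matrix(crn_initial_state(), 21, dom$n_nodes)
  mov <- run_tissue(dom, "control", list(), duration = 2, dt = 0.02,
                    record_dt = 1, init = states)
  expect_lt(max(abs(mov$frames - mov$frames[1, 1])), 0.01)
})

test_that("the reaction-only limit reproduces the single-cell trace", {
  dom <- tissue_domain("sheet", c(2, 0), dx = 1, D = 1e-12)
  states <- matrix(crn_initial_state(), 21, dom$n_nodes)
  stim <- stimulus(seq_len(dom$n_nodes), onset = 0, amplitude = 28,
                   duration = 2, period = 400, count = 2)
  mov <- run_tissue(dom, "control", list(stim), duration = 800, dt = 0.02,
                    record_dt = 1, init = states)
  m <- membrane_model("RA_PM", "control")
  ref <- basketmap:::crn_pace_cpp(crn_initial_state(), m$scalars, 400, 2,
                                  28, 2, 0.02, -1, 1)
  expect_lt(max(abs(mov$frames[1, ] - ref$vm[seq_len(ncol(mov$frames))])),
            0.5)
  a_tissue <- basketmap:::activation_times_vm(mov, after_ms = 400)
  expect_true(all(is.finite(a_tissue)))
})

test_that("the stability bound on dt is enforced", {
  dom <- tissue_domain("sheet", c(5, 5), dx = 0.2, D = 1.5)
  expect_error(run_tissue(dom, "control", list(), duration = 1, dt = 0.02),
               "stability")
})

test_that("a point stimulus on an isotropic sheet gives circular isochrones", {
  dom <- tissue_domain("sheet", c(30, 30), dx = 0.5, D = 0.1)
  states <- matrix(pace_cell(membrane_model("RA_PM", "control"),
                             pacing_protocol(500, 20))$final_state,
                   21, dom$n_nodes)
  stim <- stimulus(nodes_in_disk(dom, c(15, 15), 1.2), onset = 0,
                   amplitude = 56, duration = 2)
  mov <- run_tissue(dom, "control", list(stim), duration = 45, dt = 0.02,
                    record_dt = 0.5, init = states)
  at <- basketmap:::activation_times_vm(mov)
  t_x <- mean(c(at[basketmap:::node_id(dom, 61, 31)],
                at[basketmap:::node_id(dom, 1, 31)]))
  t_z <- mean(c(at[basketmap:::node_id(dom, 31, 61)],
                at[basketmap:::node_id(dom, 31, 1)]))
  expect_true(is.finite(t_x) && is.finite(t_z))
  expect_lt(max(t_x, t_z) / min(t_x, t_z), 1.05)
})

test_that("2:1 anisotropy elongates isochrones by sqrt(2)", {
  # resolved regime: wavefront width well above the grid spacing
  dom <- tissue_domain("sheet", c(30, 30), dx = 0.25, D = c(0.4, 0.2))
  states <- matrix(pace_cell(membrane_model("RA_PM", "control"),
                             pacing_protocol(500, 20))$final_state,
                   21, dom$n_nodes)
  stim <- stimulus(nodes_in_disk(dom, c(15, 15), 1.2), onset = 0,
                   amplitude = 56, duration = 2)
  mov <- run_tissue(dom, "control", list(stim), duration = 40, dt = 0.02,
                    record_dt = 0.5, init = states)
  at <- basketmap:::activation_times_vm(mov)
  n <- dom$nx; mid <- (n + 1) %/% 2
  t_x <- mean(c(at[basketmap:::node_id(dom, n, mid)],
                at[basketmap:::node_id(dom, 1, mid)]))
  t_z <- mean(c(at[basketmap:::node_id(dom, mid, n)],
                at[basketmap:::node_id(dom, mid, 1)]))
  expect_equal(t_z / t_x, sqrt(2), tolerance = 0.05)
})

test_that("conduction velocity scales as sqrt(D) in the resolved regime", {
  c1 <- measure_cv("control", bcl = 500, D = 0.15, dx = 0.15,
                   init_beats = 60)$cv_cm_s
  c2 <- measure_cv("control", bcl = 500, D = 0.6, dx = 0.15,
                   init_beats = 60)$cv_cm_s
  expect_equal(c2 / c1, 2, tolerance = 0.05)
})

test_that("CV converges spatially once the wavefront is resolved", {
  a <- measure_cv("control", bcl = 500, D = 0.6, dx = 0.3,
                  init_beats = 60)$cv_cm_s
  b <- measure_cv("control", bcl = 500, D = 0.6, dx = 0.15,
                  init_beats = 60)$cv_cm_s
  expect_lt(abs(a / b - 1), 0.03)
})

test_that("conduction block is signalled, not returned as a silent zero", {
  expect_error(measure_cv("control", bcl = 500, D = 1e-6, dx = 0.3,
                          init_beats = 5), "block")
})

test_that("cross-field S1-S2 initiation creates reentry on a sheet", {
  dom <- tissue_domain("sheet", c(40, 40), dx = 0.5, D = 0.1)
  states <- matrix(pace_cell(membrane_model("RA_PM", "cAF"),
                             pacing_protocol(300, 30))$final_state,
                   21, dom$n_nodes)
  mov <- run_tissue(dom, "cAF", cross_field_stimuli(dom, t_s2 = 200),
                    duration = 800, dt = 0.02, record_dt = 1,
                    init = states, conductivity_scale = 0.85)
  pm <- phase_movie(mov, trim_ms = 150)
  det <- detect_ps(pm)
  tracks <- track_rotations(track_ps(det, 5, 5), pm)
  expect_gte(length(filter_rotors(tracks, 1)), 1)
})

test_that("repeated runs with identical inputs are bit-identical", {
  dom <- tissue_domain("sheet", c(6, 6), dx = 0.5)
  states <- matrix(crn_initial_state(), 21, dom$n_nodes)
  stim <- stimulus(nodes_in_disk(dom, c(3, 3), 1), onset = 1,
                   amplitude = 56, duration = 2)
  m1 <- run_tissue(dom, "cAF", list(stim), duration = 30, dt = 0.02,
                   record_dt = 1, init = states)
  m2 <- run_tissue(dom, "cAF", list(stim), duration = 30, dt = 0.02,
                   record_dt = 1, init = states)
  expect_identical(m1$frames, m2$frames)
})
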