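# Superposition, correlation, contacts and network construction.

random_node_traj <- function(n_nodes = 5L, n_frames = 20L, seed = 1L,
                             kinds = rep("residue", n_nodes)) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(3 * n_nodes, sd = 4), n_nodes, 3)
    xyz <- t(vapply(seq_len(n_frames), function(f) {
      as.vector(t(base + matrix(rnorm(3 * n_nodes, sd = 0.4), n_nodes, 3)))
    }, numeric(3 * n_nodes)))
    fake_node_traj(xyz, fake_partition(kinds))
  })
}

rigid_move <- function(xyz, angle, shift) {
  rot <- matrix(c(cos(angle), -sin(angle), 0,
                  sin(angle), cos(angle), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  t(apply(xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(m %*% t(rot) + matrix(shift, nrow(m), 3, byrow = TRUE)))
  }))
}

test_that("superposition removes pure rigid motion and is idempotent", {
  withr::with_seed(10, {
    base <- matrix(rnorm(15, sd = 5), 5, 3)
    frames <- t(vapply(1:12, function(f) {
      ang <- f * 0.3
      rot <- matrix(c(cos(ang), -sin(ang), 0,
                      sin(ang), cos(ang), 0, 0, 0, 1), 3, 3, byrow = TRUE)
      as.vector(t(base %*% t(rot) + matrix(c(f, -f, 2 * f), 5, 3, byrow = TRUE)))
    }, numeric(15)))
  })
  ntr <- fake_node_traj(frames, fake_partition(rep("residue", 5)))
  sup <- superpose_frames(ntr)
  expect_lt(max(apply(sup$xyz, 2, var)), 1e-10)
  again <- superpose_frames(sup)
  expect_lt(max(abs(again$xyz - sup$xyz)), 1e-9)
})

test_that("superposition matches an independent quaternion oracle", {
  ntr <- random_node_traj(n_nodes = 5L, n_frames = 20L, seed = 21L)
  sup <- superpose_frames(ntr, reference = "first_frame")
  ref <- matrix(ntr$xyz[1, ], ncol = 3, byrow = TRUE)
  for (f in c(2, 7, 20)) {
    mob <- matrix(ntr$xyz[f, ], ncol = 3, byrow = TRUE)
    oracle <- quaternion_align(mob, ref)
    expect_lt(max(abs(matrix(sup$xyz[f, ], ncol = 3, byrow = TRUE) - oracle)),
              1e-8)
  }
})

test_that("degenerate collinear node sets refuse superposition", {
  xyz <- t(vapply(1:5, function(f) {
    as.vector(t(cbind(1:4, 0, 0)))
  }, numeric(12)))
  ntr <- fake_node_traj(xyz, fake_partition(rep("residue", 4)))
  expect_error(superpose_frames(ntr), class = "fqcross_error_superposition")
})

test_that("correlation handles perfect, anti- and hand-computed cases", {
  # node 2 mirrors node 1 exactly; node 3 is its negation
  d1 <- c(1, 0, 0, -1, 0, 0, 0.5, 0.5, 0, -0.5, -0.5, 0)
  xyz <- t(vapply(1:4, function(f) {
    delta <- d1[(3 * f - 2):(3 * f)]
    c(delta, delta, -delta)
  }, numeric(9)))
  ntr <- fake_node_traj(xyz, fake_partition(rep("residue", 3)))
  cm <- correlation_matrix(ntr)
  expect_equal(cm[1, 2], 1, tolerance = 1e-12)
  expect_equal(cm[1, 3], -1, tolerance = 1e-12)

  # 3-frame, 2-node hand example: C12 = (1/3) / sqrt((2/3)(2/3)) = 0.5
  xyz2 <- rbind(c(1, 0, 0, 1, 0, 0),
                c(-1, 0, 0, 0, 0, 0),
                c(0, 0, 0, -1, 0, 0))
  cm2 <- correlation_matrix(fake_node_traj(xyz2,
                                           fake_partition(rep("residue", 2))))
  expect_equal(cm2[1, 2], 0.5, tolerance = 1e-12)
})

test_that("correlation matrix is symmetric with unit diagonal and bounded", {
  ntr <- random_node_traj(n_nodes = 8L, n_frames = 40L, seed = 31L)
  cm <- correlation_matrix(ntr)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, 8), tolerance = 1e-9)
  expect_true(all(abs(cm) <= 1 + 1e-9))
})

test_that("correlation agrees with the independent bio3d dccm", {
  ntr <- random_node_traj(n_nodes = 6L, n_frames = 60L, seed = 41L)
  cm <- correlation_matrix(ntr)
  ref <- bio3d::dccm.xyz(ntr$xyz)
  expect_lt(max(abs(unclass(cm) - unclass(ref))), 1e-8)
})

test_that("a frozen node makes the correlation undefined", {
  xyz <- rbind(c(0, 0, 0, 1, 2, 3), c(1, 0, 0, 1, 2, 3), c(0, 1, 0, 1, 2, 3))
  ntr <- fake_node_traj(xyz, fake_partition(rep("residue", 2)))
  expect_error(correlation_matrix(ntr), "zero total fluctuation",
               class = "fqcross_error_degenerate")
})

test_that("rigid transformation of all frames leaves the correlation unchanged", {
  ntr <- random_node_traj(n_nodes = 6L, n_frames = 30L, seed = 51L)
  c1 <- correlation_matrix(superpose_frames(ntr))
  moved <- fake_node_traj(rigid_move(ntr$xyz, 0.9, c(4, -3, 7)),
                          ntr$partition)
  c2 <- correlation_matrix(superpose_frames(moved))
  expect_lt(max(abs(c1 - c2)), 1e-9)
})

test_that("contacts respect cutoff, persistence and inclusive bounds", {
  mk_traj <- function(dists, n_frames) {
    xyz <- t(vapply(seq_len(n_frames), function(f) {
      c(0, 0, 0, dists[f], 0, 0)
    }, numeric(6)))
    fake_traj(xyz, 2)
  }
  part <- fake_partition(c("residue", "residue"), resseq = c(1L, 5L))
  close4 <- contact_map(mk_traj(rep(3, 8), 8), part)
  expect_true(close4$in_contact[1, 2])
  far <- contact_map(mk_traj(rep(10, 8), 8), part)
  expect_false(far$in_contact[1, 2])
  # exactly 4.5 A in exactly 75% of frames -> contact (both bounds inclusive)
  boundary <- contact_map(mk_traj(c(4.5, 4.5, 4.5, 10), 4), part)
  expect_true(boundary$in_contact[1, 2])
  under <- contact_map(mk_traj(c(4.5, 4.5, 10, 10), 4), part)
  expect_false(under$in_contact[1, 2])
})

test_that("sequence neighbours stay edge-eligible regardless of distance", {
  xyz <- t(vapply(1:4, function(f) c(0, 0, 0, 50, 0, 0), numeric(6)))
  part <- fake_partition(c("residue", "residue"), resseq = c(1L, 2L))
  cm <- contact_map(fake_traj(xyz, 2), part)
  expect_true(cm$in_contact[1, 2])
})

test_that("contact parameters are validated", {
  traj <- fake_traj(matrix(0, 3, 6), 2)
  part <- fake_partition(c("residue", "residue"), resseq = c(1L, 5L))
  expect_error(contact_map(traj, part, distance_cutoff = -1),
               class = "fqcross_error_config")
  expect_error(contact_map(traj, part, min_frame_fraction = 0),
               class = "fqcross_error_config")
  expect_error(contact_map(traj, part, min_frame_fraction = 1.2),
               class = "fqcross_error_config")
})

test_that("network weights are -ln|C| with zero-correlation edges dropped", {
  cmat <- diag(3)
  cmat[1, 2] <- cmat[2, 1] <- 1
  cmat[2, 3] <- cmat[3, 2] <- 0.1
  cmat[1, 3] <- cmat[3, 1] <- 0
  contacts <- structure(list(in_contact = matrix(TRUE, 3, 3) & !diag(3),
                             params = list()), class = "fq_contact_map")
  expect_warning(net <- build_network(cmat, contacts), "zero")
  e <- net$edges
  expect_equal(nrow(e), 2)
  expect_equal(e$weight[e$i == 1 & e$j == 2], 0)
  expect_equal(e$weight[e$i == 2 & e$j == 3], 2.302585092994046,
               tolerance = 1e-12)
  # monotone: larger |C| means smaller weight
  expect_true(all(diff(e$weight[order(abs(e$cij))]) <= 0))
})

test_that("empirical network correlation converges to the generator truth", {
  spec <- trajectory_spec(n_frames = 5000L, seed = 77L)
  sim <- simulate_trajectory(make_complex(spec))
  cm <- correlation_matrix(node_trajectory(sim$trajectory, sim$partition))
  expect_lt(max(abs(unclass(cm) - sim$truth$correlation)), 0.05)
})
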