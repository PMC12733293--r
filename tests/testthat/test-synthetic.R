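# The synthetic complex/trajectory/panel generator and its ground truth.

test_that("complex generation is deterministic and geometry-aware", {
  s1 <- make_complex(trajectory_spec(n_residues = 30L, seed = 1L))
  s2 <- make_complex(trajectory_spec(n_residues = 30L, seed = 1L))
  expect_identical(s1$system$atoms, s2$system$atoms)
  s3 <- make_complex(trajectory_spec(n_residues = 30L, seed = 2L))
  expect_false(identical(s1$system$atoms, s3$system$atoms))
  expect_equal(nrow(unique(s1$system$atoms[s1$system$atoms$record == "ATOM",
                                           c("chain", "resseq")])), 30)
})

test_that("bound ligands touch the site and detached ligands are far away", {
  cx <- make_complex(trajectory_spec(seed = 4L))
  a <- cx$system$atoms
  lig <- a[a$record == "HETATM", ]
  prot <- a[a$record == "ATOM", ]
  min_d_per_res <- vapply(split(prot, prot$resseq), function(p) {
    min(sqrt(outer(p$x, lig$x, "-")^2 + outer(p$y, lig$y, "-")^2 +
               outer(p$z, lig$z, "-")^2))
  }, numeric(1))
  expect_gte(sum(min_d_per_res <= 4.5), cx$spec$n_site_residues)

  det <- make_complex(trajectory_spec(geometry = "detached", seed = 4L))
  ad <- det$system$atoms
  ligd <- ad[ad$record == "HETATM", ]
  protd <- ad[ad$record == "ATOM", ]
  min_d <- min(sqrt(outer(protd$x, ligd$x, "-")^2 +
                      outer(protd$y, ligd$y, "-")^2 +
                      outer(protd$z, ligd$z, "-")^2))
  expect_gt(min_d, 10)
})

test_that("a bound pose needs enough residues to form the pocket", {
  expect_error(make_complex(trajectory_spec(n_residues = 12L)),
               class = "fqcross_error_generation")
  # detached placement has no pocket requirement
  expect_s3_class(make_complex(trajectory_spec(n_residues = 12L,
                                               geometry = "detached")),
                  "fq_complex")
})

test_that("trajectories are seed-deterministic with PSD targets", {
  spec <- trajectory_spec(n_frames = 50L, seed = 6L)
  cx <- make_complex(spec)
  t1 <- simulate_trajectory(cx)
  t2 <- simulate_trajectory(cx)
  expect_identical(t1$trajectory$xyz, t2$trajectory$xyz)
  ev <- eigen(t1$truth$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_lt(t1$truth$psd_adjustment, 0.1)
  expect_equal(t1$truth$label, "binder")
  expect_equal(simulate_trajectory(
    make_complex(trajectory_spec(coupling_rho = 0, n_frames = 50L))
  )$truth$label, "non_binder")
})

test_that("uncoupled ligands show near-zero empirical correlation at 5000 frames", {
  spec <- trajectory_spec(coupling_rho = 0, n_frames = 5000L, seed = 13L)
  sim <- simulate_trajectory(make_complex(spec))
  cm <- correlation_matrix(node_trajectory(sim$trajectory, sim$partition))
  lig <- which(sim$partition$kind == "ligand")
  prot <- which(sim$partition$kind == "residue")
  expect_lt(mean(abs(cm[lig, prot])), 0.05)
})

test_that("coupled ligand-site correlations recover the requested coupling", {
  spec <- trajectory_spec(coupling_rho = 0.8, n_frames = 5000L, seed = 14L)
  sim <- simulate_trajectory(make_complex(spec))
  cm <- correlation_matrix(node_trajectory(sim$trajectory, sim$partition))
  lig <- which(sim$partition$kind == "ligand")
  site <- sim$truth$site_residues
  expect_lt(max(abs(cm[lig, site] - 0.8)), 0.05)
})

test_that("four-node ligands partition and simulate cleanly", {
  spec <- trajectory_spec(ligand_nodes = 4L, n_frames = 50L, seed = 15L)
  sim <- simulate_trajectory(make_complex(spec))
  expect_equal(sum(sim$partition$kind == "ligand"), 4)
  expect_equal(nrow(sim$partition), spec$n_residues + 4)
})

test_that("the ELISA panel generator honors truth, noise and seeding", {
  p1 <- simulate_elisa_panel(c(A = 1, B = NA), noise_cv = 0.03, seed = 9L)
  p2 <- simulate_elisa_panel(c(A = 1, B = NA), noise_cv = 0.03, seed = 9L)
  expect_identical(p1, p2)
  expect_equal(length(unique(p1$concentration)), 8)
  expect_equal(range(p1$concentration), c(0.001, 167))
  # flat analyte stays near the upper asymptote
  expect_lt(max(abs(p1$od[p1$analyte == "B"] - 2) / 2), 0.2)
})

test_that("the fixture writer emits a readable corpus", {
  dir <- withr::local_tempdir()
  write_fixture_set(dir, seed = 2L, n_frames = 20L)
  sys <- read_structure(file.path(dir, "synthetic_bound.pdb"))
  traj <- read_trajectory(file.path(dir, "synthetic_bound.xyz"), sys)
  expect_equal(nrow(traj$xyz), 20)
  nm <- read_node_map(file.path(dir, "synthetic_bound_node_map.tsv"))
  part <- partition_system(sys, nm)
  expect_equal(sum(part$kind == "ligand"), 3)
  truth <- readr::read_tsv(file.path(dir, "synthetic_detached_truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(truth$label, "non_binder")
})

test_that("invalid specs are rejected", {
  expect_error(trajectory_spec(ligand_nodes = 5L),
               class = "fqcross_error_config")
  expect_error(trajectory_spec(coupling_rho = 1.2),
               class = "fqcross_error_config")
  expect_error(trajectory_spec(n_site_residues = 99L),
               class = "fqcross_error_config")
  expect_error(simulate_elisa_panel(c(A = 1), noise_cv = -0.1),
               class = "fqcross_error_config")
})
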