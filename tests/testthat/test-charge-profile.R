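test_that("a single unit charge yields the textbook layer density", {
  # +1 e at z = 1.02 above a midplane-defining scaffold, box 5 x 5 -> area 25
  extra <- atom_row(0L, 9L, "KOR105", "N1", "N_PLUS", 1)
  sc <- scaffold()
  sc$coords <- sc$coords / 2  # keep scaffold inside the 5-nm box
  sc$coords[, 3] <- rep(c(1.8, 1.9, 1.8, 1.9, -1.8, -1.9, -1.8, -1.9))
  at <- rbind(sc$atoms, transform(extra, atom_id = 9L))
  co <- rbind(sc$coords, c(2, 2, 1.02))
  # neutralise the scaffold so only the probe charge contributes
  at$partial_charge[at$species == "DOPC"] <- 0
  traj <- mk_traj(at, co, box = c(5, 5, 10))
  prof <- compute_charge_profile(traj, list(ion = select_atoms(traj, role = "N_PLUS")),
                                 dz = 0.05, step = 0.1)
  expect_equal(unname(prof$densities[prof$z_grid == 1.0, "ion"]), 1 / (25 * 0.1))
  expect_equal(sum(prof$densities[, "ion"] != 0), 1L)
})

test_that("a globally neutral system integrates to zero charge", {
  sys <- generate_system(synthetic_spec(
    n_lipids_per_leaflet = 36, n_frames = 5, seed = 31,
    surfactants = list(KOR105 = list(count = 10, eta0_deg = 130,
                                     theta0_deg = 150, kappa = 8,
                                     nplus_depth_z = 1.9),
                       SDS = list(count = 10, eta0_deg = NA, theta0_deg = 160,
                                  kappa = 10, nplus_depth_z = 1.8))))
  traj <- sys$trajectory
  prof <- compute_charge_profile(traj, list(all = seq_len(n_atoms(traj))))
  total <- sum(prof$densities[, "all"]) * prof$area_xy * 2 * prof$dz
  expect_lt(abs(total), 1e-6)
})

test_that("each group's integrated profile equals its total charge", {
  sys <- generate_system(synthetic_spec(n_lipids_per_leaflet = 25,
                                        n_frames = 4, seed = 13))
  traj <- sys$trajectory
  groups <- list(P = select_atoms(traj, role = "LIPID_P"),
                 N = select_atoms(traj, role = "LIPID_N"))
  prof <- compute_charge_profile(traj, groups)
  for (g in names(groups)) {
    integral <- sum(prof$densities[, g]) * prof$area_xy * 2 * prof$dz
    expect_equal(integral, sum(traj$atoms$partial_charge[groups[[g]]]),
                 tolerance = 1e-10)
  }
})

test_that("charge planes are recovered at their placed depths", {
  # -1 e at +/-1.8 (P), +1 e at +/-1.9 (N), Gaussian jitter 0.05 nm
  sys <- generate_system(synthetic_spec(n_lipids_per_leaflet = 64,
                                        roughness_sigma = 0.05,
                                        n_frames = 20, seed = 41))
  traj <- sys$trajectory
  prof <- compute_charge_profile(traj,
                                 list(DOPC = select_atoms(traj, species = "DOPC")))
  pk <- find_extrema(prof, "DOPC")
  neg <- pk$peaks[pk$peaks$sign == "-", ]
  pos <- pk$peaks[pk$peaks$sign == "+", ]
  expect_lte(min(abs(abs(neg$z_nm[1:2]) - 1.8)), 0.1)
  expect_lte(max(abs(abs(neg$z_nm[1:2]) - 1.8)), 0.1)
  expect_lte(max(abs(abs(pos$z_nm[1:2]) - 1.9)), 0.1)
  expect_equal(peak_separation(pk, "-"), 3.6, tolerance = 0.1 / 3.6)
})

test_that("overlapping layers (dz > step/2) keep per-window normalisation", {
  sys <- generate_system(synthetic_spec(n_lipids_per_leaflet = 16,
                                        n_frames = 2, seed = 7))
  traj <- sys$trajectory
  g <- list(P = select_atoms(traj, role = "LIPID_P"))
  tiled <- compute_charge_profile(traj, g, dz = 0.05, step = 0.1)
  wide <- compute_charge_profile(traj, g, dz = 0.2, step = 0.1)
  # overlapping windows smooth the profile but cannot exceed tiled peak density
  expect_lte(max(abs(wide$densities)), max(abs(tiled$densities)) + 1e-12)
  # doubling dz and step together conserves the integrated charge exactly
  dbl <- compute_charge_profile(traj, g, dz = 0.1, step = 0.2)
  expect_equal(sum(dbl$densities[, "P"]) * dbl$area_xy * 2 * dbl$dz,
               sum(tiled$densities[, "P"]) * tiled$area_xy * 2 * tiled$dz,
               tolerance = 1e-10)
})

test_that("profiles are invariant under a rigid z-translation (recentering)", {
  sys <- generate_system(synthetic_spec(n_lipids_per_leaflet = 25,
                                        n_frames = 3, seed = 17))
  traj <- sys$trajectory
  g <- list(DOPC = select_atoms(traj, species = "DOPC"))
  p0 <- compute_charge_profile(traj, g)
  shifted <- traj
  for (f in seq_along(shifted$frames))
    shifted$frames[[f]]$coords[, 3] <- shifted$frames[[f]]$coords[, 3] + 1.23
  p1 <- compute_charge_profile(shifted, g)
  expect_equal(p1$densities, p0$densities, tolerance = 1e-12)
})

test_that("symmetric bilayers give even profiles within Monte-Carlo error", {
  sys <- generate_system(synthetic_spec(n_lipids_per_leaflet = 64,
                                        n_frames = 40, seed = 23))
  traj <- sys$trajectory
  g <- list(DOPC = select_atoms(traj, species = "DOPC"))
  # per-frame profiles give the Monte-Carlo SE per bin
  per_frame <- sapply(seq_len(n_frames(traj)), function(f) {
    w <- c(traj$frames[[f]]$time, traj$frames[[f]]$time)
    compute_charge_profile(traj, g, window = w)$densities[, 1]
  })
  m <- rowMeans(per_frame)
  se <- apply(per_frame, 1, sd) / sqrt(ncol(per_frame))
  flip <- rev(seq_along(m))  # grid is symmetric about zero
  tol <- 3 * sqrt(se^2 + se[flip]^2) + 1e-12
  expect_true(all(abs(m - m[flip]) <= tol))
})

test_that("find_extrema matches a brute-force scan and handles degenerate input", {
  set.seed(99)
  sc <- scaffold()
  traj <- mk_traj(sc$atoms, sc$coords)
  for (rep in 1:20) {
    zg <- seq(-3.5, 3.5, 0.1)
    d <- as.vector(stats::filter(rnorm(length(zg)), rep(1 / 5, 5), circular = TRUE))
    prof <- structure(list(z_grid = zg,
                           densities = matrix(d, ncol = 1,
                                              dimnames = list(NULL, "g")),
                           area_xy = 25, dz = 0.05, step = 0.1,
                           window_frames = 1L, n_frames = 1L,
                           group_charge = c(g = 0), center_on = "lipid_p"),
                      class = "memion_charge_profile")
    floor_ <- 3 * median(abs(d[abs(zg) >= 2.5]))
    got <- find_extrema(prof, "g")
    want <- scan_extrema(zg, d, floor_)
    expect_equal(got$peaks$z_nm, want$z_nm)
    expect_equal(got$peaks$amplitude, want$amplitude)
  }
  # all-zero profile -> empty peak set
  zero <- compute_charge_profile(
    mk_traj(transform(sc$atoms, partial_charge = 0), sc$coords),
    list(g = 1:8))
  expect_equal(nrow(find_extrema(zero, "g")$peaks), 0L)
  expect_error(find_extrema(zero, "missing"), "not present")
})

test_that("an empty group warns and yields a zero profile", {
  sc <- scaffold()
  traj <- mk_traj(sc$atoms, sc$coords)
  expect_warning(prof <- compute_charge_profile(traj, list(none = integer(0))),
                 "selects no atoms")
  expect_true(all(prof$densities[, "none"] == 0))
})
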