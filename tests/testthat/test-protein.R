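test_that("variable enumeration reproduces the pentapeptide dimension", {
  inst <- enumerate_variables("YGGFM")
  expect_identical(inst$m, 19L)
  # 2 backbone angles per residue plus 3+0+0+2+4 side-chain torsions
  expect_identical(sum(inst$variables$kind %in% c("phi", "psi")), 10L)
  expect_identical(sum(inst$variables$kind == "chi"), 9L)
  # stable deterministic ordering
  expect_identical(enumerate_variables("YGGFM")$variables, inst$variables)
  expect_identical(enumerate_variables("G", c("phi", "psi"))$m, 2L)
  expect_identical(enumerate_variables("GG", c("phi", "psi", "omega"))$m, 5L)
  expect_error(enumerate_variables("YGZFM"), "position 3")
  expect_error(enumerate_variables(""), "nzchar")
})

test_that("built chains honour the internal geometry table", {
  inst <- enumerate_variables("YAGFM")
  set.seed(91)
  sig <- random_conformation(inst$m)
  g <- build_coordinates(inst, sig)
  lens <- sqrt(rowSums((g$xyz[g$bonds[, 1], ] - g$xyz[g$bonds[, 2], ])^2))
  known <- c(1.329, 1.458, 1.525, 1.231, 1.530, 1.520)
  for (l in lens) expect_lt(min(abs(l - known)), 1e-6)
  expect_error(build_coordinates(inst, sig[-1]), "m = ")
})

test_that("torsion measurement inverts chain building", {
  for (seqs in list(c("YGGFM", c("phi", "psi", "chi")),
                    c("KWTQ", c("phi", "psi", "omega", "chi")))) {
    inst <- enumerate_variables(seqs[[1]],
                                angle_set = seqs[-1])
    set.seed(92)
    for (i in 1:3) {
      sig <- random_conformation(inst$m)
      g <- build_coordinates(inst, sig)
      expect_lt(max(abs(wrap_angle(measure_torsions(g) - sig))), 1e-6)
    }
  }
})

test_that("a terminal side-chain torsion moves no backbone atom", {
  inst <- enumerate_variables("YGGFM")
  set.seed(93)
  sig <- random_conformation(inst$m)
  sig2 <- sig
  j <- which(inst$variables$residue == 5 & inst$variables$kind == "chi" &
               inst$variables$chi_index == 4)
  sig2[j] <- wrap_angle(sig2[j] + 77)
  ga <- build_coordinates(inst, sig)
  gb <- build_coordinates(inst, sig2)
  bb <- ga$atoms$name %in% c("N", "CA", "C", "O", "CB")
  expect_identical(ga$xyz[bb, ], gb$xyz[bb, ])
  expect_false(identical(ga$xyz, gb$xyz))
})

test_that("energy components sum and match closed forms", {
  params <- load_energy_params()
  inst <- enumerate_variables("YGGFM")
  set.seed(94)
  g <- build_coordinates(inst, random_conformation(inst$m))
  e <- compute_energy(g, params)
  expect_identical(e$total, sum(unlist(e$components)))
  # isolated pair at the Lennard-Jones minimum distance: depth -B^2/(4A)
  eps <- params$lj$CA$eps; rmin <- params$lj$CA$rmin
  A <- eps * rmin^12; B <- 2 * eps * rmin^6
  pair <- two_atom_geometry((2 * A / B)^(1 / 6))
  e2 <- compute_energy(pair, params)
  expect_equal(e2$components$lj, -B^2 / (4 * A), tolerance = 1e-12)
  expect_equal(e2$components$torsion, 0)
  # overflow guard: coincident atoms get a finite penalty
  e3 <- compute_energy(two_atom_geometry(1e-9), params)
  expect_true(is.finite(e3$total))
  expect_gte(e3$components$lj, params$clash_penalty)
})

test_that("energy is invariant under rigid motion", {
  inst <- enumerate_variables("YGGFM")
  params <- load_energy_params()
  set.seed(95)
  g <- build_coordinates(inst, random_conformation(inst$m))
  e0 <- compute_energy(g, params)$total
  for (i in 1:10) {
    g2 <- g
    g2$xyz <- rigid_transform(g$xyz)
    expect_equal(compute_energy(g2, params)$total, e0, tolerance = 1e-9)
  }
})

test_that("planted landscapes certify their global minimum", {
  land <- planted_landscape(m = 19, n_traps = 5, seed = 42)
  expect_identical(land$energy(land$sigma_star), 0)
  set.seed(96)
  for (i in 1:2000) {
    expect_gt(land$energy(random_conformation(land$m)), 0)
  }
  # each trap is a genuine local minimum: escaping any one of its two
  # coordinates straight to the optimum still climbs
  for (tr in land$traps) {
    centre <- land$sigma_star
    centre[tr$coords] <- tr$centre
    e_c <- land$energy(centre)
    expect_gt(e_c, 0)
    for (j in tr$coords) {
      esc <- centre
      esc[j] <- land$sigma_star[j]
      expect_gt(land$energy(esc), e_c)
    }
  }
  expect_error(planted_landscape(m = 4, n_traps = 5), "disjoint")
})

test_that("a trap-free landscape is unimodal in every coordinate", {
  land <- planted_landscape(m = 4, n_traps = 0, seed = 7)
  for (j in 1:4) {
    grid <- seq(-179, 180, by = 1)
    e <- vapply(grid, function(v) {
      s <- land$sigma_star
      s[j] <- v
      land$energy(s)
    }, numeric(1))
    # single minimum, at the planted coordinate (to grid resolution)
    expect_lt(abs(wrap_angle(grid[which.min(e)] - land$sigma_star[j])), 1.01)
    d <- wrap_angle(grid - land$sigma_star[j])
    expect_true(all(abs(e - (1 - cos(d * pi / 180))) < 1e-12))
  }
})

test_that("distance RMSD has its closed-form value and invariances", {
  tri <- function(d12, d13, d23) {
    x2 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
    rbind(c(0, 0, 0), c(d12, 0, 0), c(x2, sqrt(d13^2 - x2^2), 0))
  }
  a <- tri(3, 4, 5); b <- tri(3, 4, 6)
  expect_equal(drmsd(a, b), sqrt(1 / 3))
  expect_equal(drmsd(a, a), 0)
  expect_equal(drmsd(a, b), drmsd(b, a))
  set.seed(97)
  inst <- enumerate_variables("YGGFM")
  g <- build_coordinates(inst, random_conformation(inst$m))
  for (i in 1:10) {
    g2 <- g
    g2$xyz <- rigid_transform(g$xyz)
    expect_lt(drmsd(g, g2), 1e-9)
    refl <- g$xyz
    refl[, 1] <- -refl[, 1]
    g3 <- g; g3$xyz <- refl
    expect_lt(drmsd(g, g3), 1e-9)
  }
  expect_error(drmsd(a, rbind(a, c(0, 0, 9))), "atom counts")
})
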