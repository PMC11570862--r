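test_that("distance_to_cg matches direct centroid arithmetic", {
  one <- mk_atoms(c(1, 2, 3))
  expect_equal(distance_to_cg(one, one), 0)
  a <- mk_atoms(c(5, 0, 0)); b <- mk_atoms(c(-5, 0, 0), res_seq = 2)
  both <- rbind(a, b)
  expect_equal(distance_to_cg(a, both), 5)
  expect_equal(distance_to_cg(b, both), 5)
  h <- make_helix_structure(10, "poly-A")
  res <- polymer_residues(h)
  chain <- do.call(rbind, res)
  r1 <- res[[1]]
  direct <- sqrt(sum((colMeans(cbind(r1$x, r1$y, r1$z)) -
                      colMeans(cbind(chain$x, chain$y, chain$z)))^2))
  expect_equal(distance_to_cg(r1, chain), direct, tolerance = 1e-6)
})

test_that("contact graph edges follow the distance cutoff exactly", {
  near <- list(A = mk_atoms(c(0, 0, 0)), B = mk_atoms(c(3, 0, 0), res_seq = 2))
  expect_equal(nrow(build_contact_graph(near, 5)$edges), 1)
  far <- list(A = mk_atoms(c(0, 0, 0)), B = mk_atoms(c(30, 0, 0), res_seq = 2))
  expect_equal(nrow(build_contact_graph(far, 5)$edges), 0)
  # brute-force oracle on the helix
  res <- polymer_residues(make_helix_structure(10, "poly-A"))
  cg <- build_contact_graph(res, 5)
  got <- cg$edges[, c("i", "j")]
  want <- list()
  for (i in 1:9) for (j in (i + 1):10) {
    d <- oracle_min_dist(cbind(res[[i]]$x, res[[i]]$y, res[[i]]$z),
                         cbind(res[[j]]$x, res[[j]]$y, res[[j]]$z))
    if (d <= 5) want[[length(want) + 1]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  expect_equal(as.matrix(got), want, ignore_attr = TRUE)
})

test_that("eccentricity and betweenness match toy path-graph values", {
  path5 <- mk_contact_graph(5, cbind(1:4, 2:5))
  expect_equal(graph_eccentricity(path5, "n01"), 4L)
  expect_equal(graph_eccentricity(path5, "n03"), 2L)
  path3 <- mk_contact_graph(3, cbind(1:2, 2:3))
  expect_equal(graph_bottleneck(path3, "n02"), 1.0)
  expect_equal(graph_bottleneck(path3, "n01"), 0.0)
  expect_error(graph_eccentricity(path5, "zz"), "unknown node")
})

test_that("graph descriptors equal brute-force oracles on random graphs", {
  for (seed in 1:25) {
    rg <- random_graph(seed)
    if (nrow(rg$edges) == 0) next
    cg <- mk_contact_graph(rg$n, rg$edges)
    for (v in seq_len(rg$n)) {
      id <- cg$nodes[v]
      expect_equal(graph_eccentricity(cg, id),
                   oracle_eccentricity(rg$n, rg$edges, v))
      expect_equal(graph_bottleneck(cg, id),
                   oracle_betweenness(rg$n, rg$edges, v), tolerance = 1e-9)
    }
  }
})

test_that("sponge fraction reflects void space and is monotone in deletion", {
  iso <- mk_structure(mk_atoms(c(0, 0, 0)))
  expect_gt(sponge_fraction(iso, iso$atoms), 0.99)
  # dense 1.5 A lattice filling the ball
  ax <- seq(-9, 9, by = 1.5)
  latt <- as.matrix(expand.grid(ax, ax, ax))
  latt <- latt[rowSums(latt^2) <= 12^2, ]
  dense <- mk_structure(mk_atoms(as.vector(t(latt))))
  ctr <- dense$atoms[rowSums(cbind(dense$atoms$x, dense$atoms$y,
                                   dense$atoms$z)^2) == 0, ]
  expect_lt(sponge_fraction(dense, ctr), 0.35)
  # deleting atoms never decreases the void fraction
  fx <- make_labelled_fixture(seed = 2, id = "sp")
  res <- polymer_residues(fx)
  full <- sponge_fraction(fx, res[[10]])
  drop <- fx
  drop$atoms <- drop$atoms[drop$atoms$res_seq != 12, ]
  expect_gte(sponge_fraction(drop, res[[10]]), full)
})

test_that("hydrophobicity_env averages Kyte-Doolittle over the neighbourhood", {
  ile <- mk_atoms(c(0, 0, 0), res_name = "ILE")
  expect_equal(hydrophobicity_env(list(i1 = ile), "i1"), 4.5)
  arg <- mk_atoms(c(3, 0, 0), res_name = "ARG", res_seq = 2)
  expect_equal(hydrophobicity_env(list(i1 = ile, r2 = arg), "i1"), 0)
  # direct neighbourhood-mean oracle on the helix
  h <- make_helix_structure(10, "ILKAVESTGR")
  res <- polymer_residues(h)
  kd <- c(ILE = 4.5, LEU = 3.8, LYS = -3.9, ALA = 1.8, VAL = 4.2,
          GLU = -3.5, SER = -0.8, THR = -0.7, GLY = -0.4, ARG = -4.5)
  for (target in c(1, 5, 9)) {
    vals <- c()
    for (j in seq_along(res)) {
      d <- if (j == target) 0 else
        oracle_min_dist(cbind(res[[target]]$x, res[[target]]$y, res[[target]]$z),
                        cbind(res[[j]]$x, res[[j]]$y, res[[j]]$z))
      if (d <= 6.5) vals <- c(vals, kd[res[[j]]$res_name[1]])
    }
    expect_equal(hydrophobicity_env(res, names(res)[target]),
                 mean(vals), tolerance = 1e-9)
  }
})

test_that("electrostatic_potential follows the screened Coulomb formula", {
  # no charged groups -> 0
  ala <- mk_atoms(c(0, 0, 0), name = "CA")
  s0 <- mk_structure(rbind(ala))
  expect_equal(electrostatic_potential(s0, s0$atoms), 0)
  # one +1 charge (LYS NZ) at 5 A -> 332.0636 / (4 * 5 * 5)
  lys <- mk_atoms(c(5, 0, 0), name = "NZ", element = "N",
                  res_name = "LYS", res_seq = 2)
  s1 <- mk_structure(rbind(ala, lys))
  r1 <- s1$atoms[s1$atoms$res_seq == 1, ]
  expect_equal(electrostatic_potential(s1, r1), 332.0636 / (4 * 25),
               tolerance = 1e-6)
  # symmetric +1 / -1 cancel at the midpoint
  asp <- mk_atoms(c(-5, 0, 0), name = "CG", res_name = "ASP", res_seq = 3)
  s2 <- mk_structure(rbind(ala, lys, asp))
  r1 <- s2$atoms[s2$atoms$res_seq == 1, ]
  expect_equal(electrostatic_potential(s2, r1), 0, tolerance = 1e-9)
})

test_that("backbone H-bond energies behave like an ideal helix", {
  # fully extended dipeptide: no partners in range
  h2 <- make_helix_structure(4, "poly-A")
  res2 <- polymer_residues(h2)[1:2]
  hb2 <- hbond_energies(res2)
  expect_equal(hb2$donor_energy, c(0, 0))
  expect_equal(hb2$acceptor_energy, c(0, 0))
  # mid-helix residues donate i -> i-4 with E < -0.5
  h <- make_helix_structure(12, "poly-A")
  res <- polymer_residues(h)
  hb <- hbond_energies(res)
  mid <- 6:10
  expect_true(all(hb$donor_energy[mid] < -0.5))
  expect_equal(hb$donor_partner[mid], mid - 4L)
  # bookkeeping identity: donor i's energy appears as acceptor j's record
  for (i in mid) {
    j <- hb$donor_partner[i]
    expect_equal(hb$acceptor_energy[j], hb$donor_energy[i], tolerance = 1e-9)
  }
})

test_that("descriptor tables are complete, order-invariant and deterministic", {
  fx <- make_labelled_fixture(n_res = 20, seed = 11, id = "dt")
  lb <- label_residues(fx, compute_lasa_values = FALSE)
  tab <- compute_descriptor_table(fx, lb, config = list(n_points = 240))
  expect_equal(nrow(tab), 20)
  dc <- descriptor_columns(tab)
  expect_true(all(c("rel_asa", "dist_cg", "sponge", "hydrophob_env",
                    "elec_pot", "donor_energy", "acceptor_energy",
                    "eccentricity", "bottleneck") %in% dc))
  expect_true(all(vapply(dc, function(cc) all(is.finite(tab[[cc]])),
                         logical(1))))
  # determinism: byte-identical TSV on re-run
  p1 <- tempfile(); p2 <- tempfile()
  write_descriptor_table(tab, p1)
  write_descriptor_table(compute_descriptor_table(fx, lb,
                                                  config = list(n_points = 240)),
                         p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("descriptors are invariant under rigid motion", {
  fx <- make_labelled_fixture(n_res = 16, seed = 13, id = "rm")
  lb <- label_residues(fx, compute_lasa_values = FALSE)
  t1 <- compute_descriptor_table(fx, lb, config = list(n_points = 240))
  # rotate about z by 30 degrees and translate
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  X <- as.matrix(fx$atoms[, c("x", "y", "z")]) %*% R
  fx2 <- fx
  fx2$atoms$x <- X[, 1] + 7; fx2$atoms$y <- X[, 2] - 3; fx2$atoms$z <- X[, 3] + 1
  t2 <- compute_descriptor_table(fx2, lb, config = list(n_points = 240))
  for (cc in descriptor_columns(t1)) {
    tol <- if (cc %in% c("sponge", "rel_asa")) 0.02 else 1e-6
    expect_equal(t2[[cc]], t1[[cc]], tolerance = tol, label = cc)
  }
})
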