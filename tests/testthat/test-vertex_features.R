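# Vertex features: atom->vertex mapping, chemistry, circular variance,
# curvature, heat kernel signatures, electrostatics, profile parsing and
# feature-table assembly.

test_that("inverse-distance mapping follows its weighting contract", {
  st <- point_structure()
  st$atoms <- rbind(st$atoms, transform(st$atoms, serial = 2, x = 3))
  st$residue <- c(1L, 1L)
  vals <- c(1, 0)
  mk <- function(v) {
    m <- surface_mesh(rbind(v, c(0, 9, 0), c(9, 9, 0)), matrix(1:3, 1))
    m
  }
  # equidistant -> 0.5
  expect_equal(map_atom_to_vertices(st, mk(c(1.5, 0, 0)), vals)[1], 0.5)
  # distances 1 and 2 -> (1*1 + 0.5*0) / 1.5 = 2/3
  expect_equal(map_atom_to_vertices(st, mk(c(1, 0, 0)), vals)[1], 2 / 3)
  # nothing within 2.5 A -> nearest-atom fallback
  far <- point_structure()
  far$atoms$x <- 3
  expect_equal(map_atom_to_vertices(far, mk(c(0, 0, 0)), 7)[1], 7)
  # coincident vertex copies the atom value exactly
  expect_equal(map_atom_to_vertices(st, mk(c(0, 0, 0)), vals)[1], 1)
  expect_error(map_atom_to_vertices(st, mk(c(0, 0, 0)), c(NA, 1)), "finite")
})

test_that("chemical features use the packaged tables", {
  st <- make_toy_structure(10, seed = 3)
  ch <- chemical_features(st)
  gly <- which(st$atoms$resname == "GLY")
  if (length(gly)) {
    expect_equal(unname(ch[gly[1], paste0("AF", 1:5)]),
                 unname(atchley_table()["GLY", ]))
  }
  ala <- which(st$atoms$resname == "ALA")
  if (length(ala)) {
    expect_equal(unname(ch[ala[1], paste0("AF", 1:5)]),
                 unname(atchley_table()["ALA", ]))
  }
  # backbone carbonyl O: acceptor, not donor
  o <- which(st$atoms$name == "O")[1]
  expect_equal(unname(ch[o, "HBA"]), 1)
  expect_equal(unname(ch[o, "HBD"]), 0)
  # backbone N donates (non-proline)
  n <- which(st$atoms$name == "N" & st$atoms$resname != "PRO")[1]
  expect_equal(unname(ch[n, "HBD"]), 1)

  # fully buried side chains (zero exposure) contribute zero SAP
  sasa0 <- rep(0, nrow(st$atoms))
  ch0 <- chemical_features(st, sasa = sasa0)
  expect_equal(unname(ch0[, "SAP"]), rep(0, nrow(st$atoms)))

  # non-standard residue zeros with warning
  st$atoms$resname[1] <- "LIG"
  expect_warning(chemical_features(st, sasa = rep(1, nrow(st$atoms))),
                 "non-standard")
})

test_that("circular variance matches symmetry limits and the MC oracle", {
  mk <- function(v) surface_mesh(rbind(v, c(0, 50, 0), c(50, 50, 0)),
                                 matrix(1:3, 1))
  # uniform ball around the vertex -> CV ~ 1
  set.seed(5)
  p <- matrix(runif(3 * 60000, -1, 1), ncol = 3)
  p <- p[rowSums(p^2) <= 1, ]
  expect_gt(circular_variance(mk(c(0, 0, 0)), p, radius = 2)[1], 0.98)
  # half ball boundary -> 0.5, against the Monte-Carlo oracle
  oracle <- cv_montecarlo("half_ball", n_samples = 1e5, seed = 2)
  expect_equal(oracle, 0.5, tolerance = 0.01)
  ph <- p[p[, 3] < 0, ]
  expect_equal(circular_variance(mk(c(0, 0, 0)), ph, radius = 2)[1], oracle,
               tolerance = 0.02)
  # a single neighbour -> CV = 0; no neighbour in range -> 0
  single <- matrix(c(1, 0, 0), 1)
  expect_equal(circular_variance(mk(c(0, 0, 0)), single, radius = 2)[1], 0)
  expect_equal(circular_variance(mk(c(0, 0, 0)), single, radius = 0.5)[1], 0)
})

test_that("circular variance grows with pocket depth", {
  # the neighbourhood radius must be on the scale of the pocket mouth (the
  # reason the real feature is computed at three radii); radius 10 covers
  # this crater across the whole depth range
  cvs <- sapply(c(0, 0.15, 0.3, 0.45), function(d) {
    m <- make_canonical_mesh("pocketed_sphere", 3, 10, depth = d)
    # vertex closest to the pocket axis (+z)
    bottom <- which.max(m$V[, 3] / sqrt(rowSums(m$V^2)))
    circular_variance(m, m$V[-bottom, ], radius = 10)[bottom]
  })
  expect_true(all(diff(cvs) > 0))
})

test_that("mean curvature matches analytic surfaces", {
  s <- make_canonical_mesh("sphere", 4, 2)  # 2562 vertices
  mc <- mean_curvature(s)
  expect_lt(abs(mean(mc) - 0.5) / 0.5, 0.05)
  expect_true(all(mc > 0))

  p <- make_canonical_mesh("plane", 12, 6)
  mcp <- mean_curvature(p)
  interior <- setdiff(seq_len(nrow(p$V)), attr(mcp, "boundary"))
  expect_lt(max(abs(mcp[interior])), 1e-3)
  expect_gt(length(attr(mcp, "boundary")), 0)

  cy <- make_canonical_mesh("cylinder", 16, 3)
  mcy <- mean_curvature(cy)
  inner <- setdiff(which(abs(cy$V[, 3]) < 3), attr(mcy, "boundary"))
  expect_lt(abs(mean(mcy[inner]) - 1 / 6) / (1 / 6), 0.10)
})

test_that("heat kernel signatures behave like the sphere heat kernel", {
  s <- make_canonical_mesh("sphere", 3, 1)
  hks <- heat_kernel_signature(s, n_eigen = 100, scales = c(0.1, 0.3, 1, 3),
                               normalize = FALSE)
  # spatially constant on the sphere
  cov <- apply(hks, 2, function(v) stats::sd(v) / mean(v))
  expect_true(all(cov < 0.02))
  # strictly decreasing in diffusion time before normalization
  expect_true(all(apply(hks, 1, function(r) all(diff(r) < 0))))
  # small-t value matches the truncated spherical-harmonic sum
  l <- 0:40
  analytic <- sum((2 * l + 1) * exp(-l * (l + 1) * 0.1)) / (4 * pi)
  expect_lt(abs(mean(hks[, 1]) - analytic) / analytic, 0.10)
  # eigenvalues approximate l(l+1)
  ev <- attr(hks, "eigenvalues")
  expect_equal(ev[1], 0, tolerance = 1e-8)
  expect_equal(mean(ev[2:4]), 2, tolerance = 0.05)
  expect_error(heat_kernel_signature(s, n_eigen = 8), "at least 32")
})

test_that("screened-Coulomb electrostatics follow the physics", {
  st <- point_structure(charge = 1)
  s <- make_canonical_mesh("sphere", 2, 5)
  s1 <- transform_mesh(make_canonical_mesh("sphere", 2, 8), diag(3))
  # positive charge -> positive potential, decreasing with distance
  ph_near <- electrostatics(st, s)
  ph_far <- electrostatics(st, s1)
  expect_true(all(ph_near[, "PH1"] > 0))
  expect_true(mean(ph_far[, "PH1"]) < mean(ph_near[, "PH1"]))
  # kappa = 0 limit is Coulomb: potentials at 1 and 2 A have ratio 2
  m1 <- surface_mesh(rbind(c(1, 0, 0), c(2, 0, 0), c(0, 0, 9)), matrix(1:3, 1))
  m1$normals <- matrix(rep(c(1, 0, 0), each = 3), ncol = 3)
  phc <- electrostatics(st, m1, ionic_strength = 0)
  expect_equal(unname(phc[1, "PH1"] / phc[2, "PH1"]), 2, tolerance = 1e-6)
  # spherical mesh centred on the charge: normal field uniform within 1%
  ph <- electrostatics(st, s)
  expect_lt(stats::sd(ph[, "PH2"]) / mean(ph[, "PH2"]), 0.01)
  expect_true(all(ph[, "PH2"] > 0))
})

test_that("profile parsers decode PSSM and hhm dialects", {
  hdr <- c("", "Last position-specific scoring matrix computed",
           paste(" ", paste(rep("A", 20), collapse = "  ")))
  rows <- sprintf("  %2d %s %s  %s 1.0 1.0", 1:5, c("M", "K", "T", "A", "Y"),
                  paste(rep(" 0", 20), collapse = ""),
                  paste(rep(" 0", 20), collapse = ""))
  pr <- parse_pssm(c(hdr, rows, ""))
  expect_equal(dim(pr$values), c(5, 20))
  expect_equal(unname(pr$values[1, 1]), 0.5)  # logistic(0)
  expect_error(parse_pssm(c(hdr, rows), chain_length = 6), "offset")

  hhm <- c("HHsearch 1.5", "NAME  toy", "HMM    A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y",
           "       M->M	M->I	M->D	I->M	I->I	D->M	D->D	Neff	Neff_I	Neff_D",
           "       0	*	*	0	*	0	*	1000	0	0",
           paste("M 1", paste(rep("0", 20), collapse = "\t"), "1"),
           paste(rep("0", 7), collapse = "\t"), "",
           paste("K 2", paste(rep("1000", 20), collapse = "\t"), "2"),
           paste(c(rep("0", 7), "2000", "0", "0"), collapse = "\t"),
           "//")
  hp <- parse_hhm(hhm)
  expect_equal(dim(hp$values), c(2, 30))
  expect_equal(unname(hp$values[1, 1]), 1)      # code 0 -> p = 2^0 = 1
  expect_equal(unname(hp$values[2, 1]), 0.5)    # code 1000 -> 2^-1
  expect_equal(unname(hp$values[2, 28]), 2)     # Neff 2000 -> 2.0
  expect_error(parse_hhm(hhm, chain_length = 3), "offset")
})

test_that("feature table has the full structural column set", {
  st <- make_toy_structure(6, seed = 7)
  mesh <- generate_surface(st, grid_spacing = 1.0)
  X <- compute_feature_table(st, mesh, n_eigen = 32)
  expect_identical(colnames(X), structural_feature_names())
  expect_equal(ncol(X), 18)
  expect_true(all(is.finite(X)))
  expect_true(all(X[, c("CV1", "CV2", "CV3")] >= 0 &
                    X[, c("CV1", "CV2", "CV3")] <= 1))
  expect_true(all(X[, c("HBA", "HBD")] >= 0 & X[, c("HBA", "HBD")] <= 1))
  expect_setequal(unique(attr(X, "provenance")), "computed")

  # with both profiles: + 50 MSA columns
  nres <- n_residues(st)
  pssm <- structure(list(values = matrix(0.5, nres, 20,
                                         dimnames = list(NULL, paste0("PSSM", 1:20))),
                         resno = seq_len(nres), aa = rep("A", nres),
                         kind = "pssm"), class = "ResidueProfile")
  hhm <- structure(list(values = matrix(0.1, nres, 30,
                                        dimnames = list(NULL, paste0("HMM", 1:30))),
                        resno = seq_len(nres), aa = rep("A", nres),
                        kind = "hhm"), class = "ResidueProfile")
  X2 <- compute_feature_table(st, mesh, pssm = pssm, hhm = hhm, n_eigen = 32)
  expect_equal(ncol(X2), 68)
  expect_identical(colnames(X2), c(structural_feature_names(),
                                   msa_feature_names()))
  prov <- attr(X2, "provenance")
  expect_true(all(prov[msa_feature_names()] == "parsed"))
})

test_that("structural features are invariant under rigid motion", {
  st <- make_toy_structure(5, seed = 9)
  mesh <- generate_surface(st, grid_spacing = 1.2)
  X0 <- compute_feature_table(st, mesh, n_eigen = 32)
  R <- random_rotation(11)
  tvec <- c(4, -7, 2)
  st2 <- transform_structure(st, R, tvec)
  mesh2 <- transform_mesh(mesh, R, tvec)
  mesh2 <- map_mesh_to_structure(mesh2, st2)
  X1 <- compute_feature_table(st2, mesh2, n_eigen = 32)
  expect_lt(max(abs(X1 - X0)), 1e-5)
})
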