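test_that("xyz files round-trip multi-frame coordinates", {
  set.seed(2)
  confs <- lapply(1:3, function(i)
    conformation(matrix(rnorm(12), 4, 3), labels = c("C", "N", "O", "H")))
  f <- tempfile(fileext = ".xyz")
  write_xyz(confs, f)
  back <- read_xyz(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$coords, confs[[i]]$coords, tolerance = 1e-6)
    expect_equal(back[[i]]$labels, confs[[i]]$labels)
  }
})

test_that("xyz parser flags malformed count lines and truncated frames", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
  writeLines(c("notanumber", "frame", "C 0 0 0"), f)
  expect_error(read_xyz(f), "atom count")
  writeLines(c("1", "frame", "C 0 zero 0"), f)
  expect_error(read_xyz(f), "line 3")
})

test_that("scientific-notation coordinates parse identically to plain", {
  f1 <- tempfile(fileext = ".xyz")
  f2 <- tempfile(fileext = ".xyz")
  writeLines(c("2", "plain", "C 0.00125 -4.5 1000", "N 3 2 1"), f1)
  writeLines(c("2", "sci", "C 1.25e-3 -4.5e0 1e3", "N 3E0 2.0E0 1e0"), f2)
  a <- read_xyz(f1)[[1]]
  b <- read_xyz(f2)[[1]]
  expect_identical(a$coords, b$coords)
})

test_that("path manifests round-trip losslessly including toy dimensions", {
  set.seed(4)
  p <- taps_path(matrix(rnorm(10), 5, 2))   # 2D toy path
  dir <- file.path(tempdir(), "manifest_test")
  write_path_manifest(p, dir, seed = 3L)
  back <- read_path_manifest(dir)
  expect_equal(path_length(back), 5L)
  expect_equal(path_node_matrix_test(back), path_node_matrix_test(p),
               tolerance = 1e-6)
  expect_equal(back$lambda, p$lambda, tolerance = 1e-6)
  expect_error(read_path_manifest(tempfile()), "manifest")
})

test_that("the synthetic pdb fixture reads with selections applied", {
  fx <- make_fixture("pdb_toy", seed = 5L)
  full <- suppressMessages(read_pdb_coords(fx$file))
  # 5 residues x 6 atoms, minus CB on the two glycines, altLoc collapsed
  expect_equal(nrow(full$coords), 28L)
  ca <- suppressMessages(read_pdb_coords(fx$file, elety = "CA"))
  expect_equal(nrow(ca$coords), 5L)
  expect_match(ca$labels[1], "CA")
  # residue-range heavy-atom selection matches hand enumeration:
  # residues 2-3 hold GLY (N,CA,C,O = 4 heavy) + SER (5 heavy) = 9 atoms
  sel <- suppressMessages(read_pdb_coords(fx$file, resno = 2:3,
                                          heavy_only = TRUE))
  expect_equal(nrow(sel$coords), 9L)
  expect_false(any(grepl(":HA", sel$labels)))
  expect_error(suppressMessages(read_pdb_coords(fx$file, resno = 99)),
               "empty selection")
})

test_that("altLoc conformers keep the highest occupancy", {
  fx <- make_fixture("pdb_toy", seed = 6L)
  msgs <- capture_messages(conf <- read_pdb_coords(fx$file, elety = "CA"))
  expect_match(paste(msgs, collapse = " "), "altLoc")
  expect_equal(nrow(conf$coords), 5L)   # one CA per residue survives
})

test_that("contact fractions count frames below the cutoff", {
  near <- conformation(rbind(c(0, 0, 0), c(2, 0, 0)))
  far <- conformation(rbind(c(0, 0, 0), c(6, 0, 0)))
  spec <- contact_spec(1L, 2L, cutoff = 3.5)
  expect_equal(contact_fraction(rep(list(near), 10), spec), 100)
  expect_equal(contact_fraction(c(rep(list(near), 5), rep(list(far), 5)),
                                spec), 50)
})

test_that("contact fraction reproduces a constructed exceedance count", {
  set.seed(8)
  n <- 1000L
  beyond <- sort(sample(n, 173L))
  frames <- lapply(seq_len(n), function(i) {
    d <- if (i %in% beyond) 5 else 2
    conformation(rbind(c(0, 0, 0), c(d, 0, 0)))
  })
  spec <- contact_spec(1L, 2L, cutoff = 3.5)
  expect_equal(contact_fraction(frames, spec), 82.7)
  # brute-force recount agrees
  manual <- 100 * mean(vapply(frames, function(fr)
    sqrt(sum((fr$coords[1, ] - fr$coords[2, ])^2)) <= 3.5, logical(1)))
  expect_equal(contact_fraction(frames, spec), manual)
})

test_that("contact specs validate their inputs", {
  expect_error(contact_spec(integer(0), 1L, 3), "non-empty")
  expect_error(contact_spec(1L, 2L, -1), "positive")
  expect_warning(contact_spec(1:2, 1:2, 3), "identical")
  spec <- contact_spec(1L, 5L, 3)
  frames <- list(conformation(matrix(0, 2, 3)))
  expect_error(contact_fraction(frames, spec), "out of range")
})

test_that("rmsd series statistics match direct computation", {
  set.seed(10)
  ref <- conformation(matrix(rnorm(15), 5, 3))
  m <- metric_spec("rmsd", align_idx = 1:5)
  same <- rep(list(ref), 4)
  out <- rmsd_series_stats(same, ref, m)
  expect_equal(out$mean, 0)
  expect_equal(out$sd, 0)
  # frames constructed by controlled perturbation, verified directly
  frames <- lapply(1:6, function(i)
    conformation(ref$coords + rnorm(15, sd = 0.2)))
  out <- rmsd_series_stats(frames, ref, m)
  direct <- vapply(frames, function(fr) distance(fr, ref, m), numeric(1))
  expect_equal(out$series, direct)
  expect_equal(out$mean, mean(direct))
  expect_equal(out$sd, sqrt(mean((direct - mean(direct))^2)))
  # single frame: population SD is zero
  expect_equal(rmsd_series_stats(frames[1], ref, m)$sd, 0)
  expect_error(rmsd_series_stats(frames, ref, metric_spec("euclidean")),
               "rmsd")
})

test_that("fixture bundles are reproducible and carry their oracles", {
  f1 <- make_fixture("double_well", seed = 3L)
  f2 <- make_fixture("double_well", seed = 3L)
  expect_equal(f1$oracle_delta_g, f2$oracle_delta_g)
  expect_equal(f1$endpoints, f2$endpoints)
  # the configured 2 kT offset shows up in the Boltzmann oracle
  expect_equal(f1$oracle_delta_g, 2, tolerance = 0.05)
  expect_lt(abs(f1$endpoints$a + 1), 0.1)
  expect_lt(abs(f1$endpoints$b - 1), 0.1)
  expect_error(make_fixture("nope"), "unknown fixture kind")
})

test_that("the two-basin fixture reduces to the 1D Boltzmann oracle", {
  fx <- make_fixture("two_basin_nd", seed = 2L, dim = 3L)
  expect_equal(fx$potential$dim, 3L)
  expect_equal(fx$oracle_delta_g, 2, tolerance = 0.05)
  # perpendicular modes are harmonic and identical in both basins
  e_perp <- fx$potential$energy(c(fx$endpoints$a[1], 0.5, 0)) -
    fx$potential$energy(fx$endpoints$a)
  expect_equal(e_perp, 0.5 * 2 * 0.25, tolerance = 1e-10)
})

test_that("cv tables round-trip through tab-separated text", {
  cv <- data.frame(step = c(0L, 10L, 20L), s = c(1.2, 1.4, 1.1),
                   z = c(-0.01, 0.02, 0.005))
  f <- tempfile(fileext = ".tsv")
  write_cv_table(cv, f)
  expect_identical(readLines(f)[1], "step\ts\tz")
  back <- read_cv_table(f)
  expect_equal(back, cv)
})

test_that("profiles export as tables plus states json", {
  prof <- structure(list(s_grid = 1:5, f = c(0, 1, 0.2, 2, 0),
                         p = rep(0.2, 5), counts = rep(100L, 5),
                         bin_width = 1, beta = 1, minima = NULL,
                         maxima = NULL), class = "fes_profile")
  prof <- find_states(prof, prominence = 0.1)
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$f, prof$f)
  states <- jsonlite::read_json(paste0(f, ".states.json"),
                                simplifyVector = TRUE)
  expect_equal(states$minima$s, c(1, 3, 5))
})

test_that("the cli smoke-runs an end-to-end fixture workflow", {
  root <- file.path(tempdir(), paste0("cli", as.integer(Sys.time())))
  fdir <- file.path(root, "fx")
  odir <- file.path(root, "opt")
  edir <- file.path(root, "fes")
  expect_equal(suppressMessages(taps_cli(c("fixtures", "--kind",
                                           "two_basin_nd", "--seed", "7",
                                           "--out", fdir))), 0L)
  expect_true(file.exists(file.path(fdir, "manifest.json")))
  expect_true(file.exists(file.path(fdir, "provenance.json")))
  expect_equal(suppressWarnings(suppressMessages(
    taps_cli(c("optimize", "--manifest", fdir, "--out", odir,
               "--iterations", "2", "--samples", "80", "--seed", "7")))), 0L)
  expect_true(file.exists(file.path(odir, "convergence.tsv")))
  expect_equal(suppressWarnings(suppressMessages(
    taps_cli(c("fes", "--manifest", odir, "--out", edir, "--samples",
               "200", "--seed", "7")))), 0L)
  expect_true(file.exists(file.path(edir, "profile.tsv")))
  states <- jsonlite::read_json(file.path(edir,
                                          "profile.tsv.states.json"),
                                simplifyVector = TRUE)
  expect_gte(nrow(states$minima), 2L)
})

test_that("cli reports usage and runtime errors by exit status", {
  expect_equal(taps_cli(character(0)), 1L)
  expect_equal(suppressMessages(taps_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(taps_cli(c("optimize", "--manifest",
                                           tempfile(), "--out",
                                           tempfile()))), 2L)
  expect_equal(taps_cli(c("fes", "--help")), 0L)
  expect_equal(suppressMessages(taps_cli(c("fixtures", "--bogus", "1"))),
               1L)
})
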