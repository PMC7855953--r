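test_that("cross-correlation matches the brute-force oracle on random grids", {
  expect_equal(cross_correlate(matrix(1), matrix(1))[1, 1], 1)
  z <- cross_correlate(matrix(rnorm(12), 3, 4), matrix(0, 2, 2))
  expect_true(all(z == 0))

  set.seed(7)
  for (r in 1:20) {
    nra <- sample(1:4, 1); nca <- sample(1:4, 1)
    nrb <- sample(1:4, 1); ncb <- sample(1:4, 1)
    a <- matrix(sample(-5:5, nra * nca, TRUE), nra, nca)
    b <- matrix(sample(-5:5, nrb * ncb, TRUE), nrb, ncb)
    expect_equal(unclass(cross_correlate(a, b)), brute_xcorr(a, b),
                 ignore_attr = TRUE)
  }
})

test_that("grid rotation: identity, involution, and exact 90-degree permutation", {
  g <- grid_face(rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6), c(12, 0)),
                 c(1, 2, 3, 4, 5), 5)
  expect_equal(dim(g$values), c(3, 2))
  expect_equal(rotate_grid(g, 0)$values, g$values)

  r180 <- rotate_grid(g, 180)
  expect_equal(rotate_grid(r180, 180)$values, g$values)
  expect_equal(rotate_grid(r180, 180)$occupancy, g$occupancy)

  r90 <- rotate_grid(g, 90)
  expect_equal(dim(r90$values), c(2, 3))
  # hand permutation out(i', j') = in(j', nc + 1 - i') of
  # in = [[1,3],[2,4],[5,0]]
  expect_equal(r90$values, rbind(c(3, 4, 0), c(1, 2, 5)))
  # rotated cells trace back to their source atoms
  expect_setequal(unlist(r90$bin_atoms), unlist(g$bin_atoms))
})

test_that("pair scoring honours the max/min convention on toy grids", {
  mk <- function(v) {
    g <- grid_face(matrix(c(0, 0), 1, 2), v, 5)
    list(list(charge = g, hydrophobicity = g))
  }
  cfg <- grid_config(min_overlap_bins = 1, rotation_step_deg = 90)
  hits <- score_all_pairs(mk(1), mk(-1), "charge", cfg)
  expect_equal(hits$score[1], -1)
  hits2 <- score_all_pairs(mk(2), mk(2), "hydrophobicity", cfg)
  expect_equal(hits2$score[1], 4)
})

test_that("pair scoring equals a brute-force search over rotations and lags", {
  set.seed(8)
  s <- make_blob_protein(fixture_spec(n_residues = 30, seed = 14))
  s$charge <- rnorm(nrow(s))
  t <- make_blob_protein(fixture_spec(n_residues = 30, seed = 15),
                         chain = "B", center = c(40, 0, 0))
  t$charge <- rnorm(nrow(t))
  cfg <- grid_config(rotation_step_deg = 90, min_overlap_bins = 1,
                     n_sphere_points = 120L)
  sm_s <- residue_depth(s, compute_surface_points(s, 1.4, 120L), 5)
  sm_t <- residue_depth(t, compute_surface_points(t, 1.4, 120L), 5)
  fa <- build_face_grids(s, sm_s, "charge", cfg)
  fb <- build_face_grids(t, sm_t, "charge", cfg)
  hits <- score_all_pairs(fa$grids, fb$grids, "charge", cfg, top_k = 5)

  best <- Inf
  for (i in 1:6) for (j in 1:6) for (ang in c(0, 90, 180, 270)) {
    ga <- fa$grids[[i]]$charge
    gb <- rotate_grid(fb$grids[[j]]$charge, ang)
    sc <- brute_xcorr(ga$values, gb$values)
    ov <- brute_xcorr(ga$occupancy * 1, gb$occupancy * 1)
    sc[ov < 1] <- Inf
    best <- min(best, min(sc))
  }
  expect_equal(hits$score[1], best, tolerance = 1e-10)
})

test_that("swap symmetry: best unrotated score is partner-order invariant", {
  s <- make_blob_protein(fixture_spec(n_residues = 35, seed = 16))
  s$charge <- rnorm(nrow(s))
  t <- make_blob_protein(fixture_spec(n_residues = 35, seed = 17),
                         chain = "B", center = c(40, 0, 0))
  t$charge <- rnorm(nrow(t))
  cfg <- grid_config(rotation_step_deg = 360, min_overlap_bins = 1,
                     n_sphere_points = 120L)
  sm_s <- residue_depth(s, compute_surface_points(s, 1.4, 120L), 5)
  sm_t <- residue_depth(t, compute_surface_points(t, 1.4, 120L), 5)
  fa <- build_face_grids(s, sm_s, "charge", cfg)
  fb <- build_face_grids(t, sm_t, "charge", cfg)
  h_ab <- score_all_pairs(fa$grids, fb$grids, "charge", cfg)
  h_ba <- score_all_pairs(fb$grids, fa$grids, "charge", cfg)
  expect_equal(h_ab$score[1], h_ba$score[1], tolerance = 1e-10)
})

test_that("scaling one partner's property scales scores and keeps the ranking", {
  s <- make_blob_protein(fixture_spec(n_residues = 30, seed = 18))
  s$charge <- rnorm(nrow(s))
  t <- make_blob_protein(fixture_spec(n_residues = 30, seed = 19),
                         chain = "B", center = c(40, 0, 0))
  t$charge <- rnorm(nrow(t))
  cfg <- grid_config(rotation_step_deg = 90, min_overlap_bins = 1,
                     n_sphere_points = 120L)
  sm_s <- residue_depth(s, compute_surface_points(s, 1.4, 120L), 5)
  sm_t <- residue_depth(t, compute_surface_points(t, 1.4, 120L), 5)
  fb <- build_face_grids(t, sm_t, "charge", cfg)
  h1 <- score_all_pairs(build_face_grids(s, sm_s, "charge", cfg)$grids,
                        fb$grids, "charge", cfg, top_k = 25)
  s2 <- s
  s2$charge <- 2.5 * s$charge
  h2 <- score_all_pairs(build_face_grids(s2, sm_s, "charge", cfg)$grids,
                        fb$grids, "charge", cfg, top_k = 25)
  key <- function(h) paste(h$face_a, h$face_b, h$rotation_deg,
                           h$lag_row, h$lag_col)
  expect_equal(key(h1), key(h2))
  expect_equal(h2$score, 2.5 * h1$score, tolerance = 1e-9)
})

test_that("initialization selection follows the top-10-sum rule", {
  mk_hits <- function(scores)
    tibble::tibble(face_a = 1L, face_b = 1L, rotation_deg = 0L,
                   lag_row = 0L, lag_col = 0L, score = scores)
  h <- mk_hits(seq(10, 1))
  expect_equal(select_initialization(h, h, "conservation")$chosen, 1L)
  h2 <- mk_hits(seq(12, 3))
  expect_equal(select_initialization(h, h2, "conservation")$chosen, 2L)
  c1 <- mk_hits(rep(-0.5, 10))
  c2 <- mk_hits(rep(-0.9, 10))
  expect_equal(select_initialization(c1, c2, "charge")$chosen, 2L)
  # short lists compare over the common count
  expect_equal(select_initialization(mk_hits(c(5, 5)), mk_hits(7),
                                     "hydrophobicity")$chosen, 2L)
})

test_that("the consistency rule accepts only single-face-pair top lists", {
  mk <- function(fa, fb)
    tibble::tibble(face_a = fa, face_b = fb, rotation_deg = 0L,
                   lag_row = 0L, lag_col = 0L,
                   score = seq(10, length.out = length(fa), by = -0.5))
  all_same <- consistency_check(mk(rep(2L, 10), rep(5L, 10)))
  expect_true(all_same$consistent)
  expect_equal(all_same$face_pair, c(2L, 5L))

  mixed <- consistency_check(mk(c(rep(2L, 9), 1L), c(rep(5L, 9), 1L)))
  expect_false(mixed$consistent)
  expect_equal(mixed$face_pair, c(2L, 5L))

  all_diff <- consistency_check(mk(1:6, c(2:6, 1L)))
  expect_false(all_diff$consistent)
  expect_equal(all_diff$face_pair, c(1L, 2L))
})

test_that("interface extraction returns the overlap region's residues", {
  s <- toy_structure(rbind(c(0, 0, 0), c(50, 0, 0)), atoms_per_residue = 1)
  mk1 <- function(atom_id) {
    g <- grid_face(matrix(c(0, 0), 1, 2), 1, 5, atom_ids = atom_id)
    list(list(charge = g))
  }
  hit <- tibble::tibble(face_a = 1L, face_b = 1L, rotation_deg = 0L,
                        lag_row = 0L, lag_col = 0L, score = 1)
  out <- extract_interface(hit, mk1(1L), mk1(2L), s, s, "charge")
  expect_equal(out$atoms_a, 1L)
  expect_equal(out$atoms_b, 2L)
  expect_equal(out$residues_a$residue_seq, 1L)
  expect_equal(out$residues_b$residue_seq, 2L)

  # corner lag with a one-cell overlap picks only that cell's atoms
  ga <- grid_face(rbind(c(0, 0), c(6, 6)), c(1, 2), 5, atom_ids = c(1L, 2L))
  hit2 <- tibble::tibble(face_a = 1L, face_b = 1L, rotation_deg = 0L,
                         lag_row = 1L, lag_col = 1L, score = 1)
  out2 <- extract_interface(hit2, list(list(charge = ga)),
                            list(list(charge = ga)), s, s, "charge")
  expect_equal(out2$atoms_a, 2L)
  expect_equal(out2$atoms_b, 1L)
})

test_that("prediction demands its properties up front and allows self-pairing", {
  pair <- make_fixture_pair(fixture_spec(n_residues = 30, seed = 20))
  expect_error(predict_interface(pair$a, pair$b, "conservation"),
               "conservation")
  cfg <- grid_config(rotation_step_deg = 45, n_sphere_points = 120L)
  p <- predict_interface(pair$a, pair$a, "hydrophobicity", cfg)
  expect_s3_class(p, "interface_prediction")
  expect_gt(nrow(p$residues_a), 0)
})

test_that("PCA orientation and second-interface reporting plug into the pipeline", {
  eng <- engineered_pair(seed = 33, n_residues = 50)
  cfg <- grid_config(rotation_step_deg = 45, n_sphere_points = 120L,
                     use_pca_orientation = TRUE)
  p <- predict_interface(eng$a, eng$b, "charge", cfg,
                         second_interface = TRUE)
  expect_s3_class(p, "interface_prediction")
  expect_gt(nrow(p$residues_a), 0)
  if (!is.null(p$second)) {
    # the secondary interface must involve a different face pair
    expect_false(p$second$hit$face_a == p$winning$hit$face_a &&
                   p$second$hit$face_b == p$winning$hit$face_b)
  }

  d <- withr::local_tempdir()
  g <- p$internals$builds$a[[1]]$grids[[1]]$charge
  write_grid_txt(g, file.path(d, "g.tsv"))
  m <- as.matrix(read.table(file.path(d, "g.tsv")))
  expect_equal(unname(m), unname(g$values), tolerance = 1e-12)
  pts <- compute_surface_points(eng$a, 1.4, 60L)
  write_surface_xyz(pts, file.path(d, "s.xyz"))
  expect_equal(readLines(file.path(d, "s.xyz"))[1],
               as.character(nrow(pts)))
  expect_s3_class(plot_face_grids(p$internals$builds$a[[1]]$grids,
                                  "charge"), "ggplot")
})
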