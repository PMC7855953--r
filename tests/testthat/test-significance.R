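test_that("confusion statistics implement the standard formulas", {
  u <- paste0("A:", 1:20)
  perfect <- confusion_stats(u[1:6], u[1:6], u)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # hand case: tp=3 fp=1 fn=2 tn=10
  cs <- confusion_stats(u[1:4], u[c(1:3, 5:6)], u[1:16])
  expect_equal(unlist(cs[, c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 1, fn = 2, tn = 10))
  expect_equal(cs$precision, 0.75)
  expect_equal(cs$recall, 0.6)
  expect_equal(cs$accuracy, 0.8125)
  expect_equal(cs$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)

  degenerate <- confusion_stats(character(0), u[1:3], u)
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$recall, 0)
  expect_error(confusion_stats(u[1], u[2], character(0)), "universe")
})

test_that("counts always sum to the universe and metrics stay in [0, 1]", {
  set.seed(9)
  u <- paste0("A:", 1:50)
  for (r in 1:20) {
    p <- sample(u, sample(0:30, 1))
    t <- sample(u, sample(0:30, 1))
    cs <- confusion_stats(p, t, u)
    expect_equal(cs$tp + cs$fp + cs$fn + cs$tn, 50)
    expect_true(all(unlist(cs[, c("precision", "recall", "accuracy",
                                  "f1")]) >= 0))
    expect_true(all(unlist(cs[, c("precision", "recall", "accuracy",
                                  "f1")]) <= 1))
  }
})

test_that("true interface residues are those within the heavy-atom cutoff", {
  a <- toy_structure(c(0, 0, 0))
  b4 <- toy_structure(c(4, 0, 0), chain = "B")
  ti <- true_interface(a, b4, cutoff = 5)
  expect_equal(nrow(ti$residues_a), 1)
  expect_equal(nrow(ti$residues_b), 1)
  b6 <- toy_structure(c(6, 0, 0), chain = "B")
  ti2 <- true_interface(a, b6, cutoff = 5)
  expect_equal(nrow(ti2$residues_a), 0)
  expect_equal(nrow(ti2$residues_b), 0)

  # independent double-loop oracle on a posed fixture pair
  pair <- make_fixture_pair(fixture_spec(n_residues = 25, seed = 21))
  ti3 <- true_interface(pair$a, pair$b, cutoff = 5)
  xa <- as.matrix(pair$a[, c("x", "y", "z")])
  xb <- as.matrix(pair$b[, c("x", "y", "z")])
  mind <- sapply(seq_len(nrow(xa)), function(i)
    min(sqrt(colSums((t(xb) - xa[i, ])^2))))
  oracle_a <- sort(unique(pair$a$residue_seq[mind < 5]))
  expect_equal(sort(ti3$residues_a$residue_seq), oracle_a)
})

test_that("evaluation maps residues onto the bound complex; 10 A cutoff is laxer", {
  eng <- engineered_pair(seed = 22, n_residues = 40)
  ti <- true_interface(eng$a, eng$b, 5)
  ev <- evaluate_prediction(list(residues_a = ti$residues_a,
                                 residues_b = ti$residues_b),
                            eng$a, eng$b, cutoff = 5)
  expect_equal(ev$precision, c(1, 1, 1))
  expect_equal(ev$recall, c(1, 1, 1))
  expect_equal(ev$f1, c(1, 1, 1))

  ev10 <- evaluate_prediction(list(residues_a = ti$residues_a,
                                   residues_b = ti$residues_b),
                              eng$a, eng$b, cutoff = 10)
  expect_true(all(ev10$tp[1:2] <= ev$tp[1:2]))    # truth can only grow
  expect_true(all(ev10$fn[1:2] >= ev$fn[1:2]))

  # same prediction, wider truth: per-partner recall of the 5 A truth set
  # evaluated at 10 A never drops tp below the 5 A evaluation
  pred_half <- list(residues_a = ti$residues_a[1:2, ],
                    residues_b = ti$residues_b[1:2, ])
  e5 <- evaluate_prediction(pred_half, eng$a, eng$b, cutoff = 5)
  e10 <- evaluate_prediction(pred_half, eng$a, eng$b, cutoff = 10)
  expect_true(all(e10$tp[1:2] >= e5$tp[1:2] - 2))

  # unmappable residues are excluded with a warning
  bad <- list(residues_a = tibble::tibble(chain_id = "Z", residue_seq = 99L,
                                          icode = ""),
              residues_b = ti$residues_b)
  expect_warning(evaluate_prediction(bad, eng$a, eng$b), "not present")
})

test_that("macro and pooled partner combination both stay bounded", {
  eng <- engineered_pair(seed = 23, n_residues = 40)
  ti <- true_interface(eng$a, eng$b, 5)
  pred <- list(residues_a = ti$residues_a,
               residues_b = ti$residues_b[0, ])
  macro <- evaluate_prediction(pred, eng$a, eng$b)
  pooled <- evaluate_prediction(pred, eng$a, eng$b, pooled = TRUE)
  expect_equal(macro$recall[3], 0.5)
  expect_true(pooled$recall[3] > 0 && pooled$recall[3] < 1)
})

test_that("shuffle test: constant properties give p = 1, reruns are identical", {
  pair <- make_fixture_pair(fixture_spec(n_residues = 40, seed = 24))
  a <- pair$a; a$charge <- 0.5
  b <- pair$b; b$charge <- 0.5
  cfg <- grid_config(n_shuffles = 20, rng_seed = 3, rotation_step_deg = 45,
                     n_sphere_points = 120L)
  sh <- shuffle_test(a, b, "charge", cfg)
  expect_equal(sh$p_value, 1)
  expect_length(sh$null_scores, 20)
  expect_true(all(sh$null_scores == sh$observed_score))

  eng <- engineered_pair(seed = 24, n_residues = 40)
  cfg2 <- grid_config(n_shuffles = 15, rng_seed = 11,
                      rotation_step_deg = 45, n_sphere_points = 120L)
  s1 <- shuffle_test(eng$a, eng$b, "charge", cfg2)
  s2 <- shuffle_test(eng$a, eng$b, "charge", cfg2)
  expect_identical(s1$null_scores, s2$null_scores)
  expect_identical(s1$p_value, s2$p_value)
  expect_true(s1$p_value >= 0 && s1$p_value <= 1)
  expect_error(shuffle_test(eng$a, eng$b, "charge",
                            grid_config(n_shuffles = 0)), "n_shuffles")
})

test_that("tidiers summarise predictions and shuffle results", {
  eng <- engineered_pair(seed = 25, n_residues = 40)
  cfg <- grid_config(rotation_step_deg = 45, n_sphere_points = 120L)
  pred <- predict_interface(eng$a, eng$b, "charge", cfg)
  td <- tidy(pred)
  expect_equal(td$property, "charge")
  gl <- glance(pred)
  expect_equal(gl$n_residues_a, nrow(pred$residues_a))

  sh <- shuffle_test(eng$a, eng$b, "charge",
                     grid_config(n_shuffles = 10, rotation_step_deg = 45,
                                 n_sphere_points = 120L), prediction = pred)
  expect_equal(nrow(tidy(sh)), 10)
  expect_equal(glance(sh)$p_value, sh$p_value)
  p1 <- autoplot(sh)
  expect_s3_class(p1, "ggplot")
  g <- pred$internals$builds$a[[1]]$grids[[1]]$charge
  expect_s3_class(autoplot(g), "ggplot")
})
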