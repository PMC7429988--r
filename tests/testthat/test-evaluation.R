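# Dice, consensus, signed-rank comparison, split and experiment grid.

test_that("dice matches its definition and a counting oracle", {
  d <- c(6, 6, 3)
  a <- array(0L, d); a[1:2, 1:2, 1] <- 1L          # |A| = 4
  b <- array(0L, d); b[1:3, 1:2, 1] <- 1L          # |B| = 6, |A n B| = 4
  b[1, 1, 1] <- 0L                                 # |B| = 5... adjust below
  b <- array(0L, d); b[1:3, 1:2, 1] <- 1L
  a2 <- a; a2[2, 2, 1] <- 0L; a2[4, 4, 2] <- 1L    # overlap 3, |A| = 4
  expect_equal(dice(a2, b), 2 * 3 / (4 + 6))

  m <- array(1L, d)
  expect_equal(dice(m, m), 1)
  expect_equal(dice(a, array(0L, d) + 0L * a), dice(a, array(0L, d)))
  expect_equal(dice(array(0L, d), array(0L, d)), 1)  # both-empty convention
  disj <- array(0L, d); disj[6, 6, 3] <- 1L
  expect_equal(dice(a, disj), 0)
  expect_error(dice(a, array(0L, c(2, 2, 2))), "shape mismatch")

  # counting oracle on random pairs; symmetry; permutation invariance
  pqseg:::with_seed(14, {
    for (i in 1:100) {
      x <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
      y <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
      inter <- 0; sx <- 0; sy <- 0
      for (v in 1:64) {
        inter <- inter + (x[v] == 1 && y[v] == 1)
        sx <- sx + (x[v] == 1); sy <- sy + (y[v] == 1)
      }
      expected <- if (sx + sy == 0) 1 else 2 * inter / (sx + sy)
      expect_identical(dice(x, y), expected)
      expect_identical(dice(y, x), dice(x, y))
      perm <- sample(64)
      xp <- array(x[perm], dim(x)); yp <- array(y[perm], dim(y))
      expect_identical(dice(xp, yp), dice(x, y))
    }
  })
})

test_that("majority vote implements the strict-majority rule", {
  d <- c(5, 5, 2)
  m1 <- array(0L, d); m1[1:3, , ] <- 1L
  m2 <- array(0L, d); m2[2:4, , ] <- 1L
  m3 <- array(0L, d); m3[3:5, , ] <- 1L
  cons <- majority_vote(list(m1, m2, m3))
  expect_true(all(cons[2:4, , ] == 1))   # each covered by >= 2 observers
  expect_true(all(cons[c(1, 5), , ] == 0))
  expect_identical(majority_vote(list(m1, m1, m1)), m1)
  # even observers tie -> background (strict majority)
  expect_true(all(majority_vote(list(m1, m3))[3, , ] == 1))
  expect_true(all(majority_vote(list(m1, m3))[1, , ] == 0))
  expect_error(majority_vote(list(m1)), "at least 2")
  expect_error(majority_vote(list(m1, array(0L, c(2, 2, 2)))), "mismatch")
  # brute-force per-voxel count oracle on random observer triples
  pqseg:::with_seed(15, {
    for (i in 1:100) {
      ms <- lapply(1:3, function(j) array(rbinom(27, 1, 0.5), c(3, 3, 3)))
      got <- majority_vote(ms)
      for (v in 1:27) {
        expect_identical(got[v], as.integer(ms[[1]][v] + ms[[2]][v] +
                                              ms[[3]][v] >= 2))
      }
    }
  })
})

test_that("signed-rank comparison: exact branch, degeneracy, approximation", {
  expect_true(compare_models(rep(0.7, 6), rep(0.7, 6))$degenerate)
  # n = 6, all differences positive: two-sided exact p = 2/2^6
  res <- compare_models(c(0.8, 0.82, 0.85, 0.9, 0.78, 0.88),
                        c(0.7, 0.71, 0.72, 0.73, 0.74, 0.75))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.03125)
  # agreement with the base-R oracle on tie-free data
  pqseg:::with_seed(16, {
    for (i in 1:20) {
      a <- runif(10); b <- runif(10)
      ours <- compare_models(a, b)
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
    # exact and normal branches agree within 0.01 at n = 12
    for (i in 1:20) {
      a <- runif(12); b <- runif(12)
      pe <- compare_models(a, b, exact_limit = 12)$p_value
      pn <- compare_models(a, b, exact_limit = 4)$p_value
      expect_lt(abs(pe - pn), 0.01)
      expect_true(pe > 0 && pe <= 1)
      expect_true(pn > 0 && pn <= 1)
    }
  })
  # a clear paired shift at n = 30 is highly significant
  pqseg:::with_seed(17, {
    base <- runif(30, 0.4, 0.6)
    res30 <- compare_models(base + 0.3 + rnorm(30, 0, 0.01), base)
    expect_equal(res30$method, "normal")
    expect_lt(res30$p_value, 0.01)
  })
  expect_error(compare_models(1:3 / 4, 1:3 / 5), "at least 5")
})

test_that("splits are disjoint, covering and proportional", {
  ids <- sprintf("s%02d", 1:12)
  sp <- make_split(ids, fractions = c(8, 2, 2), seed = 3)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 2)
  expect_length(sp$test_ids, 2)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
  expect_equal(length(intersect(sp$train_ids, sp$test_ids)), 0)
  # the 40/10/30 clinical proportions at n = 12
  sp2 <- make_split(ids, fractions = c(40, 10, 30), seed = 3)
  expect_equal(lengths(sp2[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 6L, val_ids = 2L, test_ids = 4L))
  expect_identical(make_split(ids, c(8, 2, 2), seed = 3)$train_ids,
                   sp$train_ids)
})

test_that("the experiment grid keeps books, pairs cases and reproduces", {
  co <- tiny_cohort(n = 4)
  ids <- vapply(co, function(e) e$study$study_id, character(1))
  split <- make_split(ids, fractions = c(2, 1, 1), seed = 5)
  tc <- train_config(epochs = 1, segments_per_epoch = 12, batch_size = 6,
                     learning_rate = 1e-3, seed = 5)
  specs <- list(model_spec(0, input_channels = c("p", "FLAIR"),
                           target_mask = "p-mask"),
                model_spec(13))
  rep1 <- run_experiment_grid(co, specs, split, tc,
                              net_config_fn = tiny_net_config,
                              train_dice = FALSE)
  expect_s3_class(rep1, "pqseg_report")
  expect_equal(nrow(rep1), 2)
  expect_true(all(rep1$status == "ok"))
  expect_true(all(vapply(rep1$test_dcs, length, integer(1)) == 1))
  expect_true(all(unlist(rep1$test_dcs) >= 0 & unlist(rep1$test_dcs) <= 1))
  expect_true(all(is.na(rep1$test_sd_dc) | rep1$test_sd_dc >= 0))

  rep2 <- run_experiment_grid(co, specs, split, tc,
                              net_config_fn = tiny_net_config,
                              train_dice = FALSE)
  expect_equal(rep1$test_mean_dc, rep2$test_mean_dc)
  expect_identical(rep1$test_dcs, rep2$test_dcs)

  # tidy/glance surfaces
  td <- tidy(rep1)
  expect_true(all(c("model_id", "target", "test_dcs", "case") %in% names(td)))
  expect_equal(nrow(td), 2 * length(split$test_ids))
  gl <- glance(rep1)
  expect_equal(gl$n_train, c(2L, 2L))

  # a failing model is recorded, not dropped
  co_broken <- co
  for (i in seq_along(co_broken)) {
    co_broken[[i]]$masks$masks[["p-mask"]][] <- 0L
  }
  rep3 <- run_experiment_grid(co_broken, specs[1], split, tc,
                              net_config_fn = tiny_net_config,
                              train_dice = FALSE)
  expect_match(rep3$status, "failed")
})

test_that("stored per-case scores are reproducible from the trained model", {
  co <- tiny_cohort(n = 4)
  ids <- vapply(co, function(e) e$study$study_id, character(1))
  split <- make_split(ids, fractions = c(2, 1, 1), seed = 7)
  tc <- train_config(epochs = 1, segments_per_epoch = 10, batch_size = 5,
                     learning_rate = 1e-3, seed = 7)
  sp <- model_spec(0, input_channels = "FLAIR", target_mask = "FLAIR-mask")
  rep <- run_experiment_grid(co, list(sp), split, tc,
                             net_config_fn = tiny_net_config,
                             train_dice = FALSE)
  mod <- attr(rep, "models")[[1]]
  te <- co[ids %in% split$test_ids]
  rescored <- vapply(te, function(e) {
    dice(predict_study(mod, e$study, sp)$binary_mask,
         e$masks$masks[["FLAIR-mask"]])
  }, numeric(1))
  expect_identical(unname(rescored), unname(rep$test_dcs[[1]]))
})

test_that("reports render as plots and CSV tables", {
  co <- tiny_cohort(n = 4)
  ids <- vapply(co, function(e) e$study$study_id, character(1))
  split <- make_split(ids, fractions = c(2, 1, 1), seed = 5)
  tc <- train_config(epochs = 1, segments_per_epoch = 6, batch_size = 6,
                     learning_rate = 1e-3, seed = 5)
  rep <- run_experiment_grid(co, list(model_spec(15)), split, tc,
                             net_config_fn = tiny_net_config,
                             train_dice = FALSE)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  f <- file.path(withr::local_tempdir(), "report.csv")
  write_report_csv(rep, f)
  back <- utils::read.csv(f)
  expect_equal(back$test_mean_dc, rep$test_mean_dc, tolerance = 1e-12)
})
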