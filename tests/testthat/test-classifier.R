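# small synthetic training volumes: noise vs noise plus a bright central blob
make_blob_set <- function(n_per_class, d = 16L, strength = 0.5, seed = 1) {
  with_seed <- tomoshell:::with_seed
  with_seed(seed, {
    blob <- array(0, dim = c(d, d, d))
    ctr <- (d + 1) / 2
    idx <- expand.grid(z = 1:d, y = 1:d, x = 1:d)
    u2 <- (idx$z - ctr)^2 + (idx$y - ctr)^2 + (idx$x - ctr)^2
    blob[u2 <= (d / 4)^2] <- strength
    vols <- list(); labs <- character(0)
    for (i in seq_len(n_per_class)) {
      vols[[length(vols) + 1]] <- array(runif(d^3, 0, 0.3), dim = c(d, d, d))
      labs <- c(labs, "neg")
      vols[[length(vols) + 1]] <- array(runif(d^3, 0, 0.3), dim = c(d, d, d)) + blob
      labs <- c(labs, "pos")
    }
    list(vols = vols, labs = labs)
  })
}

tiny_model_cfg <- function() {
  # three blocks so 16^3 inputs keep a 2^3 final map (16 -> 8 -> 4 -> 2)
  model_config(n_blocks = 3, layers_per_block = 1, growth = 2, init_channels = 4)
}

test_that("preprocessing crops around the cell, normalizes and resizes", {
  spec <- tiny_spec(noise_sd = 0.002, center_offset_vox = c(2, -3, 1))
  tom <- make_phantom(spec, seed = 6)
  v <- preprocess_volume(tom, preprocess_config(c(16, 16, 16)))
  expect_identical(dim(v), c(16L, 16L, 16L))
  expect_equal(range(v), c(0, 1))

  # crop box contains the whole cell mask
  mask <- segment_cell(tom)
  ctr <- cell_center_radius(mask)$center
  r_um <- cell_center_radius(mask, spacing = tom$voxel_spacing_um)$radius
  rv <- ceiling(r_um / tom$voxel_spacing_um)
  co <- which(mask, arr.ind = TRUE)
  for (a in 1:3) {
    expect_gte(min(co[, a]), round(ctr[a]) - rv[a])
    expect_lte(max(co[, a]), round(ctr[a]) + rv[a])
  }

  # constant crop maps to all zeros by convention
  flat <- tomogram(array(1.35, dim = c(12, 12, 12)), 0.3, 1.337)
  v0 <- preprocess_volume(flat, preprocess_config(c(8, 8, 8)),
                          center = c(6, 6, 6), radius_um = 1)
  expect_true(all(v0 == 0))
  expect_error(preprocess_volume(flat, center = c(6, 6, 6), radius_um = 0),
               "radius")
})

test_that("dataset splits are 8:1:1, deterministic, and can isolate subjects", {
  labs <- rep(c("a", "b"), 50)
  sp <- split_dataset(labs, seed = 3)
  expect_equal(lengths(sp[c("train", "val", "test")]), c(train = 80L, val = 10L, test = 10L))
  expect_identical(sp, split_dataset(labs, seed = 3))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sort(unname(unlist(sp))), seq_along(labs))

  subj <- rep(sprintf("s%02d", 1:10), each = 10)
  sps <- split_dataset(labs, seed = 4, subject = subj, by_subject = TRUE)
  for (part in sps) {
    others <- setdiff(unlist(sps), part)
    expect_length(intersect(unique(subj[part]), unique(subj[others])), 0)
  }
})

test_that("concordance AUROC equals exhaustive pairwise enumeration", {
  # the worked toy case: 3 of 4 pairs concordant
  expect_equal(auroc(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  set.seed(19)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    labs <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # force ties
    expect_equal(auroc(scores, labs), oracle_auroc(scores, labs))
  }
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("concordance AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  scores <- round(runif(60), 2)
  labs <- runif(60) < 0.4
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labs, scores))))
  expect_equal(auroc(scores, labs), ref, tolerance = 1e-12)
})

test_that("network gradients match finite differences", {
  mc <- model_config(n_blocks = 2, layers_per_block = 1, growth = 2,
                     init_channels = 2)
  net <- tomoshell:::init_net_params(mc, seed = 42)
  cfg <- tomoshell:::net_cfg(mc)
  set.seed(7)
  x <- array(runif(8 * 8 * 8 * 3), dim = c(8, 8, 8, 1, 3))
  y <- c(0L, 1L, 0L)
  copy <- function(s) lapply(s, function(v) v + 0)
  res <- tomoshell:::cpp_net_train_batch(net$params, copy(net$state), x, y, cfg)
  eps <- 1e-6
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    ii <- unique(round(seq(1, length(p), length.out = min(3, length(p)))))
    for (i in ii) {
      pp <- net$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      l1 <- tomoshell:::cpp_net_train_batch(pp, copy(net$state), x, y, cfg)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      l2 <- tomoshell:::cpp_net_train_batch(pp, copy(net$state), x, y, cfg)$loss
      fd <- (l1 - l2) / (2 * eps)
      an <- res$grads[[nm]][i]
      expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("the desk-scale network learns a separable two-class problem", {
  ds <- make_blob_set(20, seed = 23)
  sp <- split_dataset(ds$labs, ratios = c(0.7, 0.15, 0.15), seed = 2)
  tc <- train_config(batch_size = 8, lr = 0.005, max_epochs = 12, patience = 12)
  mod <- train_classifier(ds$vols[sp$train], ds$labs[sp$train],
                          ds$vols[sp$val], ds$labs[sp$val],
                          mc = tiny_model_cfg(), tc = tc, seed = 31)
  expect_s3_class(mod, "dense3d_model")
  expect_lte(nrow(mod$history), mod$best_epoch + tc$patience)
  pr <- predict(mod, ds$vols[sp$train])
  acc <- mean(colnames(pr)[max.col(pr)] == ds$labs[sp$train])
  expect_gte(acc, 0.95)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)

  # saliency: non-negative, input-shaped, normalized to 1, cell-localized
  smap <- saliency(mod, ds$vols[[2]])
  expect_identical(dim(smap), c(16L, 16L, 16L))
  expect_gte(min(smap), 0)
  expect_equal(max(smap), 1)
  expect_true(all(saliency(mod, array(0, dim = c(16, 16, 16))) == 0))
  d <- 16; ctr <- (d + 1) / 2
  idx <- expand.grid(z = 1:d, y = 1:d, x = 1:d)
  inside <- array((idx$z - ctr)^2 + (idx$y - ctr)^2 + (idx$x - ctr)^2 <= (d / 4)^2,
                  dim = c(d, d, d))
  pos_vols <- ds$vols[sp$test][ds$labs[sp$test] == "pos"]
  loc <- vapply(pos_vols, function(v) {
    m <- saliency(mod, v, class = "pos")
    mean(m[inside]) - mean(m[!inside])
  }, 0.0)
  expect_gt(mean(loc), 0)
})

test_that("training input shape must match the pooling ladder", {
  ds <- make_blob_set(4, d = 12L, seed = 5)
  expect_error(train_classifier(ds$vols[1:6], ds$labs[1:6], ds$vols[7:8],
                                ds$labs[7:8], mc = tiny_model_cfg()),
               "divisible")
})

test_that("bootstrap AUROC is deterministic, honest on separated scores, and
           tightens with more cells", {
  sep <- bootstrap_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), k = 2,
                         iterations = 50, seed = 1)
  expect_equal(sep$auroc, 1)
  expect_equal(sep$ci_upper - sep$ci_lower, 0)

  set.seed(33)
  scores <- c(runif(60, 0.35, 1), runif(60, 0, 0.65))
  labs <- rep(c(1, 0), each = 60)
  r1 <- bootstrap_auroc(scores, labs, k = 1, iterations = 400, seed = 9)
  r5 <- bootstrap_auroc(scores, labs, k = 5, iterations = 400, seed = 9)
  expect_lte(r5$ci_upper - r5$ci_lower, r1$ci_upper - r1$ci_lower)
  expect_identical(r1$draws,
                   bootstrap_auroc(scores, labs, k = 1, iterations = 400,
                                   seed = 9)$draws)

  # subject-level aggregation uses one score per subject
  subj <- rep(sprintf("s%d", 1:12), each = 10)
  rs <- bootstrap_auroc(scores, labs, k = 3, subject = subj,
                        iterations = 200, seed = 4)
  expect_true(rs$auroc > 0.5)
  expect_error(bootstrap_auroc(scores, rep(1, 120), k = 1), "both classes")
})
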