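#' Preprocessing configuration for the 3D classifier
#'
#' Each cell is centre-cropped to a box of centre plus/minus its radius per
#' axis (clipped at the volume edge and padded with the medium RI), resized
#' by trilinear interpolation to a fixed target shape chosen before
#' training, and min-max normalized to \[0, 1\] per image (normalization
#' last, so every non-constant volume attains 0 and 1 exactly).
#'
#' @param resize_target integer triple (z, y, x), or `"median"` to use the
#'   per-axis median of the training-set crop shapes (fixed at training
#'   time and reused at inference).
#' @param nominal_extent nominal acquisition extent in voxels; recorded for
#'   provenance, crops larger than it are refused.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(resize_target = c(32, 32, 32),
                              nominal_extent = c(210, 276, 276)) {
  if (!identical(resize_target, "median")) {
    resize_target <- as.integer(as_triple(resize_target, "resize_target"))
    if (any(resize_target < 2)) stop("'resize_target' must be >= 2 per axis")
  }
  structure(list(resize_target = resize_target,
                 nominal_extent = as.integer(as_triple(nominal_extent, "nominal_extent"))),
            class = "preprocess_config")
}

#' Trilinear resize of a 3D array
#'
#' @param a numeric 3D array.
#' @param target integer triple of output dimensions.
#' @return resized array.
#' @export
resize_trilinear <- function(a, target) {
  target <- as.integer(as_triple(target, "target"))
  for (ax in 1:3) {
    n_src <- dim(a)[ax]
    n_tgt <- target[ax]
    if (n_src == n_tgt) next
    s <- (seq_len(n_tgt) - 0.5) * (n_src / n_tgt) - 0.5  # 0-based source coord
    lo <- pmin(pmax(floor(s), 0), n_src - 1)
    hi <- pmin(lo + 1, n_src - 1)
    w <- pmin(pmax(s - lo, 0), 1)
    a_lo <- switch(ax, a[lo + 1, , , drop = FALSE], a[, lo + 1, , drop = FALSE],
                   a[, , lo + 1, drop = FALSE])
    a_hi <- switch(ax, a[hi + 1, , , drop = FALSE], a[, hi + 1, , drop = FALSE],
                   a[, , hi + 1, drop = FALSE])
    a <- sweep(a_lo, ax, 1 - w, "*") + sweep(a_hi, ax, w, "*")
  }
  a
}

#' Preprocess one tomogram for the classifier
#'
#' Crop, normalize, resize (see [preprocess_config()]). A constant crop
#' normalizes to all zeros by convention.
#'
#' @param tom a [tomogram()].
#' @param cfg a [preprocess_config()]; `resize_target` must be numeric here
#'   (resolve `"median"` beforehand with [median_crop_shape()]).
#' @param center,radius_um optional precomputed centre (array indices) and
#'   physical radius; segmented from the tomogram when `NULL`.
#' @param config [morphometry_config()] used if segmentation is needed.
#' @return numeric 3D array with values in \[0, 1\] and shape
#'   `cfg$resize_target`.
#' @export
preprocess_volume <- function(tom, cfg = preprocess_config(), center = NULL,
                              radius_um = NULL, config = morphometry_config()) {
  if (identical(cfg$resize_target, "median")) {
    stop("resolve resize_target = \"median\" before preprocessing ",
         "(see median_crop_shape())")
  }
  if (is.null(center) || is.null(radius_um)) {
    mask <- segment_cell(tom, config)
    center <- cell_center_radius(mask)$center
    radius_um <- cell_center_radius(mask, spacing = tom$voxel_spacing_um)$radius
  }
  if (radius_um <= 0) stop("cell radius is zero; cannot define a crop box")
  crop <- crop_box(tom, center, radius_um)
  out <- resize_trilinear(crop, cfg$resize_target)
  # normalize after resampling so the output attains 0 and 1 exactly
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0
}

# axis-aligned box centre +- radius per axis, padded with medium RI
crop_box <- function(tom, center, radius_um) {
  d <- dim(tom$ri)
  rv <- pmax(1L, as.integer(ceiling(radius_um / tom$voxel_spacing_um)))
  ctr <- as.integer(round(center))
  lo <- ctr - rv
  hi <- ctr + rv
  out <- array(tom$medium_ri, dim = hi - lo + 1L)
  src <- lapply(1:3, function(a) max(lo[a], 1L):min(hi[a], d[a]))
  dst <- lapply(1:3, function(a) (src[[a]] - lo[a]) + 1L)
  out[dst[[1]], dst[[2]], dst[[3]]] <- tom$ri[src[[1]], src[[2]], src[[3]]]
  out
}

#' Median crop shape of a set of tomograms
#'
#' Resolves the `"median"` resize target: the per-axis median of the crop
#' box shapes over the (training) set, rounded up to the nearest multiple
#' of `2^n_blocks` so the pooling ladder divides evenly.
#'
#' @param tomograms list of [tomogram()] objects.
#' @param config [morphometry_config()] for segmentation.
#' @param n_blocks number of dense blocks the model will use.
#' @return integer triple.
#' @export
median_crop_shape <- function(tomograms, config = morphometry_config(),
                              n_blocks = 4L) {
  shapes <- vapply(tomograms, function(tom) {
    mask <- segment_cell(tom, config)
    ctr <- cell_center_radius(mask)$center
    r <- cell_center_radius(mask, spacing = tom$voxel_spacing_um)$radius
    2L * pmax(1L, as.integer(ceiling(r / tom$voxel_spacing_um))) + 1L
  }, integer(3))
  med <- apply(shapes, 1L, stats::median)
  mult <- 2L^n_blocks
  as.integer(pmax(mult, ceiling(med / mult) * mult))
}

#' Split a dataset into train/validation/test
#'
#' Deterministic 8:1:1 (configurable) split given a seed. The default
#' splits at the cell level; `by_subject = TRUE` assigns whole subjects to
#' partitions so no subject spans two of them. If a class is absent from
#' any partition the split is reshuffled (up to `max_attempts`), then an
#' error is raised.
#'
#' @param labels class label per cell.
#' @param ratios train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @param subject optional subject id per cell, for `by_subject`.
#' @param by_subject split whole subjects instead of cells.
#' @param max_attempts reshuffle attempts when a class is missing.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          subject = NULL, by_subject = FALSE,
                          max_attempts = 20L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("split fractions must sum to 1")
  n <- length(labels)
  if (by_subject && is.null(subject)) stop("'by_subject' needs subject ids")
  seeds <- derive_seeds(seed, max_attempts)
  for (att in seq_len(max_attempts)) {
    sp <- with_seed(seeds[att], {
      if (by_subject) {
        subj <- sample(unique(subject))
        csize <- cumsum(vapply(subj, function(s) sum(subject == s), 0L)) / n
        p <- findInterval(csize - 1e-12, cumsum(ratios)[1:2]) + 1L
        part <- p[match(subject, subj)]
        list(train = which(part == 1L), val = which(part == 2L),
             test = which(part == 3L))
      } else {
        ord <- sample.int(n)
        ntr <- floor(n * ratios[1])
        nva <- floor(n * ratios[2])
        list(train = sort(ord[seq_len(ntr)]),
             val = sort(ord[ntr + seq_len(nva)]),
             test = sort(ord[(ntr + nva + 1):n]))
      }
    })
    ok <- all(vapply(sp, function(ix) {
      length(ix) > 0 && length(unique(labels[ix])) == length(unique(labels))
    }, TRUE))
    if (ok) return(sp)
    if (att < max_attempts) {
      warning("a class is absent from a partition; reshuffling (attempt ",
              att, ")")
    }
  }
  stop("could not produce a split with every class in every partition after ",
       max_attempts, " attempts")
}

#' Model configuration for the 3D dense-block network
#'
#' A DenseNet-style 3D CNN: an initial 3x3x3 convolution and 2x average
#' pooling, `n_blocks` dense blocks of `layers_per_block` composite layers
#' (batch norm, ReLU, 3x3x3 convolution producing `growth` channels,
#' concatenated onto the running feature stack), 1x1x1 compression and 2x
#' pooling between blocks, then batch norm, ReLU, global average pooling
#' and a linear classifier. The desk default (4 blocks x 2 layers = 8 dense
#' layers, growth 4) trains on a CPU in minutes; a paper-scale deep
#' configuration is expressible through the same fields.
#'
#' @param n_blocks number of dense blocks.
#' @param layers_per_block dense layers per block.
#' @param growth channels added by each dense layer.
#' @param init_channels channels of the initial convolution.
#' @param compression transition compression factor in (0, 1].
#' @param n_classes number of classes.
#' @param task `"diagnosis"` (T1 vs H) or `"prognosis"` (T1 survivor vs
#'   non-survivor); defines the label mapping used by the pipeline.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_blocks = 4L, layers_per_block = 2L, growth = 4L,
                         init_channels = 8L, compression = 0.5, n_classes = 2L,
                         task = c("diagnosis", "prognosis")) {
  task <- match.arg(task)
  stopifnot(is_count(n_blocks), is_count(layers_per_block), is_count(growth),
            is_count(init_channels), is_count(n_classes), n_classes >= 2,
            compression > 0, compression <= 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 layers_per_block = as.integer(layers_per_block),
                 growth = as.integer(growth),
                 init_channels = as.integer(init_channels),
                 compression = compression,
                 n_classes = as.integer(n_classes),
                 task = task),
            class = "model_config")
}

#' Training configuration
#'
#' Cross-entropy loss, stochastic gradient descent with momentum, cosine
#' annealing of the learning rate, once-per-image-per-epoch augmentation
#' (axis-aligned 90-degree in-plane rotations and horizontal/vertical
#' flips), and early stopping on validation loss.
#'
#' @param batch_size mini-batch size.
#' @param lr initial learning rate of the cosine schedule.
#' @param lr_period cosine annealing period, epochs.
#' @param momentum SGD momentum.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement), >= 1.
#' @param augment enable augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 0.001, lr_period = 64L,
                         momentum = 0.9, max_epochs = 64L, patience = 30L,
                         augment = TRUE) {
  stopifnot(is_count(batch_size), is_count(lr_period), is_count(max_epochs),
            is_count(patience), lr > 0, momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_period = as.integer(lr_period), momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), augment = isTRUE(augment)),
            class = "train_config")
}

net_cfg <- function(mc) {
  list(init_channels = mc$init_channels, growth = mc$growth,
       layers_per_block = mc$layers_per_block, n_blocks = mc$n_blocks,
       n_classes = mc$n_classes, compression = mc$compression)
}

# channel bookkeeping mirroring the C++ forward walk
net_channel_walk <- function(mc) {
  C <- mc$init_channels
  walk <- list(conv0 = C)
  for (b in seq_len(mc$n_blocks) - 1L) {
    for (l in seq_len(mc$layers_per_block) - 1L) {
      walk[[sprintf("db%d.l%d", b, l)]] <- C  # channels entering the layer
      C <- C + mc$growth
    }
    if (b < mc$n_blocks - 1L) {
      walk[[sprintf("tr%d", b)]] <- c(C, floor(mc$compression * C))
      C <- floor(mc$compression * C)
    }
  }
  walk$final <- C
  walk
}

# He-initialized parameters and batch-norm state for the network
init_net_params <- function(mc, seed = NULL) {
  with_seed(seed, {
    walk <- net_channel_walk(mc)
    params <- list(); state <- list()
    he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
    add_bn <- function(nm, C) {
      params[[paste0(nm, ".g")]] <<- rep(1, C)
      params[[paste0(nm, ".b")]] <<- rep(0, C)
      state[[paste0(nm, ".m")]] <<- rep(0, C)
      state[[paste0(nm, ".v")]] <<- rep(1, C)
    }
    C0 <- mc$init_channels
    params[["conv0.W"]] <- he(c(3, 3, 3, 1, C0), 27)
    add_bn("bn0", C0)
    for (b in seq_len(mc$n_blocks) - 1L) {
      for (l in seq_len(mc$layers_per_block) - 1L) {
        Cin <- walk[[sprintf("db%d.l%d", b, l)]]
        add_bn(sprintf("db%d.l%d.bn", b, l), Cin)
        params[[sprintf("db%d.l%d.W", b, l)]] <- he(c(3, 3, 3, Cin, mc$growth), 27 * Cin)
      }
      if (b < mc$n_blocks - 1L) {
        ct <- walk[[sprintf("tr%d", b)]]
        add_bn(sprintf("tr%d.bn", b), ct[1])
        params[[sprintf("tr%d.W", b)]] <- he(c(ct[1], ct[2]), ct[1])
      }
    }
    Cf <- walk$final
    add_bn("bnF", Cf)
    params[["fc.W"]] <- he(c(Cf, mc$n_classes), Cf)
    params[["fc.b"]] <- rep(0, mc$n_classes)
    list(params = params, state = state)
  })
}

# stack a list of 3D arrays into the (D,H,W,1,N) batch layout
stack_volumes <- function(vols, idx = seq_along(vols)) {
  d <- dim(vols[[idx[1]]])
  x <- array(0, dim = c(d, 1L, length(idx)))
  for (i in seq_along(idx)) x[, , , 1L, i] <- vols[[idx[i]]]
  x
}

# random axis-aligned augmentation: k * 90-degree in-plane rotation plus
# optional horizontal/vertical flips (interpolation-free)
augment_volume <- function(a) {
  k <- sample(0:3, 1)
  if (k > 0 && dim(a)[2] == dim(a)[3]) for (i in seq_len(k)) {
    a <- aperm(a, c(1, 3, 2))
    a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  }
  if (runif(1) < 0.5) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  if (runif(1) < 0.5) a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  a
}

#' Train the 3D dense-block classifier
#'
#' Stochastic gradient descent with momentum on cross-entropy loss, cosine
#' annealing of the learning rate, once-per-image-per-epoch augmentation,
#' and early stopping on validation loss: training stops after
#' `patience` epochs without improvement and the parameters of the best
#' epoch are kept.
#'
#' @param x_train,x_val lists of preprocessed volumes (equal shapes, values
#'   in \[0, 1\]).
#' @param y_train,y_val class labels (factor or character); both classes
#'   must appear in both sets.
#' @param mc a [model_config()].
#' @param tc a [train_config()].
#' @param seed integer seed governing initialization, shuffling and
#'   augmentation.
#' @param verbose print per-epoch losses.
#' @return object of class `dense3d_model` with elements `params`, `state`,
#'   `model_config`, `train_config`, `classes`, `input_shape`, `history`
#'   (data.frame) and `best_epoch`.
#' @export
train_classifier <- function(x_train, y_train, x_val, y_val,
                             mc = model_config(), tc = train_config(),
                             seed = 1L, verbose = FALSE) {
  classes <- sort(unique(c(as.character(y_train), as.character(y_val))))
  if (length(classes) != mc$n_classes) {
    stop("found ", length(classes), " classes but model expects ", mc$n_classes)
  }
  if (length(unique(as.character(y_train))) < 2L ||
      length(unique(as.character(y_val))) < 2L) {
    stop("both classes must appear in the training and validation sets")
  }
  ytr <- match(as.character(y_train), classes) - 1L
  yva <- match(as.character(y_val), classes) - 1L
  d <- dim(x_train[[1]])
  if (any(d %% 2L^mc$n_blocks != 0L) || any(d %/% 2L^mc$n_blocks < 1L)) {
    stop("input shape ", paste(d, collapse = "x"), " must be divisible by 2^",
         mc$n_blocks, " (one initial pooling plus ", mc$n_blocks - 1L,
         " transitions)")
  }
  cfg <- net_cfg(mc)
  seeds <- derive_seeds(seed, 2L)
  net <- init_net_params(mc, seed = seeds[1])
  params <- net$params
  # batch-norm running stats are updated in place by the C++ pass, so the
  # working state and any snapshot must be genuine copies
  copy_state <- function(s) lapply(s, function(v) v + 0)
  state <- copy_state(net$state)
  vel <- lapply(params, function(p) p * 0)
  xval <- stack_volumes(x_val)
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  hist <- list()
  n <- length(x_train)
  with_seed(seeds[2], {
    for (epoch in seq_len(tc$max_epochs)) {
      lr <- tc$lr * 0.5 * (1 + cos(pi * ((epoch - 1) %% tc$lr_period) / tc$lr_period))
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, n)]
        vols <- x_train[idx]
        if (tc$augment) vols <- lapply(vols, augment_volume)
        xb <- stack_volumes(vols)
        res <- tryCatch(
          cpp_net_train_batch(params, state, xb, ytr[idx], cfg),
          error = function(e) {
            stop("training diverged at epoch ", epoch,
                 " (last completed epoch ", epoch - 1L, "): ",
                 conditionMessage(e))
          })
        for (nm in names(params)) {
          vel[[nm]] <- tc$momentum * vel[[nm]] - lr * res$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + res$loss; nb <- nb + 1
      }
      vfw <- cpp_net_forward(params, state, xval, cfg, FALSE)
      vp <- pmax(vfw$probs[cbind(yva + 1L, seq_along(yva))], 1e-300)
      val_loss <- mean(-log(vp))
      val_acc <- mean(max.col(t(vfw$probs)) == yva + 1L)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = ep_loss / nb,
                                  val_loss = val_loss, val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d lr %.5f train %.4f val %.4f acc %.3f",
                        epoch, lr, ep_loss / nb, val_loss, val_acc))
      }
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params,
                     state = copy_state(state),
                     epoch = epoch)
      }
      if (epoch - best$epoch >= tc$patience) break
    }
  })
  structure(list(params = best$params, state = best$state,
                 model_config = mc, train_config = tc,
                 classes = classes, input_shape = d,
                 history = do.call(rbind, hist), best_epoch = best$epoch),
            class = "dense3d_model")
}

#' @export
print.dense3d_model <- function(x, ...) {
  mc <- x$model_config
  cat("<dense3d_model> ", mc$task, ": ", paste(x$classes, collapse = " vs "),
      "\n", sep = "")
  cat("  ", mc$n_blocks, " dense blocks x ", mc$layers_per_block,
      " layers (growth ", mc$growth, "), input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs, best epoch ", x$best_epoch,
      " (val loss ", signif(min(x$history$val_loss), 4), ")\n", sep = "")
  invisible(x)
}

#' Predict class probabilities from a trained model
#'
#' @param object a `dense3d_model`.
#' @param volumes list of preprocessed volumes with the model's input
#'   shape.
#' @param type `"prob"` (matrix of class probabilities) or `"class"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return matrix (cells x classes) of probabilities, or a character vector
#'   of class labels.
#' @export
predict.dense3d_model <- function(object, volumes, type = c("prob", "class"),
                                  batch_size = 16L, ...) {
  type <- match.arg(type)
  if (is.array(volumes) && length(dim(volumes)) == 3L) volumes <- list(volumes)
  cfg <- net_cfg(object$model_config)
  n <- length(volumes)
  probs <- matrix(0, n, object$model_config$n_classes,
                  dimnames = list(NULL, object$classes))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- stack_volumes(volumes, idx)
    probs[idx, ] <- t(cpp_net_forward(object$params, object$state, xb, cfg,
                                      FALSE)$probs)
  }
  if (type == "class") object$classes[max.col(probs)] else probs
}

#' AUROC by pairwise concordance
#'
#' The probability that a random positive scores above a random negative,
#' ties counted one half (equivalently the rank-sum / Mann-Whitney form).
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels logical or two-level labels; `positive` names the positive
#'   level when labels are not logical.
#' @param positive positive class label.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (is.null(positive)) positive <- lev[length(lev)]
    labels <- as.character(labels) == positive
  }
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("need both classes to compute AUROC")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Bootstrap few-cell AUROC
#'
#' Replicates few-cell evaluation: per iteration, `k` cells are sampled per
#' unit and the AUROC of the resulting scores is recorded; the point
#' estimate is the mean over iterations with a 2.5/97.5 percentile
#' confidence interval. With subject ids, the `k` sampled cells of each
#' subject are aggregated (mean probability, or majority vote) into one
#' score per subject and the AUROC is computed across subjects. Without
#' subject ids, `k` cells are sampled per class and the AUROC is computed
#' over the individual cell scores. Sampling is with replacement whenever a
#' unit holds fewer than `k` cells.
#'
#' @param scores per-cell positive-class probabilities.
#' @param labels per-cell class labels.
#' @param k cells sampled per unit, typically 1..5.
#' @param subject optional subject id per cell.
#' @param iterations bootstrap iterations.
#' @param aggregate `"mean"` of probabilities or majority `"vote"`.
#' @param positive positive class label.
#' @param seed integer seed.
#' @return object of class `auroc_result`: list with `k`, `auroc`,
#'   `ci_lower`, `ci_upper`, `iterations` and the iteration `draws`.
#' @export
bootstrap_auroc <- function(scores, labels, k = 1L, subject = NULL,
                            iterations = 1000L, aggregate = c("mean", "vote"),
                            positive = NULL, seed = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(is_count(k), is_count(iterations))
  if (!is.logical(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (is.null(positive)) positive <- lev[length(lev)]
    labels <- as.character(labels) == positive
  }
  if (!any(labels) || all(labels)) stop("need both classes in the test set")
  agg <- function(s) if (aggregate == "mean") mean(s) else mean(s > 0.5)
  draws <- with_seed(seed, {
    if (!is.null(subject)) {
      units <- split(seq_along(scores), subject)
      ulab <- vapply(units, function(ix) labels[ix[1]], TRUE)
      if (!any(ulab) || all(ulab)) {
        stop("need subjects of both classes for subject-level AUROC")
      }
      vapply(seq_len(iterations), function(i) {
        us <- vapply(units, function(ix) {
          agg(scores[sample(ix, k, replace = length(ix) < k)])
        }, 0.0)
        auroc(us, ulab)
      }, 0.0)
    } else {
      pos <- which(labels); neg <- which(!labels)
      vapply(seq_len(iterations), function(i) {
        ip <- sample(pos, k, replace = length(pos) < k)
        ineg <- sample(neg, k, replace = length(neg) < k)
        auroc(c(scores[ip], scores[ineg]),
              c(rep(TRUE, k), rep(FALSE, k)))
      }, 0.0)
    }
  })
  structure(list(k = as.integer(k), auroc = mean(draws),
                 ci_lower = unname(stats::quantile(draws, 0.025)),
                 ci_upper = unname(stats::quantile(draws, 0.975)),
                 iterations = as.integer(iterations), draws = draws),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc_result> k = %d: AUROC %.4f (95%% CI %.4f-%.4f, %d resamples)\n",
              x$k, x$auroc, x$ci_lower, x$ci_upper, x$iterations))
  invisible(x)
}

#' Evaluate a trained classifier over 1..k cells
#'
#' Predicts positive-class probabilities on the test set and runs
#' [bootstrap_auroc()] for each requested number of cells.
#'
#' @param model a `dense3d_model`.
#' @param volumes list of preprocessed test volumes.
#' @param labels test labels.
#' @param cells numbers of cells per prediction (default 1:5).
#' @param subject optional subject ids.
#' @param iterations bootstrap iterations.
#' @param seed integer seed.
#' @return data.frame with columns k, auroc, ci_lower, ci_upper.
#' @export
eval_classifier <- function(model, volumes, labels, cells = 1:5,
                            subject = NULL, iterations = 1000L, seed = NULL) {
  probs <- predict(model, volumes)
  pos <- model$classes[length(model$classes)]
  scores <- probs[, pos]
  seeds <- derive_seeds(seed, length(cells))
  rows <- lapply(seq_along(cells), function(i) {
    r <- bootstrap_auroc(scores, labels, k = cells[i], subject = subject,
                         iterations = iterations, positive = pos,
                         seed = seeds[i])
    data.frame(k = r$k, auroc = r$auroc, ci_lower = r$ci_lower,
               ci_upper = r$ci_upper)
  })
  out <- do.call(rbind, rows)
  attr(out, "positive") <- pos
  out
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping on the network's last
#' post-activation feature maps (those feeding global average pooling):
#' channel weights are the spatial means of the target-class logit
#' gradient, the map is the ReLU of the weighted channel sum, upsampled
#' trilinearly to the input shape and normalized to a maximum of 1. With
#' this architecture the construction coincides with the classical class
#' activation map. A constant input yields an all-zero map by convention.
#'
#' @param model a `dense3d_model`.
#' @param volume one preprocessed volume.
#' @param class target class label (default: the predicted class).
#' @param block dense block (1-based) whose feature maps are weighted;
#'   defaults to the deepest block whose maps retain at least 4 voxels per
#'   axis, since the maps above the last pooling stages carry little or no
#'   spatial information.
#' @return non-negative 3D array with the input's spatial shape, maximum 1
#'   (or all zeros).
#' @export
saliency <- function(model, volume, class = NULL, block = NULL) {
  stopifnot(inherits(model, "dense3d_model"))
  if (max(volume) == min(volume)) return(array(0, dim = dim(volume)))
  cfg <- net_cfg(model$model_config)
  nb <- model$model_config$n_blocks
  if (is.null(block)) {
    d <- min(dim(volume))
    block <- max(1L, min(nb, as.integer(floor(log2(d / 4)))))
  }
  if (block < 1 || block > nb) stop("'block' must be in 1..", nb)
  x <- stack_volumes(list(volume))
  if (is.null(class)) {
    p <- predict(model, list(volume))
    class <- model$classes[which.max(p[1, ])]
  }
  tgt <- match(as.character(class), model$classes)
  if (is.na(tgt)) stop("unknown class '", class, "'")
  gc <- cpp_net_gradcam(model$params, model$state, x, tgt - 1L, block - 1L, cfg)
  w <- apply(gc$grad, 4L, mean)
  fm <- gc$fmap
  map <- array(0, dim = dim(fm)[1:3])
  for (c in seq_along(w)) map <- map + w[c] * fm[, , , c]
  map[map < 0] <- 0
  map <- resize_trilinear(map, dim(volume))
  map[map < 0] <- 0
  if (max(map) > 0) map <- map / max(map)
  map
}
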