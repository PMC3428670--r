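#' ROC curve over all score thresholds
#'
#' Points are computed at every distinct score value with ties grouped, giving
#' the trapezoidal geometry whose area equals the Mann-Whitney concordance
#' statistic (ties counted one half).
#'
#' @param scores numeric classifier scores (higher = more W-like)
#' @param labels true classes; `"W"`/`TRUE` is the positive class
#' @param positive label treated as positive (default `"W"`)
#' @return object of class `roc_points`: list with `points`
#'   (`threshold`, `fpr`, `tpr`) and `auc`
#' @export
roc_curve <- function(scores, labels, positive = "W") {
  if (length(scores) != length(labels))
    stop("roc_curve: scores and labels differ in length")
  y <- if (is.logical(labels)) labels else labels == positive
  if (!any(y) || all(y)) stop("roc_curve: both classes must be present")
  P <- sum(y); N <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(yo)[grp_end]
  fp <- cumsum(!yo)[grp_end]
  pts <- data.frame(threshold = c(Inf, s[grp_end]),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  a <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = a), class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.6f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC with tie grouping; equals the probability that a random
#' positive outscores a random negative, ties counted one half.
#'
#' @inheritParams roc_curve
#' @return numeric in `[0, 1]`
#' @export
auc <- function(scores, labels, positive = "W") {
  roc_curve(scores, labels, positive)$auc
}

.draw_training_idx <- function(features, n_w, ratio, stratify, bin = 500L) {
  w_idx <- which(features$label == "W")
  n_idx <- which(features$label == "NONW")
  n_nonw <- round(ratio * n_w)
  if (length(w_idx) < n_w || length(n_idx) < n_nonw)
    stop("insufficient labeled contigs: have ", length(w_idx), " W and ",
         length(n_idx), " non-W, need ", n_w, " and ", n_nonw)
  if (!stratify)
    return(c(sample(w_idx, n_w), sample(n_idx, n_nonw)))
  lb <- length_bin(features$length, bin)
  c(.stratified_sample(w_idx, lb[w_idx], n_w),
    .stratified_sample(n_idx, lb[n_idx], n_nonw))
}

# proportional allocation across strata (largest remainder), at least one
# member from every occupied stratum while the budget allows
.stratified_sample <- function(idx, strata, n) {
  tab <- table(strata)
  ns <- length(tab)
  target <- n * as.numeric(tab) / length(idx)
  alloc <- floor(target)
  if (n >= ns) alloc <- pmax(alloc, 1)
  alloc <- pmin(alloc, as.numeric(tab))
  rem <- n - sum(alloc)
  while (rem != 0) {
    room <- as.numeric(tab) - alloc
    if (rem > 0) {
      pick <- which(room > 0)[order(-(target - alloc)[room > 0])][1]
      alloc[pick] <- alloc[pick] + 1; rem <- rem - 1
    } else {
      pick <- which(alloc > if (n >= ns) 1 else 0)
      pick <- pick[order((target - alloc)[pick])][1]
      alloc[pick] <- alloc[pick] - 1; rem <- rem + 1
    }
  }
  out <- integer(0)
  lv <- names(tab)
  for (i in seq_len(ns)) {
    at <- idx[strata == lv[i]]
    if (alloc[i] > 0) out <- c(out, sample(at, alloc[i]))
  }
  out
}

#' Cross-validated AUC of the classifier
#'
#' Per iteration, a training set of `n_w` W and `round(ratio * n_w)` non-W
#' contigs is drawn at random (allocated proportionally across length bins
#' when conditioning), the remainder is scored, and the AUC recorded.
#' Iterations whose validation fold lacks a class are redrawn and logged.
#'
#' @param features labeled feature data.frame
#' @param n_w W contigs per training set (default 50)
#' @param ratio non-W:W training ratio (default 1)
#' @param iterations number of random splits (default 100)
#' @param seed RNG seed
#' @param bin_width,epsilon,length_condition passed to [wbayes()]
#' @return object of class `cv_result`: list with `mean_auc`, `sd_auc`,
#'   `aucs`, `n_rerolled`, and the call parameters
#' @export
cross_validate <- function(features, n_w = 50L, ratio = 1, iterations = 100L,
                           seed = NULL, bin_width = 0.005, epsilon = 1e-6,
                           length_condition = TRUE) {
  stopifnot(iterations >= 1)
  aucs <- numeric(iterations)
  n_rerolled <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      repeat {
        tr_idx <- .draw_training_idx(features, n_w, ratio, length_condition)
        val <- features[-tr_idx, , drop = FALSE]
        if (any(val$label == "W") && any(val$label == "NONW")) break
        n_rerolled <- n_rerolled + 1L
        if (n_rerolled > 100L * iterations)
          stop("cross_validate: cannot draw a validation fold with both classes")
      }
      model <- wbayes(features[tr_idx, , drop = FALSE], bin_width = bin_width,
                      epsilon = epsilon, length_condition = length_condition)
      aucs[it] <- auc(predict(model, val), val$label)
    }
  })
  if (n_rerolled > 0)
    message("cross_validate: redrew ", n_rerolled,
            " split(s) whose validation fold lacked a class")
  structure(list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), aucs = aucs,
                 n_w = n_w, ratio = ratio, iterations = as.integer(iterations),
                 n_rerolled = n_rerolled, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: mean AUC %.4f (sd %.4f) over %d iterations [n_w=%d, ratio=%g]\n",
              x$mean_auc, if (is.na(x$sd_auc)) 0 else x$sd_auc,
              x$iterations, x$n_w, x$ratio))
  invisible(x)
}

.new_grid <- function(factor_name, levels, auc_mat, iterations, seed) {
  structure(list(factor = factor_name, levels = levels,
                 mean_auc = colMeans(auc_mat),
                 sd_auc = apply(auc_mat, 2, stats::sd),
                 auc = auc_mat, iterations = as.integer(iterations),
                 seed = seed),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("Experiment grid over %s (%d iterations):\n", x$factor,
              x$iterations))
  print(data.frame(level = x$levels, mean_auc = round(x$mean_auc, 4),
                   sd_auc = round(x$sd_auc, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.experiment_grid <- function(x, ...) {
  lv <- suppressWarnings(as.numeric(x$levels))
  if (anyNA(lv)) lv <- seq_along(x$levels)
  graphics::plot(lv, x$mean_auc, type = "b", xlab = x$factor,
                 ylab = "mean AUC", ylim = c(min(x$mean_auc) - 0.02, 1), ...)
  invisible(x)
}

#' Training-set size experiment (learning curve)
#'
#' Per iteration a validation set (a fixed fraction of each class) is drawn
#' once and shared across all size levels, and the training sets are nested
#' (the draw for a larger size extends the draw for a smaller one). Nesting
#' makes the per-iteration AUC differences reflect pure information gain
#' rather than draw-to-draw noise.
#'
#' @param features labeled feature data.frame
#' @param sizes W contigs per class per training set
#'   (default `c(50, 100, 150, 200)`)
#' @param ratio non-W:W training ratio (default 1)
#' @param iterations iterations per level (default 25)
#' @param seed RNG seed
#' @param validation_frac fraction of each class held out for validation
#' @param bin_width,epsilon,length_condition passed to [wbayes()]
#' @return an `experiment_grid`
#' @export
size_experiment <- function(features, sizes = c(50L, 100L, 150L, 200L),
                            ratio = 1, iterations = 25L, seed = NULL,
                            validation_frac = 0.3, bin_width = 0.005,
                            epsilon = 1e-6, length_condition = FALSE) {
  sizes <- sort(as.integer(sizes))
  w_idx <- which(features$label == "W")
  n_idx <- which(features$label == "NONW")
  v_w <- max(1L, round(validation_frac * length(w_idx)))
  v_n <- max(1L, round(validation_frac * length(n_idx)))
  max_s <- max(sizes)
  if (length(w_idx) - v_w < max_s || length(n_idx) - v_n < round(ratio * max_s))
    stop("size_experiment: insufficient labeled contigs for size ", max_s)
  auc_mat <- matrix(NA_real_, iterations, length(sizes))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      val_idx <- c(sample(w_idx, v_w), sample(n_idx, v_n))
      val <- features[val_idx, , drop = FALSE]
      pool_w <- sample(setdiff(w_idx, val_idx))
      pool_n <- sample(setdiff(n_idx, val_idx))
      for (j in seq_along(sizes)) {
        s <- sizes[j]
        tr <- features[c(pool_w[seq_len(s)],
                         pool_n[seq_len(round(ratio * s))]), , drop = FALSE]
        model <- wbayes(tr, bin_width = bin_width, epsilon = epsilon,
                        length_condition = length_condition)
        auc_mat[it, j] <- auc(predict(model, val), val$label)
      }
    }
  })
  .new_grid("training-set size (W contigs per class)", as.character(sizes),
            auc_mat, iterations, seed)
}

#' Training-set imbalance experiment
#'
#' Per iteration a validation set (a fixed fraction of each class) is drawn
#' once and shared across all ratio levels; for each non-W:W ratio a training
#' set is drawn from the remaining pool and the validation AUC recorded.
#' Infeasible levels are skipped with a warning.
#'
#' @param features labeled feature data.frame
#' @param ratios non-W:W ratios to evaluate (default `c(1, 10, 100)`)
#' @param n_w W contigs per training set
#' @param iterations iterations per level (default 25)
#' @param seed RNG seed
#' @param validation_frac fraction of each class held out for validation
#' @param bin_width,epsilon,length_condition passed to [wbayes()]
#' @return an `experiment_grid`
#' @export
imbalance_experiment <- function(features, ratios = c(1, 10, 100), n_w = 10L,
                                 iterations = 25L, seed = NULL,
                                 validation_frac = 0.3, bin_width = 0.005,
                                 epsilon = 1e-6, length_condition = FALSE) {
  stopifnot(all(ratios >= 1))
  w_idx <- which(features$label == "W")
  n_idx <- which(features$label == "NONW")
  v_w <- max(1L, round(validation_frac * length(w_idx)))
  v_n <- max(1L, round(validation_frac * length(n_idx)))
  feasible <- vapply(ratios, function(r) {
    length(w_idx) - v_w >= n_w && length(n_idx) - v_n >= round(r * n_w)
  }, TRUE)
  if (!all(feasible))
    warning("imbalance_experiment: skipped infeasible ratio level(s) ",
            paste(ratios[!feasible], collapse = ", "))
  ratios <- ratios[feasible]
  if (!length(ratios)) stop("imbalance_experiment: no feasible ratio level")
  auc_mat <- matrix(NA_real_, iterations, length(ratios))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      val_idx <- c(sample(w_idx, v_w), sample(n_idx, v_n))
      val <- features[val_idx, , drop = FALSE]
      pool <- features[-val_idx, , drop = FALSE]
      # key each training draw on the ratio value, so a repeated level is an
      # exact control (identical training data, identical AUC)
      it_seed <- sample.int(2147483646L, 1)
      for (j in seq_along(ratios)) {
        tr_idx <- with_seed(
          derive_seed(it_seed, paste0("ratio_", ratios[j])),
          .draw_training_idx(pool, n_w, ratios[j], length_condition))
        model <- wbayes(pool[tr_idx, , drop = FALSE], bin_width = bin_width,
                        epsilon = epsilon, length_condition = length_condition)
        auc_mat[it, j] <- auc(predict(model, val), val$label)
      }
    }
  })
  .new_grid("non-W:W training ratio", as.character(ratios), auc_mat,
            iterations, seed)
}

#' Contig-length transfer experiment
#'
#' Evaluates, on one fixed validation set, classifiers trained on fragments of
#' a single length (no length conditioning) for each requested length, plus
#' the length-conditioned classifier trained on the pooled per-length draws.
#'
#' @param training_by_length named list mapping fragment length to a labeled
#'   feature data.frame of training fragments at that length
#' @param validation labeled feature data.frame to score (its `length` column
#'   drives the conditioned classifier)
#' @param n_w,ratio training composition per length (defaults 200 and 1)
#' @param iterations iterations (default 25)
#' @param seed RNG seed
#' @param bin_width,epsilon passed to [wbayes()]
#' @return an `experiment_grid` with one level per training length plus
#'   `"conditioned"`
#' @export
length_transfer_experiment <- function(training_by_length, validation,
                                       n_w = 200L, ratio = 1,
                                       iterations = 25L, seed = NULL,
                                       bin_width = 0.005, epsilon = 1e-6) {
  lengths <- names(training_by_length)
  stopifnot(length(lengths) >= 1)
  levels <- c(lengths, "conditioned")
  auc_mat <- matrix(NA_real_, iterations, length(levels))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      pooled <- list()
      for (j in seq_along(lengths)) {
        pool <- training_by_length[[j]]
        tr_idx <- .draw_training_idx(pool, n_w, ratio, FALSE)
        tr <- pool[tr_idx, , drop = FALSE]
        pooled[[j]] <- tr
        model <- wbayes(tr, bin_width = bin_width, epsilon = epsilon,
                        length_condition = FALSE)
        auc_mat[it, j] <- auc(predict(model, validation), validation$label)
      }
      cond <- wbayes(do.call(rbind, pooled), bin_width = bin_width,
                     epsilon = epsilon, length_condition = TRUE)
      auc_mat[it, length(levels)] <-
        auc(predict(cond, validation), validation$label)
    }
  })
  .new_grid("training fragment length", levels, auc_mat, iterations, seed)
}
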