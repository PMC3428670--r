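#' Discretize a feature value into an equal-width bin index
#'
#' Half-open convention: value `x` falls in bin `k` with
#' `k*w <= x < (k+1)*w`. When `max_value` is supplied (e.g. 1 for coverage),
#' values exactly at the maximum are closed into the top bin.
#'
#' @param x numeric vector of non-negative feature values
#' @param bin_width bin width `w > 0`
#' @param max_value optional known maximum of the feature
#' @return integer vector of bin indices (0-based)
#' @export
discretize <- function(x, bin_width, max_value = NULL) {
  stopifnot(bin_width > 0)
  if (any(x < 0)) stop("discretize: negative feature value")
  # small tolerance so exact bin boundaries are not lost to floating point
  k <- as.integer(floor(x / bin_width + 1e-9))
  if (!is.null(max_value)) {
    top <- as.integer(ceiling(max_value / bin_width - 1e-9)) - 1L
    k[x >= max_value] <- top
  }
  k
}

.wb_features <- c("coverage", "read_depth")
.wb_feature_max <- list(coverage = 1, read_depth = NULL)

.wb_table <- function(values, bin_width, max_value) {
  bins <- discretize(values, bin_width, max_value)
  tab <- table(bins) / length(bins)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Fit a length-conditioned naive Bayes classifier for W-specific contigs
#'
#' Estimates discretized class-conditional distributions of coverage (`x1`)
#' and read depth (`x2`) from labeled training contigs, separately per 500-bp
#' contig-length bin when `length_condition = TRUE`. The two features are
#' treated as conditionally independent, each bin frequency receives an
#' `epsilon` smoothing increment, and posteriors are evaluated in log space.
#'
#' @param features training data.frame with columns `label` (`"W"`/`"NONW"`),
#'   `coverage`, `read_depth`, and `length` (bp; required when conditioning)
#' @param bin_width feature discretization width (default 0.005, the
#'   cross-validated optimum)
#' @param epsilon smoothing constant added to every bin frequency
#'   (default 1e-6)
#' @param prior_w prior probability that a contig is W-specific; defaults to
#'   the W proportion of the training set
#' @param mode `"standard"` applies Bayes' rule with both class priors;
#'   `"as_printed"` evaluates the posterior with the W prior in the numerator
#'   only and an unweighted likelihood sum in the denominator
#' @param length_condition fit one distribution table per length bin
#' @param length_bin_width width of the contig-length bins (default 500 bp)
#' @return an object of class `wbayes` with `print`, `summary`, `predict` and
#'   `plot` methods
#' @seealso [classify()], [write_wbayes()]
#' @export
wbayes <- function(features, bin_width = 0.005, epsilon = 1e-6,
                   prior_w = NULL, mode = c("standard", "as_printed"),
                   length_condition = TRUE, length_bin_width = 500L) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0, epsilon > 0)
  need <- c("label", .wb_features)
  if (length_condition) need <- c(need, "length")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("wbayes: missing columns: ", paste(miss, collapse = ", "))
  if (!all(features$label %in% c("W", "NONW")))
    stop("wbayes: labels must be 'W' or 'NONW'")
  if (nrow(features) == 0) stop("wbayes: empty training set")

  Lv <- if (length_condition)
    length_bin(features$length, length_bin_width) else rep(0L, nrow(features))
  tables <- list()
  n_train <- list()
  for (L in sort(unique(Lv))) {
    at_l <- features[Lv == L, , drop = FALSE]
    for (cls in c("W", "NONW")) {
      if (!any(at_l$label == cls))
        stop("wbayes: class ", cls, " absent at length bin ", L)
    }
    key <- as.character(L)
    tables[[key]] <- lapply(
      stats::setNames(c("W", "NONW"), c("W", "NONW")),
      function(cls) {
        rows <- at_l[at_l$label == cls, , drop = FALSE]
        lapply(stats::setNames(.wb_features, .wb_features), function(fe) {
          .wb_table(rows[[fe]], bin_width, .wb_feature_max[[fe]])
        })
      })
    n_train[[key]] <- c(W = sum(at_l$label == "W"),
                        NONW = sum(at_l$label == "NONW"))
  }
  if (is.null(prior_w)) prior_w <- mean(features$label == "W")
  if (prior_w <= 0 || prior_w >= 1)
    stop("wbayes: prior_w must lie strictly inside (0, 1)")
  structure(list(tables = tables, bin_width = bin_width, epsilon = epsilon,
                 prior_w = prior_w, mode = mode,
                 length_condition = length_condition,
                 length_bin_width = as.integer(length_bin_width),
                 n_train = n_train, call = match.call()),
            class = "wbayes")
}

.wb_log_lik <- function(model, L_key, cls, feature, values) {
  tab <- model$tables[[L_key]][[cls]][[feature]]
  bins <- as.character(discretize(values, model$bin_width,
                                  .wb_feature_max[[feature]]))
  freq <- tab[bins]
  freq[is.na(freq)] <- 0
  log(freq + model$epsilon)
}

#' Posterior probabilities from a fitted `wbayes` model
#'
#' @param object a [wbayes] model
#' @param newdata data.frame with `coverage`, `read_depth` (and `length` when
#'   the model conditions on length)
#' @param type `"posterior"` returns P(W | X, L); `"class"` thresholds it at
#'   `tau` (strictly greater)
#' @param tau posterior threshold for `type = "class"` (default 0.95)
#' @param mode optionally override the model's posterior mode
#' @param ... unused
#' @return numeric vector of posteriors, or character vector of calls
#' @export
predict.wbayes <- function(object, newdata, type = c("posterior", "class"),
                           tau = 0.95, mode = NULL, ...) {
  type <- match.arg(type)
  mode <- mode %||% object$mode
  if (nrow(newdata) == 0) return(numeric(0))
  Lv <- if (object$length_condition) {
    if (!"length" %in% names(newdata))
      stop("predict.wbayes: 'length' column required for a length-conditioned model")
    length_bin(newdata$length, object$length_bin_width)
  } else rep(0L, nrow(newdata))
  keys <- as.character(Lv)
  missing_l <- setdiff(unique(keys), names(object$tables))
  if (length(missing_l))
    stop("predict.wbayes: no training distribution for length bin(s) ",
         paste(missing_l, collapse = ", "))
  post <- numeric(nrow(newdata))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    llw <- .wb_log_lik(object, key, "W", "coverage", newdata$coverage[idx]) +
      .wb_log_lik(object, key, "W", "read_depth", newdata$read_depth[idx])
    lln <- .wb_log_lik(object, key, "NONW", "coverage", newdata$coverage[idx]) +
      .wb_log_lik(object, key, "NONW", "read_depth", newdata$read_depth[idx])
    pri <- object$prior_w
    if (mode == "standard") {
      a <- log(pri) + llw
      b <- log(1 - pri) + lln
      post[idx] <- exp(a - logsumexp2(a, b))
    } else {
      post[idx] <- exp(log(pri) + llw - logsumexp2(llw, lln))
    }
  }
  if (type == "class") return(ifelse(post > tau, "W", "NONW"))
  post
}

#' @export
print.wbayes <- function(x, ...) {
  cat("Length-conditioned naive Bayes classifier for W-specific contigs\n")
  cat(sprintf("  bin width %.4g, epsilon %.2g, prior P(W) = %.4g, mode '%s'\n",
              x$bin_width, x$epsilon, x$prior_w, x$mode))
  if (x$length_condition) {
    cat(sprintf("  %d length bin(s): %s\n", length(x$tables),
                paste(names(x$tables), collapse = ", ")))
  } else {
    cat("  not conditioned on contig length\n")
  }
  invisible(x)
}

#' @export
summary.wbayes <- function(object, ...) {
  tr <- do.call(rbind, lapply(names(object$n_train), function(k) {
    data.frame(L = as.integer(k), n_w = object$n_train[[k]][["W"]],
               n_nonw = object$n_train[[k]][["NONW"]])
  }))
  structure(list(model = object, training = tr), class = "summary.wbayes")
}

#' @export
print.summary.wbayes <- function(x, ...) {
  print(x$model)
  cat("Training members per length bin:\n")
  print(x$training, row.names = FALSE)
  invisible(x)
}

#' @export
plot.wbayes <- function(x, L = NULL, feature = c("coverage", "read_depth"),
                        ...) {
  feature <- match.arg(feature)
  L <- L %||% as.integer(names(x$tables)[1])
  key <- as.character(L)
  if (!key %in% names(x$tables)) stop("plot.wbayes: no length bin ", L)
  tw <- x$tables[[key]][["W"]][[feature]]
  tn <- x$tables[[key]][["NONW"]][[feature]]
  bins <- sort(unique(as.integer(c(names(tw), names(tn)))))
  m <- rbind(W = tw[as.character(bins)], NONW = tn[as.character(bins)])
  m[is.na(m)] <- 0
  graphics::barplot(m, beside = TRUE, names.arg = bins * x$bin_width,
                    legend.text = c("W", "non-W"),
                    xlab = feature, ylab = "relative frequency",
                    main = sprintf("class-conditional %s, L = %s", feature, key),
                    ...)
  invisible(x)
}

#' Call W-specific contigs with a fitted model
#'
#' Scores every eligible contig and predicts W when the posterior strictly
#' exceeds `tau`. Ineligible contigs (no possible read placement) are excluded
#' and reported via a message and the `excluded` attribute.
#'
#' @param features feature data.frame (from [contig_features()]) for the
#'   contigs to classify
#' @param model a [wbayes] model
#' @param tau posterior threshold (default 0.95)
#' @return data.frame of calls (`contig_id`, `L`, `coverage`, `read_depth`,
#'   `posterior_w`, `call`), sorted by descending posterior
#' @export
classify <- function(features, model, tau = 0.95) {
  elig <- if ("eligible" %in% names(features)) features$eligible else
    rep(TRUE, nrow(features))
  excluded <- features$contig_id[!elig]
  if (length(excluded))
    message("classify: excluded ", length(excluded),
            " ineligible contig(s) with no possible read placement")
  feats <- features[elig, , drop = FALSE]
  post <- predict(model, feats, type = "posterior")
  out <- data.frame(
    contig_id = feats$contig_id,
    L = if (model$length_condition)
      length_bin(feats$length, model$length_bin_width) else NA_integer_,
    coverage = feats$coverage, read_depth = feats$read_depth,
    posterior_w = post,
    call = ifelse(post > tau, "W", "NONW"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$posterior_w, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Serialize a `wbayes` model to versioned JSON
#' @param model a [wbayes] model
#' @param path output file
#' @export
write_wbayes <- function(model, path) {
  doc <- list(
    format = "wbayes-model", version = 1L,
    bin_width = model$bin_width, epsilon = model$epsilon,
    prior_w = model$prior_w, mode = model$mode,
    length_condition = model$length_condition,
    length_bin_width = model$length_bin_width,
    n_train = lapply(model$n_train, as.list),
    tables = lapply(model$tables, function(by_cls)
      lapply(by_cls, function(by_fe) lapply(by_fe, as.list))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a `wbayes` model from JSON
#' @param path file written by [write_wbayes()]
#' @return a [wbayes] model
#' @export
read_wbayes <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "wbayes-model"))
    stop("read_wbayes: not a wbayes model document")
  tables <- lapply(doc$tables, function(by_cls)
    lapply(by_cls, function(by_fe)
      lapply(by_fe, function(tab)
        stats::setNames(as.numeric(unlist(tab)), names(tab)))))
  n_train <- lapply(doc$n_train, function(v)
    stats::setNames(as.integer(unlist(v)), names(v)))
  structure(list(tables = tables, bin_width = doc$bin_width,
                 epsilon = doc$epsilon, prior_w = doc$prior_w,
                 mode = doc$mode, length_condition = doc$length_condition,
                 length_bin_width = as.integer(doc$length_bin_width),
                 n_train = n_train, call = NULL),
            class = "wbayes")
}
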