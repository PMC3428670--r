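#' Assemble a resolved run configuration
#'
#' All pipeline tunables with their defaults: 36-bp reads, up to 2 mismatches,
#' 50-bp duplicate and segment thresholds, 0.005 feature bins, 1e-6 smoothing,
#' a 0.95 posterior call threshold, 1000 bootstrap replicates, and one master
#' seed fanned out deterministically per stage.
#'
#' @param ... overrides of the defaults listed above
#' @return object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(read_length = 36L, max_mismatches = 2L, min_dup_len = 50L,
              min_seg_len = 50L, max_mono_frac = 0.8, bin_width = 0.005,
              epsilon = 1e-6, prior_w = NULL, mode = "standard",
              length_condition = TRUE, length_bin_width = 500L,
              tau = 0.95, B = 1000L, iterations = 100L,
              honor_softmask = TRUE, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("run_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$read_length >= 1, cfg$max_mismatches >= 0,
            cfg$min_dup_len >= 1, cfg$min_seg_len >= 1, cfg$bin_width > 0,
            cfg$epsilon > 0, cfg$tau >= 0, cfg$tau <= 1, cfg$B >= 1)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys override [run_config()] defaults
#' @return a `run_config`
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full classification pipeline
#'
#' Reference preparation (mask, duplicate filter, short-segment filter), read
#' QC and unique mapping, per-contig features, bootstrap separation
#' statistics on the labeled contigs, classifier training on the labeled
#' (W / non-W) contigs and classification of the unlabeled
#' (UNMAPPED / UNKNOWN) contigs. Writes TSV/JSON artifacts plus a manifest
#' carrying the config hash and the filtering funnel, and logs counts at each
#' stage.
#'
#' @param config a [run_config]
#' @param reference list of [masked_contig] objects, or a FASTA path
#' @param reads reads data.frame, or a FASTQ/FASTA path
#' @param mask_bed optional mask intervals data.frame, or a BED path
#' @param labels optional data.frame (`contig_id`, `label`) assigning
#'   W / NONW / UNMAPPED labels (overrides labels carried by `reference`)
#' @param sam optional SAM path used instead of the built-in mapper
#' @param out_dir directory for output artifacts (created if missing)
#' @return invisibly, a list with `features`, `calls`, `model`, `stats`,
#'   `funnel`, `manifest`, `paths`
#' @export
run_pipeline <- function(config, reference, reads, mask_bed = NULL,
                         labels = NULL, sam = NULL, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("run_pipeline: cannot create directory ", out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  contigs <- stage("prep", {
    if (is.character(reference))
      reference <- read_reference(reference, labels = labels,
                                  honor_softmask = config$honor_softmask)
    if (!is.null(labels)) {
      lab_map <- stats::setNames(labels$label, labels$contig_id)
      reference <- lapply(reference, function(ct) {
        if (ct$id %in% names(lab_map)) ct$label <- unname(lab_map[[ct$id]])
        ct
      })
    }
    if (is.character(mask_bed)) mask_bed <- read_mask_bed(mask_bed)
    reference
  })
  message("prep: ", length(contigs), " contigs in")
  prep <- stage("prep", prep_reference(contigs, intervals = mask_bed,
                                       min_dup_len = config$min_dup_len,
                                       min_seg_len = config$min_seg_len))
  contigs <- prep$contigs
  funnel <- prep$funnel
  message("prep: ", funnel$unmasked_bp[nrow(funnel)], " unmasked bp after filtering")

  reads <- stage("reads", {
    if (is.character(reads)) reads <- read_short_reads(reads)
    reads
  })
  n_in <- nrow(reads)
  reads <- stage("reads", dedupe_reads(reads))
  n_dedup <- nrow(reads)
  reads <- stage("reads", filter_low_complexity(reads, config$max_mono_frac))
  n_qc <- nrow(reads)
  message("reads: ", n_in, " in, ", n_dedup, " after dedupe, ", n_qc,
          " after low-complexity filter")
  funnel <- rbind(funnel,
                  data.frame(step = c("reads_in", "reads_dedupe", "reads_qc"),
                             unmasked_bp = c(n_in, n_dedup, n_qc)))

  placements <- stage("map", {
    if (!is.null(sam)) ingest_sam(sam, contigs)
    else map_reads_unique(reads, contigs, config$max_mismatches)
  })
  ms <- attr(placements, "summary")
  message("map: ", nrow(placements), " unique placements (",
          paste(names(ms), unlist(ms), sep = "=", collapse = ", "), ")")
  funnel <- rbind(funnel, data.frame(step = "reads_placed",
                                     unmasked_bp = nrow(placements)))

  features <- stage("features",
                    contig_features(contigs, placements, config$read_length))

  seed_stats <- derive_seed(config$seed, "stats")
  stats_out <- stage("stats", {
    lab <- features$label
    out <- list()
    if (any(lab == "W") && any(lab == "NONW")) {
      w <- features[lab == "W" & features$eligible, , drop = FALSE]
      nw <- features[lab == "NONW" & features$eligible, , drop = FALSE]
      for (fe in c("coverage", "read_depth")) {
        out[[paste0("w_", fe)]] <-
          bootstrap_ci(w[[fe]], B = config$B,
                       seed = derive_seed(seed_stats, paste0("w_", fe)),
                       statistic_name = paste("mean W", fe))
        out[[paste0("nonw_", fe)]] <-
          bootstrap_ci(nw[[fe]], B = config$B,
                       seed = derive_seed(seed_stats, paste0("nonw_", fe)),
                       statistic_name = paste("mean non-W", fe))
        out[[paste0("separation_", fe)]] <-
          quantile_separation_test(w[[fe]], nw[[fe]], B = config$B,
                                   seed = derive_seed(seed_stats,
                                                      paste0("sep_", fe)))
      }
    }
    out
  })

  model <- stage("train", {
    train <- features[features$label %in% c("W", "NONW") & features$eligible, ,
                      drop = FALSE]
    if (!any(train$label == "W") || !any(train$label == "NONW")) NULL
    else {
      if (config$length_condition) {
        # only length bins with both classes can contribute a distribution
        lb <- length_bin(train$length, config$length_bin_width)
        ok <- intersect(unique(lb[train$label == "W"]),
                        unique(lb[train$label == "NONW"]))
        dropped <- sum(!(lb %in% ok))
        if (dropped > 0)
          message("train: dropped ", dropped,
                  " training contig(s) in length bins lacking a class")
        train <- train[lb %in% ok, , drop = FALSE]
      }
      wbayes(train, bin_width = config$bin_width, epsilon = config$epsilon,
             prior_w = config$prior_w, mode = config$mode,
             length_condition = config$length_condition,
             length_bin_width = config$length_bin_width)
    }
  })

  calls <- stage("classify", {
    if (is.null(model)) NULL
    else {
      targets <- features[features$label %in% c("UNMAPPED", "UNKNOWN"), ,
                          drop = FALSE]
      if (nrow(targets) == 0)
        targets <- features[features$label %in% c("W", "NONW"), , drop = FALSE]
      if (config$length_condition) {
        tb <- length_bin(targets$length, config$length_bin_width)
        covered <- tb %in% as.integer(names(model$tables))
        if (any(!covered))
          message("classify: ", sum(!covered), " contig(s) fall in length ",
                  "bins without a trained distribution and are not scored")
        targets <- targets[covered, , drop = FALSE]
      }
      classify(targets[targets$eligible, , drop = FALSE], model,
               tau = config$tau)
    }
  })
  if (!is.null(calls))
    message("classify: ", sum(calls$call == "W"), " W calls of ",
            nrow(calls), " classified contigs at tau=", config$tau)

  paths <- stage("write", {
    p <- c(features = file.path(out_dir, "features.tsv"),
           config = file.path(out_dir, "config.json"),
           manifest = file.path(out_dir, "manifest.json"))
    write_features(features, p["features"])
    jsonlite::write_json(unclass(config), p["config"], auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    if (!is.null(calls)) {
      p <- c(p, calls = file.path(out_dir, "calls.tsv"))
      utils::write.table(calls, p["calls"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    if (!is.null(model)) {
      p <- c(p, model = file.path(out_dir, "model.json"))
      write_wbayes(model, p["model"])
    }
    if (length(stats_out)) {
      p <- c(p, stats = file.path(out_dir, "stats.json"))
      rep <- lapply(stats_out, function(s) {
        if (inherits(s, "bootstrap_ci"))
          list(statistic = s$statistic, estimate = s$estimate,
               ci_low = s$ci_low, ci_high = s$ci_high, B = s$B)
        else list(statistic = "quantile separation", p = s$p, B = s$B,
                  mean_gap = mean(s$diffs))
      })
      jsonlite::write_json(rep, p["stats"], auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    p
  })

  manifest <- stage("write", {
    m <- list(format = "wlinker-run", version = 1L,
              config_hash = .config_hash(config),
              funnel = funnel,
              map_summary = ms,
              files = lapply(as.list(paths[names(paths) != "manifest"]),
                             function(f) list(name = basename(f),
                                              md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(m, paths["manifest"], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    m
  })

  invisible(list(features = features, calls = calls, model = model,
                 stats = stats_out, funnel = funnel, manifest = manifest,
                 paths = paths))
}
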