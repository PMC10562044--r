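#' Configuration of a full simulate-train-denoise-evaluate run
#'
#' Bundles every stage's parameters with their desk-scale defaults: a
#' reduced training corpus and network trainable on one CPU core, the
#' full-size Derenzo (both target-to-background ratios) and torso (three
#' time points) test scenes, and the evaluation settings.
#'
#' @param corpus_spec [training_corpus_spec()] for the training scenes.
#' @param scanner_train scanner used for the training scenes.
#' @param scanner_test scanner used for the test scenes.
#' @param fractions count fractions simulated and evaluated.
#' @param network [network_spec()].
#' @param train [train_config()].
#' @param tbr_values Derenzo target-to-background ratios to test.
#' @param times_h torso imaging time points (h).
#' @param alpha ROI significance level.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory for reports (`NULL` = no files).
#' @param model optional pre-trained `densenet_denoiser` (skips training).
#' @return object of class `run_config`.
#' @export
run_config <- function(corpus_spec = training_corpus_spec(n_slices = 15L,
                                                          n_duplicates = 30L,
                                                          matrix = 96L),
                       scanner_train = scanner_model(matrix = c(96L, 96L)),
                       scanner_test = scanner_model(),
                       fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       network = network_spec(),
                       train = train_config(),
                       tbr_values = c(5, 20), times_h = c(24, 96, 168),
                       alpha = 0.01, seed = 1L, out_dir = NULL,
                       model = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  structure(list(corpus_spec = corpus_spec, scanner_train = scanner_train,
                 scanner_test = scanner_test, fractions = fractions,
                 network = network, train = train, tbr_values = tbr_values,
                 times_h = times_h, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir, model = model),
            class = "run_config")
}

#' Build a training patch dataset from simulated corpus scans
#'
#' Simulates every corpus phantom (anterior view), thins to each count
#' fraction, and extracts paired noisy/full-count sub-images.
#'
#' @param corpus list of phantoms from [make_training_corpus()].
#' @param scanner a [scanner_model()].
#' @param fractions count fractions paired with the full-count label.
#' @param seed integer seed.
#' @param size,stride passed to [extract_patches()].
#' @param balance_fractions weight sampling by `1/sqrt(1 - f)` so each
#'   count fraction contributes comparably to the training loss (the
#'   absolute residual scale of a pair grows as the retained fraction
#'   shrinks, so unweighted sampling lets the lowest fractions dominate
#'   the gradient).
#' @return a `patch_dataset`.
#' @export
corpus_patches <- function(corpus, scanner, fractions, seed = 1L,
                           size = 25L, stride = 25L,
                           balance_fractions = FALSE) {
  sets <- list()
  set.seed(seed)
  for (i in seq_along(corpus)) {
    scan <- simulate_scan(corpus[[i]], scanner, fractions,
                          seed = seed + 13L * i, views = "anterior")
    full <- scan$anterior$full
    set.seed(seed + 7919L * i)
    for (f in fractions) {
      ds <- extract_patches(scan$anterior[[sprintf("%g", f)]], full,
                            size = size, stride = stride)
      if (ncol(ds$input)) {
        if (balance_fractions)
          ds$weights <- rep(1 / sqrt(1 - f), ncol(ds$input))
        sets[[length(sets) + 1L]] <- ds
      }
    }
  }
  bind_patches(sets)
}

#' Run the full experiment
#'
#' Executes the pipeline: training-corpus simulation, denoiser training
#' (unless a model is supplied), Derenzo and torso test-scene simulation,
#' denoising of every reduced-count anterior image, whole-image metric
#' reports, ROI significance tables, conjugate-view organ activities,
#' and a run manifest.  With `out_dir` set, reports are written as CSV
#' and the manifest as JSON with per-file checksums.
#'
#' @param config a [run_config()].
#' @return list with `model`, `metrics` (data frame), `significance`
#'   (data frame), `activities` (data frame), `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  fractions <- sort(config$fractions[config$fractions < 1])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  model <- config$model
  if (is.null(model)) {
    corpus <- stage("phantoms", make_training_corpus(config$corpus_spec,
                                                     seed = config$seed))
    patches <- stage("simulate", corpus_patches(corpus, config$scanner_train,
                                                fractions, seed = config$seed))
    model <- stage("train", denoiser(patches, config$network, config$train))
  }
  scenes <- list()
  for (tbr in config$tbr_values) {
    dz <- stage("phantoms", make_derenzo(rod_spec(tbr = tbr)))
    scenes[[sprintf("derenzo_tbr%g", tbr)]] <-
      list(phantom = dz$phantom, labels = dz$labels, kind = "derenzo")
  }
  for (t_h in config$times_h) {
    to <- stage("phantoms", make_anthropomorphic(time_h = t_h))
    scenes[[sprintf("torso_%gh", t_h)]] <-
      list(phantom = to$phantom, labels = to$labels, kind = "torso")
  }
  metrics <- list(); signif <- list(); activities <- list()
  for (sn in names(scenes)) {
    sc <- scenes[[sn]]
    scan <- stage("simulate",
                  simulate_scan(sc$phantom, config$scanner_test, fractions,
                                seed = config$seed + 101L))
    full <- scan$anterior$full
    tests <- list(full = full)
    for (f in fractions) {
      key <- sprintf("%g", f)
      tests[[paste0("input_", key)]] <- scan$anterior[[key]]
      tests[[paste0("output_", key)]] <-
        stage("denoise", predict(model, scan$anterior[[key]]))
    }
    rois <- stage("evaluate", if (sc$kind == "derenzo") {
      rod_rois(full, project_labels(sc$labels, sc$phantom,
                                    config$scanner_test, "anterior"))
    } else {
      organ_rois(sc$labels, sc$phantom, config$scanner_test, "anterior")
    })
    mr <- stage("evaluate", metric_report(full, tests))
    mr$scene <- sn
    metrics[[sn]] <- mr
    st <- stage("evaluate", significance_table(full, tests, rois,
                                               alpha = config$alpha))
    st$scene <- sn
    signif[[sn]] <- st
    if (sc$kind == "torso")
      activities[[sn]] <- stage("dosimetry",
        conjugate_view_report(sc, scan, model, config, fractions, sn))
  }
  metrics <- do.call(rbind, metrics)
  signif <- do.call(rbind, signif)
  activities <- if (length(activities)) do.call(rbind, activities)
  manifest <- list(seed = config$seed, fractions = fractions,
                   scenes = names(scenes),
                   network = unclass(config$network),
                   train = unclass(config$train),
                   alpha = config$alpha,
                   r_version = as.character(getRversion()))
  result <- list(model = model, metrics = metrics, significance = signif,
                 activities = activities, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(metrics = file.path(config$out_dir, "metrics.csv"),
               significance = file.path(config$out_dir, "significance.csv"))
    utils::write.csv(metrics, paths["metrics"], row.names = FALSE)
    utils::write.csv(signif, paths["significance"], row.names = FALSE)
    if (!is.null(activities)) {
      paths["activities"] <- file.path(config$out_dir, "activities.csv")
      utils::write.csv(activities, paths["activities"], row.names = FALSE)
    }
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

# conjugate-view organ activities for full-count vs denoised torso scans
conjugate_view_report <- function(sc, scan, model, config, fractions, sn) {
  scanner <- config$scanner_test
  rois_a <- organ_rois(sc$labels, sc$phantom, scanner, "anterior")
  rois_p <- organ_rois(sc$labels, sc$phantom, scanner, "posterior")
  th_a <- project_labels(sc$labels, sc$phantom, scanner, "anterior")
  mu_w <- max(sc$phantom$attenuation)
  total_thick <- dim(sc$phantom$activity)[2] * sc$phantom$voxel_size[2]
  rows <- list()
  imgs <- list(full = list(a = scan$anterior$full, p = scan$posterior$full))
  for (f in fractions) {
    key <- sprintf("%g", f)
    imgs[[paste0("output_", key)]] <-
      list(a = predict(model, scan$anterior[[key]]),
           p = predict(model, scan$posterior[[key]]))
  }
  for (nm in names(rois_a)) {
    ts <- mean(th_a[[nm]][th_a[[nm]] > 0])   # mean source thickness, mm
    f_corr <- self_attenuation_factor(mu_w, ts)
    t_fac <- exp(-mu_w * total_thick)
    for (id in names(imgs)) {
      ia <- sum(as_count_matrix(imgs[[id]]$a)[rois_a[[nm]]$mask]) /
        scanner$scan_time
      ip <- sum(as_count_matrix(imgs[[id]]$p)[rois_p[[nm]]$mask]) /
        scanner$scan_time
      scale <- if (id == "full") 1 else 1  # denoised outputs are full-scale
      a_mbq <- conjugate_view_activity(conjugate_view_measurement(
        ia * scale, ip * scale, t_fac, scanner$sensitivity, f_corr))
      rows[[length(rows) + 1L]] <- data.frame(
        scene = sn, organ = nm, image_id = id, activity_mbq = a_mbq)
    }
  }
  do.call(rbind, rows)
}

#' Format significance results as publication-style tables
#'
#' Pivots the long significance table of [run_experiment()] into one wide
#' CSV per scene (rows: full-count reference, reduced-count inputs,
#' denoised outputs; columns: mean/SD/P per ROI) plus a percent-difference
#' summary of denoised ROI means against the full-count reference.
#'
#' @param run result of [run_experiment()], or a directory containing its
#'   `significance.csv`.
#' @param out_dir optional directory for the CSVs.
#' @return named list of wide data frames plus `$percent_difference`.
#' @export
make_paper_tables <- function(run, out_dir = NULL) {
  sig <- if (is.character(run)) {
    utils::read.csv(file.path(run, "significance.csv"))
  } else run$significance
  if (is.null(sig)) stop("no significance results found")
  out <- list()
  pd <- list()
  for (sn in unique(sig$scene)) {
    s <- sig[sig$scene == sn, ]
    rois <- unique(s$roi)
    ids <- unique(s$image_id)
    wide <- data.frame(image = ids)
    for (rn in rois) {
      sub <- s[s$roi == rn, ][match(ids, s$image_id[s$roi == rn]), ]
      wide[[paste0(rn, "_mean")]] <- round(sub$mean, 2)
      wide[[paste0(rn, "_sd")]] <- round(sub$sd, 2)
      wide[[paste0(rn, "_p")]] <- signif(sub$p, 2)
    }
    out[[sn]] <- wide
    full_rows <- s[s$image_id == "full", ]
    outputs <- s[grepl("^output_", s$image_id), ]
    if (nrow(full_rows) && nrow(outputs))
      pd[[sn]] <- do.call(rbind, lapply(split(outputs, outputs$image_id),
        function(o) data.frame(
          scene = sn, image_id = o$image_id, roi = o$roi,
          percent_diff = percent_difference(
            full_rows$mean[match(o$roi, full_rows$roi)], o$mean))))
  }
  out$percent_difference <- do.call(rbind, pd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
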