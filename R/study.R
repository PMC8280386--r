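#' Ablation study over training-data configurations and system modes
#'
#' Runs the full desk-scale experiment: generates a seeded phantom dataset,
#' trains the two classifiers and the refinement U-net once, trains one
#' binarizer U-net per requested training-data configuration, and evaluates
#' every (configuration x system mode) cell on the held-out test slices —
#' the ablation grid of the three-stage system.  A separate set of
#' high-severity slices measures refinement efficacy (contour refinement
#' enabled vs disabled).
#'
#' @param seed master seed for data generation and training.
#' @param n total number of phantom slices (split `n_test` off for
#'   evaluation, remainder for training).
#' @param n_test number of held-out test slices.
#' @param image_size slice side in pixels.
#' @param config_ids training-data configurations for the binarizer U-net.
#' @param modes system modes to evaluate.
#' @param lung_fraction,severity_range phantom dataset composition.
#' @param iters per-network iteration caps (desk-scale budgets).
#' @param unet_batch minibatch size for the U-nets.
#' @param n_severity slices in the dedicated severity-0.3 refinement set.
#' @param refine_severity pathology severity of that set.
#' @param verbose print progress.
#' @return list with `evaluation` (data frame: one row per configuration x
#'   mode), `refinement` (data frame comparing refinement on/off),
#'   `models`, `logs` (per-network training loss curves) and `manifest`.
#' @export
ablation_study <- function(seed = 1L, n = 600, n_test = 100, image_size = 128,
                           config_ids = c(2, 5),
                           modes = c("three_stage", "without_cnns",
                                     "without_enhancement"),
                           lung_fraction = 0.8, severity_range = c(0, 0.3),
                           iters = c(cnn1 = 120, unet1 = 80, unet2 = 300,
                                     cnn2 = 120),
                           unet_batch = 4, n_severity = 20,
                           refine_severity = 0.3, verbose = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(...)
  say("generating phantom dataset (", n, " slices) ...")
  ds <- make_dataset(n, lung_fraction = lung_fraction,
                     severity_range = severity_range, image_size = image_size,
                     split = c(train = 1 - n_test / n, val = 0, test = n_test / n),
                     seed = seed)
  tr <- ds$slices[ds$manifest$split == "train"]
  te <- ds$slices[ds$manifest$split == "test"]

  tc <- train_config(seed = seed + 100L)
  cfg_for <- function(off, what, batch = NULL) {
    cfg <- tc
    cfg$seed <- tc$seed + off
    cfg$max_iterations <- unname(iters[what])
    if (!is.null(batch)) cfg$minibatch_size <- as.integer(batch)
    cfg
  }

  say("training shared networks (slice gate, component filter, refiner) ...")
  cnn1 <- train_classifier(build_cnn1_set(tr), classifier_spec(64),
                           cfg_for(11L, "cnn1"))
  cnn2 <- train_classifier(build_cnn2_set(tr, seed = seed), classifier_spec(64),
                           cfg_for(44L, "cnn2"))
  unet2 <- train_unet(build_unet2_set(tr), unet_spec(2, image_size),
                      cfg_for(33L, "unet2", unet_batch))

  unet1s <- list()
  for (cid in config_ids) {
    say("training binarizer U-net, configuration ", cid, " ...")
    set1 <- build_unet1_set(tr, cid, seed = seed)
    unet1s[[as.character(cid)]] <-
      train_unet(set1, unet_spec(set1$label_arity, image_size),
                 cfg_for(22L + cid, "unet1", unet_batch))
  }

  cfgs <- list()
  for (cid in config_ids)
    for (mode in modes)
      cfgs[[paste0("config", cid, ".", mode)]] <- pipeline_config(
        models = list(cnn1 = cnn1, unet1 = unet1s[[as.character(cid)]],
                      unet2 = unet2, cnn2 = cnn2),
        mode = mode)
  say("evaluating ", length(cfgs), " pipeline configurations on ",
      length(te), " test slices ...")
  evaluation <- evaluate_pipeline(te, cfgs)

  say("measuring refinement efficacy on severity-", refine_severity,
      " slices ...")
  sev <- lapply(seq_len(n_severity), function(i) make_thorax_slice(
    phantom_params(image_size, pathology_severity = refine_severity,
                   noise_sigma = 0.01, seed = seed * 1000L + i)))
  base <- list(cnn1 = cnn1, unet1 = unet1s[[1]], unet2 = unet2, cnn2 = cnn2)
  refinement <- evaluate_pipeline(sev, list(
    refined = pipeline_config(base, "three_stage"),
    unrefined = pipeline_config(base, "three_stage", refine = FALSE)))

  logs <- c(list(cnn1 = cnn1$log, cnn2 = cnn2$log, unet2 = unet2$log),
            stats::setNames(lapply(unet1s, function(m) m$log),
                            paste0("unet1_config", names(unet1s))))
  list(evaluation = evaluation, refinement = refinement,
       models = c(list(cnn1 = cnn1, cnn2 = cnn2, unet2 = unet2),
                  stats::setNames(unet1s, paste0("unet1_config", names(unet1s)))),
       logs = logs, manifest = ds$manifest)
}
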