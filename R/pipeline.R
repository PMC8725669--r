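# End-to-end orchestration: generate or load data, refine segmentations
# through the quantization path, extract and fuse saliency + backend
# features, cross-validate a classifier, and report. Every stage is
# seeded; re-running with the same config reproduces all outputs.

pipeline_defaults <- function() {
  list(
    data = list(n_benign = 200L, n_malignant = 100L, difficulty = 0.3,
                seed = 0L, shape = c(128L, 128L), dir = NULL),
    refine = list(n_levels = 3L, smooth_sigma = 1.5, min_area = 25L,
                  trigger_area_frac = 0.001, trigger_solidity = 0.5),
    ica = list(patch_size = 11L, stride = 4L, k = 32L, drop_top = 1L,
               max_patches = 50000L, seed = 0L),
    stub = list(dim = 32L, seed = 0L),
    classify = list(kind = "svm_cubic", k = 5L, seed = 0L, positive = "B"),
    out = NULL)
}

merge_config <- function(user, defaults) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    sq_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      merge_config(user[[nm]], defaults[[nm]]) else user[[nm]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds a validated configuration from a named list of overrides or a
#' YAML file. Unknown keys are rejected.
#'
#' @param cfg named list of overrides, or a path to a YAML file
#' @return full configuration list
#' @export
pipeline_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  merge_config(cfg, pipeline_defaults())
}

load_samples <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lab)), function(i) {
    id <- lab$id[i]
    list(image = read_image(file.path(dir, "images", paste0(id, ".png"))),
         mask = read_mask(file.path(dir, "masks", paste0(id, ".png"))),
         label = lab$label[i])
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthetic data generation (or loading from
#' \code{cfg$data$dir}); standalone quantization segmentation of every
#' image (empty coarse mask, so the refinement trigger always fires);
#' sparse-filter model training on all images; per-lesion saliency
#' features f1 over the refined masks; deterministic backend stub
#' features f2; serial fusion; stratified k-fold cross-validation with a
#' pooled confusion matrix. When \code{cfg$out} is set, per-stage
#' artifacts (features CSV, metrics JSON, manifest with file checksums)
#' are written there.
#'
#' @param cfg a \code{\link{pipeline_config}} (or overrides / YAML path
#'   accepted by it)
#' @return report list: \code{mean_iou} (refined vs ground-truth masks),
#'   \code{cm}, \code{metrics}, \code{n}, \code{features}, \code{labels},
#'   \code{config}
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- pipeline_config(cfg)
  samples <- if (!is.null(cfg$data$dir)) load_samples(cfg$data$dir)
             else make_dataset(cfg$data$n_benign, cfg$data$n_malignant,
                               seed = cfg$data$seed,
                               difficulty = cfg$data$difficulty,
                               shape = cfg$data$shape)
  n <- length(samples)
  if (n == 0L) sq_stop("no samples to process")
  labels <- factor(vapply(samples, `[[`, "", "label"), levels = c("B", "M"))
  images <- lapply(samples, `[[`, "image")

  # stage: segmentation via the quantization path
  crit <- region_criteria(min_area = cfg$refine$min_area)
  trig <- trigger_rule(cfg$refine$trigger_area_frac,
                       cfg$refine$trigger_solidity)
  empty <- matrix(0, cfg$data$shape[1L], cfg$data$shape[2L])
  refined <- lapply(images, function(img)
    refine_segmentation(img, matrix(0, nrow(img), ncol(img)),
                        n = cfg$refine$n_levels, crit = crit,
                        trigger = trig,
                        smooth_sigma = cfg$refine$smooth_sigma))
  miou <- mean_iou(refined, lapply(samples, `[[`, "mask"))

  # stage: saliency model + features
  pcfg <- patch_config(cfg$ica$patch_size, cfg$ica$stride,
                       cfg$ica$max_patches, cfg$ica$seed)
  patches <- extract_patches(images, pcfg)
  model <- fit_ica_model(patches, k = cfg$ica$k,
                         drop_top = cfg$ica$drop_top, seed = cfg$ica$seed)
  feat_mask <- lapply(refined, function(m) {
    if (sum(m) == 0) matrix(1, nrow(m), ncol(m)) else m
  })
  f1 <- t(mapply(function(img, m) ica_feature_vector(img, m, model),
                 images, feat_mask))
  f2 <- t(mapply(function(img, m)
    deep_feature_stub(img, m, dim = cfg$stub$dim, seed = cfg$stub$seed),
    images, feat_mask))

  # stage: fusion + cross-validation
  fused <- serial_fuse(f1, f2)
  spec <- classifier_spec(cfg$classify$kind, seed = cfg$classify$seed)
  cv <- cross_validate(fused, labels, spec, k = cfg$classify$k,
                       seed = cfg$classify$seed,
                       positive = cfg$classify$positive)

  report <- list(mean_iou = miou, cm = cv$cm, metrics = cv$metrics, n = n,
                 features = fused, labels = labels, config = cfg)
  if (!is.null(cfg$out)) write_pipeline_artifacts(report, samples, cfg$out)
  report
}

write_pipeline_artifacts <- function(report, samples, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  feats <- data.frame(id = sprintf("sample_%04d", seq_len(report$n)),
                      label = as.character(report$labels),
                      unclass(report$features))
  utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean_iou = report$mean_iou,
         confusion = report$cm[c("bb", "bm", "mb", "mm")],
         metrics = report$metrics[c("accuracy", "precision", "recall",
                                    "f1", "kappa")]),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    config = report$config,
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
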