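# End-to-end reproducible runs: cmd_simulate writes a synthetic cohort to
# disk (PNG + GeoJSON + CSV); cmd_run_all executes the whole pipeline
# (simulate -> tile -> train classifier -> train segmenters -> score ->
# evaluate) on a synthetic cohort and writes prediction tables, score tables
# and an evaluation report. A thin Rscript front-end lives in
# inst/scripts/zebra.R.

zebra_stop <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Read and validate a run configuration
#'
#' Configurations are JSON with a required top-level `seed` and optional
#' blocks `cohort` (fields of [cohort_spec()]), `tiling`
#' ([tiling_config()]), `classify` ([train_config()]), `segment`
#' ([seg_train_config()]), plus `cutoff` (case ZS cutoff in percent,
#' default 0.19), `aggregation_rule` and `aggregation_unit`
#' (`"case"` or `"slide"`; the screening unit is configurable because
#' real cohorts report it ambiguously).
#'
#' @param config path to a JSON file, or an equivalent named list.
#' @return validated config list (class `run_config`) with defaults filled.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      zebra_stop("zebra_config_error", "config file not found: ", config)
    config <- tryCatch(jsonlite::fromJSON(config, simplifyVector = TRUE),
                       error = function(e)
                         zebra_stop("zebra_config_error",
                                    "config is not valid JSON: ",
                                    conditionMessage(e)))
  }
  if (!is.list(config))
    zebra_stop("zebra_config_error", "config must be a JSON object")
  if (is.null(config$seed))
    zebra_stop("zebra_config_error", "missing required field: seed")
  known <- c("seed", "cohort", "tiling", "classify", "segment", "cutoff",
             "aggregation_rule", "aggregation_unit", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    zebra_stop("zebra_config_error", "unknown config field(s): ",
               paste(unknown, collapse = ", "))
  config$cutoff <- config$cutoff %||% 0.19
  config$aggregation_rule <- config$aggregation_rule %||% "any_positive"
  config$aggregation_unit <- config$aggregation_unit %||% "case"
  if (!config$aggregation_unit %in% c("case", "slide"))
    zebra_stop("zebra_config_error",
               "aggregation_unit must be 'case' or 'slide'")
  cohort_args <- as.list(config$cohort %||% list())
  if (is.null(cohort_args$seed)) cohort_args$seed <- config$seed
  spec <- tryCatch(do.call(cohort_spec, cohort_args),
                   error = function(e)
                     zebra_stop("zebra_config_error", "invalid cohort block: ",
                                conditionMessage(e)))
  config$spec <- spec
  structure(config, class = "run_config")
}

run_stage <- function(name, log, code) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[zebra] stage %-10s ...", name))
  res <- tryCatch(force(code), error = function(e) {
    if (inherits(e, "zebra_config_error")) stop(e)
    zebra_stop("zebra_stage_error", "stage '", name, "' failed: ",
               conditionMessage(e))
  })
  el <- proc.time()[["elapsed"]] - t0
  log$timings[[name]] <- el
  message(sprintf("[zebra] stage %-10s done in %.1f s", name, el))
  res
}

#' Simulate a synthetic cohort to disk
#'
#' Writes per-glomerulus RGB images and 0/255 mask PNGs, QuPath-dialect
#' GeoJSON annotations, and the cohort manifest / case tables as CSV (stamped
#' with the config hash and seed).
#'
#' @param config JSON path or list, see [read_run_config()].
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return invisibly, a list with the manifest and case table.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir))
    zebra_stop("zebra_config_error", "missing required field: out_dir")
  for (d in file.path(out_dir, c("images", "masks", "annotations")))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      zebra_stop("zebra_data_error", "cannot create directory ", d)
  stamp <- paste0("config_hash=", config_hash(unclass(cfg)),
                  " seed=", cfg$seed)
  sink_case <- function(cs) {
    for (g in cs$glomeruli) {
      base <- sprintf("%s_%s", g$case_id, g$glomerulus_id)
      write_image(g$image, file.path(out_dir, "images",
                                     paste0(base, ".png")))
      write_image(g$glomerulus_mask,
                  file.path(out_dir, "masks",
                            paste0(base, "_glomerulus.png")))
      write_image(g$podocyte_mask,
                  file.path(out_dir, "masks", paste0(base, "_podocyte.png")))
    }
    export_annotations(cs, file.path(out_dir, "annotations"))
  }
  cohort <- generate_cohort(cfg$spec, callback = sink_case)
  write_stamped_csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                    stamp)
  write_stamped_csv(cohort$case_table, file.path(out_dir, "cases.csv"), stamp)
  message("[zebra] wrote cohort of ", nrow(cohort$case_table), " cases / ",
          nrow(cohort$manifest), " glomeruli to ", out_dir)
  invisible(list(manifest = cohort$manifest,
                 case_table = cohort$case_table, out_dir = out_dir))
}

# Tile one synthetic glomerulus: 256 um template region around the tuft
# centroid, single 512 px tile at 0.5 um/px with ground-truth masks, labeled
# by exact polygon intersection; tile tensors are then reduced to the
# segmentation working resolution to keep the cohort in memory.
tile_glomerulus <- function(g, tcfg, store_px) {
  s <- g$mpp / tcfg$target_mpp
  ctr <- which(g$glomerulus_mask, arr.ind = TRUE)
  cx_um <- (mean(ctr[, 2]) - 0.5) * g$mpp
  cy_um <- (mean(ctr[, 1]) - 0.5) * g$mpp
  tmpl <- make_region_templates(cbind(cx_um, cy_um),
                                side_um = tcfg$tile_px * tcfg$target_mpp,
                                mpp = g$mpp)[[1]]
  tmpl$class_name <- "glomerulus"
  tmpl$case_id <- g$case_id; tmpl$slide_id <- g$slide_id
  tmpl$region_id <- g$glomerulus_id
  tiles <- extract_tiles(g$image, tmpl, tcfg, src_mpp = g$mpp,
                         masks = list(glomerulus = g$glomerulus_mask,
                                      podocyte = g$podocyte_mask))
  pods <- lapply(mask_to_polygons(g$podocyte_mask), function(p)
    region_annotation(p * s, "foamy_podocyte", g$case_id, g$slide_id,
                      g$glomerulus_id))
  tiles <- label_tiles(tiles, pods, tile_px = tcfg$tile_px)
  lapply(tiles, function(tl) {
    f <- nrow(tl$pixels) / store_px
    tl$pixels <- shrink_tile(tl$pixels, store_px)
    tl$masks <- lapply(tl$masks, function(m)
      block_mean(m * 1, as.integer(f)) >= 0.5)
    tl
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort, extracts labeled tiles, trains the tile classifier
#' and the podocyte and glomerulus segmenters with case-level 5-fold
#' cross-validation, aggregates out-of-fold predictions to glomerulus and
#' case level, computes ZEBRA scores from the predicted masks, and evaluates
#' everything ([evaluate_run()]). All outputs are stamped with the config
#' hash and seed.
#'
#' @param config JSON path or list, see [read_run_config()].
#' @param out_dir output directory for CSV tables, the report JSON and a
#'   model bundle; `NULL` skips writing.
#' @return object of class `zebra_run`: the report plus prediction/score
#'   tables, pooled segmentation metrics and stage timings.
#' @export
cmd_run_all <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  log <- new.env()
  log$timings <- list()
  t_start <- proc.time()[["elapsed"]]

  tcfg <- do.call(tiling_config, as.list(cfg$tiling %||% list()))
  cls_args <- as.list(cfg$classify %||% list())
  if (is.null(cls_args$seed)) cls_args$seed <- derive_seed(cfg$seed, "cls")
  ccfg <- do.call(train_config, cls_args)
  seg_args <- as.list(cfg$segment %||% list())
  if (is.null(seg_args$seed)) seg_args$seed <- derive_seed(cfg$seed, "seg")
  scfg_pod <- do.call(seg_train_config,
                      c(seg_args, list(target = "podocyte")))
  scfg_glo <- do.call(seg_train_config,
                      c(seg_args, list(target = "glomerulus")))

  tiles <- list()
  cohort <- run_stage("simulate", log, {
    generate_cohort(cfg$spec, callback = function(cs) {
      for (g in cs$glomeruli)
        tiles <<- c(tiles, tile_glomerulus(g, tcfg, scfg_pod$input_px))
    })
  })
  tiles <- unname(tiles)
  if (length(tiles) == 0)
    zebra_stop("zebra_data_error", "cohort produced no tiles")

  folds <- run_stage("folds", log,
    make_case_folds(vapply(tiles, `[[`, character(1), "case_id"), k = 5,
                    seed = derive_seed(cfg$seed, "folds")))

  cls <- run_stage("classify", log, train_classifier(tiles, folds, ccfg))
  tile_preds <- cls$oof

  agg <- run_stage("aggregate", log, {
    key <- paste(tile_preds$case_id, tile_preds$region_id, sep = "::")
    region_rows <- lapply(split(seq_len(nrow(tile_preds)), key), function(ii) {
      pr <- tile_preds[ii, ]
      a <- aggregate_glomerulus(pr, rule = cfg$aggregation_rule)
      data.frame(case_id = pr$case_id[1], slide_id = pr$slide_id[1],
                 region_id = pr$region_id[1], predicted_label = a$label,
                 score = a$score,
                 label = if (any(pr$label == "foamy")) "foamy" else
                   "not_foamy",
                 stringsAsFactors = FALSE)
    })
    region_preds <- do.call(rbind, region_rows)
    unit <- if (cfg$aggregation_unit == "slide") region_preds$slide_id else
      region_preds$case_id
    case_rows <- lapply(split(seq_len(nrow(region_preds)), unit),
                        function(ii) {
      rp <- region_preds[ii, ]
      data.frame(case_id = unit[ii][1],
                 predicted = aggregate_case(rp$predicted_label),
                 disease = if (any(rp$label == "foamy")) "FN" else "control",
                 stringsAsFactors = FALSE)
    })
    list(region_preds = region_preds, case_preds = do.call(rbind, case_rows))
  })

  seg_pod <- run_stage("seg-podocyte", log,
                       train_segmenter(tiles, folds, scfg_pod))
  seg_glo <- run_stage("seg-glomerulus", log,
                       train_segmenter(tiles, folds, scfg_glo))

  sc <- run_stage("score", log, {
    notes <- character(0)
    idx <- intersect(seg_pod$oof_index, seg_glo$oof_index)
    reg_key <- paste(vapply(tiles, `[[`, character(1), "case_id"),
                     vapply(tiles, `[[`, character(1), "region_id"),
                     sep = "::")
    gscores <- list()
    for (k in unique(reg_key[idx])) {
      ii <- idx[reg_key[idx] == k]
      fpA <- sum(vapply(ii, function(i)
        sum(seg_pod$oof_masks[[i]] & seg_glo$oof_masks[[i]]), numeric(1)))
      tgA <- sum(vapply(ii, function(i)
        sum(seg_glo$oof_masks[[i]]), numeric(1)))
      if (tgA == 0) {
        notes <- c(notes, paste0("region ", k,
                                 ": empty predicted glomerulus; skipped"))
        next
      }
      gscores[[k]] <- structure(
        list(fpA = fpA, tgA = tgA, zs = 100 * fpA / tgA,
             region_id = tiles[[ii[1]]]$region_id,
             case_id = tiles[[ii[1]]]$case_id),
        class = "glomerulus_score")
    }
    case_ids <- vapply(gscores, `[[`, character(1), "case_id")
    cscores <- lapply(split(gscores, case_ids), function(gs)
      classify_case(case_zs(unname(gs)), cfg$cutoff))
    # screening behaviour of the segmentation output
    pod_pos <- vapply(seg_pod$oof_index, function(i)
      tile_positive(seg_pod$oof_masks[[i]]), logical(1))
    pod_lab <- vapply(tiles[seg_pod$oof_index], `[[`, character(1), "label")
    list(gscores = gscores, cscores = cscores,
         screening = seg_screen_metrics(pod_pos, pod_lab), notes = notes)
  })

  report <- run_stage("evaluate", log, {
    case_scores <- case_score_table(sc$cscores)
    rep <- evaluate_run(tile_preds, agg$region_preds, agg$case_preds,
                        case_scores = case_scores,
                        case_records = cohort$case_table,
                        seed = derive_seed(cfg$seed, "eval"))
    rep$segmentation <- list(
      podocyte = seg_pod$metrics, glomerulus = seg_glo$metrics,
      screening = sc$screening)
    rep$zs_roc_youden <- tryCatch(
      youden_cutoff(case_scores$mean_zs,
                    cohort$case_table$disease[
                      match(case_scores$case_id,
                            cohort$case_table$case_id)]),
      error = function(e) NULL)
    rep$notes <- c(rep$notes, sc$notes)
    rep
  })

  elapsed <- proc.time()[["elapsed"]] - t_start
  stamp <- paste0("config_hash=", config_hash(unclass(cfg)),
                  " seed=", cfg$seed)
  run <- structure(list(
    report = report, tile_preds = tile_preds,
    region_preds = agg$region_preds, case_preds = agg$case_preds,
    glomerulus_scores = glomerulus_score_table(unname(sc$gscores)),
    case_scores = case_score_table(sc$cscores),
    manifest = cohort$manifest, case_table = cohort$case_table,
    timings = log$timings, elapsed = elapsed, stamp = stamp,
    config_hash = config_hash(unclass(cfg)), seed = cfg$seed),
    class = "zebra_run")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      zebra_stop("zebra_data_error", "cannot create directory ", out_dir)
    write_stamped_csv(run$tile_preds,
                      file.path(out_dir, "predictions_tiles.csv"), stamp)
    write_stamped_csv(run$region_preds,
                      file.path(out_dir, "predictions_glomeruli.csv"), stamp)
    write_stamped_csv(run$case_preds,
                      file.path(out_dir, "predictions_cases.csv"), stamp)
    write_stamped_csv(run$glomerulus_scores,
                      file.path(out_dir, "scores_glomeruli.csv"), stamp)
    write_stamped_csv(run$case_scores,
                      file.path(out_dir, "scores_cases.csv"), stamp)
    rep_json <- c(list(config_hash = run$config_hash, seed = run$seed,
                       elapsed_s = elapsed, timings = log$timings),
                  unclass(report))
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    save_model_bundle(cls$models[[1]],
                      file.path(out_dir, "models", "classifier_fold0"))
  }
  message(sprintf("[zebra] pipeline finished in %.1f s", elapsed))
  run
}

#' @export
print.zebra_run <- function(x, ...) {
  cat(sprintf("zebrascore run (seed %s, config %s, %.1f s)\n",
              x$seed, x$config_hash, x$elapsed))
  print(x$report)
  invisible(x)
}
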