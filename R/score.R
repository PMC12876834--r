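# The ZEBRA score: foamy-podocyte area (fpA) as a percentage of total
# glomerular area (tgA), per glomerulus, averaged per case, and compared with
# a cutoff to call FN vs control. Podocyte pixels predicted outside the
# glomerular mask are excluded: the score is by definition a proportion of
# glomerular area.

#' Compute the ZEBRA score of one glomerulus
#'
#' `fpA = |podocyte n glomerulus|`, `tgA = |glomerulus|`,
#' `zs = 100 * fpA / tgA` (percent).
#'
#' @param podocyte_mask,glomerulus_mask logical or 0/1 masks of one shape.
#' @param region_id,case_id provenance identifiers.
#' @return object of class `glomerulus_score` with `fpA`, `tgA`, `zs`.
#' @export
compute_zs <- function(podocyte_mask, glomerulus_mask,
                       region_id = NA_character_, case_id = NA_character_) {
  if (!all(dim(podocyte_mask) == dim(glomerulus_mask)))
    stop("mask shapes differ")
  tgA <- sum(glomerulus_mask != 0)
  if (tgA == 0)
    stop("empty glomerulus mask: ZEBRA score undefined for region '",
         region_id, "' (caller may skip this region)")
  fpA <- sum(podocyte_mask != 0 & glomerulus_mask != 0)
  structure(list(fpA = fpA, tgA = tgA, zs = 100 * fpA / tgA,
                 region_id = region_id, case_id = case_id),
            class = "glomerulus_score")
}

#' @export
print.glomerulus_score <- function(x, ...) {
  cat(sprintf("ZS %.3f%% (fpA %d / tgA %d) region %s case %s\n",
              x$zs, x$fpA, x$tgA, x$region_id, x$case_id))
  invisible(x)
}

#' Case-level ZEBRA score
#'
#' Unweighted mean of the per-glomerulus scores of one case.
#'
#' @param scores list of [compute_zs()] results, all from the same case.
#' @return object of class `case_score` with `case_id`, `mean_zs`,
#'   `n_glomeruli` (and `predicted`/`cutoff_used` unset until
#'   [classify_case()]).
#' @export
case_zs <- function(scores) {
  if (length(scores) == 0) stop("no glomerulus scores supplied")
  ids <- unique(vapply(scores, `[[`, character(1), "case_id"))
  if (length(ids) > 1)
    stop("glomerulus scores mix cases: ", paste(ids, collapse = ", "))
  zs <- vapply(scores, `[[`, numeric(1), "zs")
  structure(list(case_id = ids, mean_zs = mean(zs),
                 n_glomeruli = length(zs), predicted = NA_character_,
                 cutoff_used = NA_real_),
            class = "case_score")
}

#' Classify a case against a ZEBRA-score cutoff
#'
#' FN iff `mean_zs >= cutoff` (inclusive: a tie favours sensitivity, in line
#' with the screening intent).
#'
#' @param case_score a [case_zs()] result.
#' @param cutoff non-negative cutoff, same percent scale as `mean_zs`.
#' @return the `case_score` with `predicted` (`"FN"`/`"control"`) and
#'   `cutoff_used` filled in.
#' @export
classify_case <- function(case_score, cutoff) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  case_score$predicted <- if (case_score$mean_zs >= cutoff) "FN" else "control"
  case_score$cutoff_used <- cutoff
  case_score
}

# Tabulate score objects for CSV export.
glomerulus_score_table <- function(scores) {
  do.call(rbind, lapply(scores, function(s)
    data.frame(case_id = s$case_id, region_id = s$region_id, fpA = s$fpA,
               tgA = s$tgA, zs = s$zs, stringsAsFactors = FALSE)))
}

case_score_table <- function(case_scores) {
  do.call(rbind, lapply(case_scores, function(s)
    data.frame(case_id = s$case_id, n_glomeruli = s$n_glomeruli,
               mean_zs = s$mean_zs, predicted = s$predicted,
               cutoff_used = s$cutoff_used, stringsAsFactors = FALSE)))
}
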