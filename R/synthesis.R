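# Synthetic glomerulus generator: stain-tinted background, elliptical/blobby
# glomerular tuft, and "foamy podocyte" lesions rendered as clusters of
# overlapping pale discs with a darker rim. Every image comes with paired
# ground-truth masks so downstream tiling, training and scoring are testable
# without whole-slide images.

STAIN_PALETTES <- list(
  HE = list(bg = c(0.95, 0.92, 0.93), tuft = c(0.84, 0.60, 0.68),
            foam = c(0.97, 0.95, 0.96), rim = c(0.55, 0.42, 0.52)),
  PAS = list(bg = c(0.96, 0.92, 0.95), tuft = c(0.76, 0.44, 0.64),
             foam = c(0.97, 0.94, 0.96), rim = c(0.48, 0.30, 0.46))
)

#' Specify a synthetic cohort
#'
#' Defaults describe the desk-scale stand-in cohort: 10 Fabry-nephropathy (FN)
#' and 10 control cases, 4-8 glomeruli per case, per-glomerulus lesion area
#' fractions drawn from \[0.10, 0.35\] for lesioned glomeruli, and 74% of a
#' positive case's glomeruli bearing lesions (the share reported for real FN
#' cohorts). Images are emitted at a scanner source resolution (default
#' 0.2208 um/px) so the tiling module's physical-scale normalization is always
#' exercised.
#'
#' @param n_cases_pos,n_cases_neg number of FN and control cases.
#' @param glomeruli_per_case integer range (length 2) of glomeruli per case.
#' @param target_fraction_range range of foamy-area fraction for lesioned
#'   glomeruli (each in \[0, 0.5\]).
#' @param fraction_positive_glomeruli share of a positive case's glomeruli
#'   that carry lesions.
#' @param stain `"HE"` or `"PAS"`.
#' @param source_mpp source resolution in um/px; one of 0.2208, 0.2506, 0.25
#'   (the scanner resolutions of the reference dataset) or any positive value.
#' @param noise_level sd of additive Gaussian pixel noise.
#' @param region_um physical side of the square glomerular region image (um).
#' @param seed master seed for cohort generation.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases_pos = 10, n_cases_neg = 10,
                        glomeruli_per_case = c(4, 8),
                        target_fraction_range = c(0.10, 0.35),
                        fraction_positive_glomeruli = 0.74,
                        stain = c("HE", "PAS"),
                        source_mpp = 0.2208,
                        noise_level = 0.02,
                        region_um = 256,
                        seed = 1L) {
  stain <- match.arg(stain)
  spec <- list(n_cases_pos = as.integer(n_cases_pos),
               n_cases_neg = as.integer(n_cases_neg),
               glomeruli_per_case = as.integer(glomeruli_per_case),
               target_fraction_range = as.numeric(target_fraction_range),
               fraction_positive_glomeruli = fraction_positive_glomeruli,
               stain = stain, source_mpp = source_mpp,
               noise_level = noise_level, region_um = region_um,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_cases_pos < 0 || n_cases_neg < 0 || n_cases_pos + n_cases_neg < 1)
      stop("cohort must contain at least one case")
    if (length(glomeruli_per_case) != 2 || any(glomeruli_per_case < 1) ||
        glomeruli_per_case[1] > glomeruli_per_case[2])
      stop("glomeruli_per_case must be an increasing range of counts >= 1")
    if (length(target_fraction_range) != 2 ||
        target_fraction_range[1] > target_fraction_range[2] ||
        any(target_fraction_range < 0) || any(target_fraction_range > 0.5))
      stop("target_fraction_range must be an increasing pair in [0, 0.5]")
    if (fraction_positive_glomeruli < 0 || fraction_positive_glomeruli > 1)
      stop("fraction_positive_glomeruli must be in [0, 1]")
    if (source_mpp <= 0) stop("source_mpp must be positive")
    if (noise_level < 0) stop("noise_level must be >= 0")
    if (region_um <= 0) stop("region_um must be positive")
  })
  invisible(spec)
}

#' Generate one synthetic glomerulus image with ground-truth masks
#'
#' Draws an elliptical tuft with a wobbly boundary on a stain-tinted
#' background and places pale "foamy" disc clusters inside the tuft by greedy
#' placement with rejection until the foamy area fraction is within +/- 0.01
#' of `target_fraction` (exactly zero when the target is zero). Uses the
#' current R RNG stream; seed upstream for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param target_fraction desired foamy-area / glomerular-area fraction, in
#'   \[0, 0.5\].
#' @param case_id,slide_id,glomerulus_id provenance identifiers.
#' @return object of class `synthetic_glomerulus`: fields `image` (H x W x 3
#'   array in \[0,1\]), `glomerulus_mask`, `podocyte_mask` (logical matrices),
#'   `true_fraction`, `label` (`"foamy"`/`"not_foamy"`), provenance and `mpp`.
#' @export
generate_glomerulus <- function(spec, target_fraction,
                                case_id = "case1", slide_id = "S1",
                                glomerulus_id = "G1") {
  if (target_fraction < 0 || target_fraction > 0.5)
    stop("target_fraction must be in [0, 0.5]; lesion fractions above 0.5 ",
         "are unrealistic and disc placement may not converge")
  side <- as.integer(round(spec$region_um / spec$source_mpp))
  pal <- STAIN_PALETTES[[spec$stain]]
  nl <- spec$noise_level

  # background with low-frequency mottle; one shared fine-noise field keeps
  # the channels luminance-correlated (and the generator fast)
  img <- array(0, c(side, side, 3))
  mott <- resize_bilinear(matrix(rnorm(64), 8, 8), side, side)
  fine <- matrix(rnorm(side * side, 0, 1), side, side)
  for (ch in 1:3)
    img[, , ch] <- clamp01(pal$bg[ch] + 0.02 * mott + nl * fine)

  # wobbly elliptical tuft
  cx <- side / 2 + runif(1, -0.03, 0.03) * side
  cy <- side / 2 + runif(1, -0.03, 0.03) * side
  rx <- side * 0.35 * runif(1, 0.9, 1.1)
  ry <- side * 0.35 * runif(1, 0.9, 1.1)
  a2 <- runif(1, 0.02, 0.06); p2 <- runif(1, 0, 2 * pi)
  a3 <- runif(1, 0.02, 0.06); p3 <- runif(1, 0, 2 * pi)
  xs <- (seq_len(side) - 0.5)
  u <- outer(rep(1, side), (xs - cx) / rx)
  v <- outer(xs - cy, rep(1, side)) / ry
  th <- atan2(v, u)
  tuft <- sqrt(u^2 + v^2) <= 1 + a2 * cos(2 * th + p2) + a3 * cos(3 * th + p3)
  tx <- resize_bilinear(matrix(rnorm(256), 16, 16), side, side)
  for (ch in 1:3) {
    w <- img[, , ch]
    w[tuft] <- clamp01(pal$tuft[ch] + 0.04 * tx[tuft] + nl * fine[tuft])
    img[, , ch] <- w
  }

  tgA <- sum(tuft)
  pod <- matrix(FALSE, side, side)
  if (target_fraction > 0) {
    r_eff <- sqrt(tgA / pi)
    inside_idx <- which(tuft)
    tries <- 0L
    while (sum(pod) / tgA < target_fraction - 0.01 && tries < 2000L) {
      tries <- tries + 1L
      deficit <- target_fraction - sum(pod) / tgA
      # disc radius scaled down as the deficit shrinks so we can always land
      # inside the +/- 0.01 band
      rbase <- r_eff * min(0.09, max(0.02, sqrt(deficit / 8)))
      r0 <- rbase * runif(1, 0.8, 1.2)
      ndisc <- sample(2:10, 1)
      ctr <- inside_idx[sample.int(length(inside_idx), 1)]
      ccy <- ((ctr - 1) %% side) + 0.5
      ccx <- ((ctr - 1) %/% side) + 0.5
      shrink <- 1
      for (attempt in 1:6) {
        dcx <- ccx + rnorm(ndisc, 0, r0 * shrink * 1.1)
        dcy <- ccy + rnorm(ndisc, 0, r0 * shrink * 1.1)
        dr <- r0 * shrink * runif(ndisc, 0.7, 1.3)
        rimw <- max(1.5, 0.12 * r0 * shrink)
        # candidate disc masks (fill and rim) in local windows
        cand <- vector("list", ndisc)
        for (d in seq_len(ndisc)) {
          c0 <- max(1L, floor(dcx[d] - dr[d] - rimw))
          c1 <- min(side, ceiling(dcx[d] + dr[d] + rimw))
          q0 <- max(1L, floor(dcy[d] - dr[d] - rimw))
          q1 <- min(side, ceiling(dcy[d] + dr[d] + rimw))
          if (c0 > c1 || q0 > q1) next
          xc <- (c0:c1) - 0.5; yc <- (q0:q1) - 0.5
          d2 <- outer((yc - dcy[d])^2, (xc - dcx[d])^2, `+`)
          tw <- tuft[q0:q1, c0:c1]
          cand[[d]] <- list(fill = (d2 <= dr[d]^2) & tw,
                            rim = (d2 > dr[d]^2) & (d2 <= (dr[d] + rimw)^2) &
                              tw,
                            q0 = q0, q1 = q1, c0 = c0, c1 = c1)
        }
        tmp <- pod
        for (cd in cand) if (!is.null(cd))
          tmp[cd$q0:cd$q1, cd$c0:cd$c1] <- tmp[cd$q0:cd$q1, cd$c0:cd$c1] |
            cd$fill
        if (sum(tmp) / tgA <= target_fraction + 0.01) {
          if (sum(tmp) > sum(pod)) {
            pod <- tmp
            for (cd in cand) {
              if (is.null(cd)) next
              rows <- cd$q0:cd$q1; cols <- cd$c0:cd$c1
              txw <- tx[rows, cols]
              for (ch in 1:3) {
                w <- img[rows, cols, ch]
                w[cd$fill] <- clamp01(pal$foam[ch] + 0.03 * txw[cd$fill])
                w[cd$rim] <- clamp01(pal$rim[ch] + 0.03 * txw[cd$rim])
                img[rows, cols, ch] <- w
              }
            }
          }
          break
        }
        shrink <- shrink * 0.65
      }
    }
  }

  structure(list(image = img, glomerulus_mask = tuft, podocyte_mask = pod,
                 true_fraction = sum(pod) / tgA,
                 label = if (sum(pod) > 0) "foamy" else "not_foamy",
                 case_id = case_id, slide_id = slide_id,
                 glomerulus_id = glomerulus_id,
                 mpp = spec$source_mpp, stain = spec$stain),
            class = "synthetic_glomerulus")
}

#' Generate one synthetic case
#'
#' Reproducible independently of other cases: the case RNG stream is derived
#' from `spec$seed` and `case_id`.
#'
#' @param spec a [cohort_spec()].
#' @param case_id case identifier.
#' @param disease `"FN"` or `"control"`.
#' @return object of class `synthetic_case` with fields `case_id`, `disease`,
#'   `sex`, `glomeruli` (list of [generate_glomerulus()] outputs) and
#'   `synthetic_mpvs` (0-3 manual-score emulation; exactly 0 for controls).
#' @export
generate_case <- function(spec, case_id, disease = c("FN", "control")) {
  disease <- match.arg(disease)
  with_seed(derive_seed(spec$seed, case_id), {
    rng <- spec$glomeruli_per_case
    n_glom <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1L
    sex <- sample(c("F", "M"), 1)
    glomeruli <- vector("list", n_glom)
    for (g in seq_len(n_glom)) {
      lesioned <- disease == "FN" &&
        runif(1) < spec$fraction_positive_glomeruli
      tf <- if (lesioned)
        runif(1, spec$target_fraction_range[1], spec$target_fraction_range[2])
      else 0
      glomeruli[[g]] <- generate_glomerulus(
        spec, tf, case_id = case_id, slide_id = paste0(case_id, "_S1"),
        glomerulus_id = sprintf("G%02d", g))
    }
    mean_tf <- mean(vapply(glomeruli, `[[`, numeric(1), "true_fraction"))
    mpvs <- if (disease == "control") 0 else
      min(3, max(0, 3 * mean_tf / spec$target_fraction_range[2] +
                   rnorm(1, 0, 0.15)))
    structure(list(case_id = case_id, disease = disease, sex = sex,
                   glomeruli = glomeruli, synthetic_mpvs = mpvs),
              class = "synthetic_case")
  })
}

case_manifest <- function(case) {
  do.call(rbind, lapply(case$glomeruli, function(g)
    data.frame(case_id = g$case_id, slide_id = g$slide_id,
               glomerulus_id = g$glomerulus_id, disease = case$disease,
               label = g$label, true_fraction = g$true_fraction,
               mpp = g$mpp, stain = g$stain, stringsAsFactors = FALSE)))
}

#' Generate a synthetic cohort
#'
#' Builds positive (FN) and control cases per the spec. With the default
#' in-memory mode all cases are returned; with a `callback` each case is
#' handed over as soon as it is generated and then dropped, so large cohorts
#' never hold more than one case of image data in memory.
#'
#' @param spec a [cohort_spec()].
#' @param callback optional `function(case)` consuming each case.
#' @return list of class `synthetic_cohort` with `cases` (list, or `NULL`
#'   in callback mode), `manifest` (one row per glomerulus), `case_table`
#'   (one row per case: disease, sex, stain, synthetic MPVS) and `spec`.
#' @export
generate_cohort <- function(spec, callback = NULL) {
  validate_cohort_spec(spec)
  ids <- c(if (spec$n_cases_pos > 0)
    sprintf("FN%02d", seq_len(spec$n_cases_pos)),
    if (spec$n_cases_neg > 0)
      sprintf("CTRL%02d", seq_len(spec$n_cases_neg)))
  diseases <- c(rep("FN", spec$n_cases_pos), rep("control", spec$n_cases_neg))
  cases <- if (is.null(callback)) vector("list", length(ids)) else NULL
  manifest <- vector("list", length(ids))
  case_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cs <- generate_case(spec, ids[i], diseases[i])
    manifest[[i]] <- case_manifest(cs)
    case_rows[[i]] <- data.frame(case_id = cs$case_id, disease = cs$disease,
                                 sex = cs$sex, stain = spec$stain,
                                 mpvs = cs$synthetic_mpvs,
                                 n_glomeruli = length(cs$glomeruli),
                                 stringsAsFactors = FALSE)
    if (is.null(callback)) cases[[i]] <- cs else callback(cs)
  }
  structure(list(cases = cases, manifest = do.call(rbind, manifest),
                 case_table = do.call(rbind, case_rows), spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic cohort:", nrow(x$case_table), "cases,", nrow(m),
      "glomeruli\n")
  cat("  FN glomeruli:", sum(m$disease == "FN"),
      sprintf("(%d foamy)", sum(m$label == "foamy")),
      "| control glomeruli:", sum(m$disease == "control"), "\n")
  invisible(x)
}

#' Summarize cohort bookkeeping from a glomerulus manifest
#'
#' Computes the counts used for dataset reporting: glomeruli per disease arm,
#' the share of FN glomeruli bearing vacuolized podocytes, and the final
#' positive/negative distribution (negatives pool lesion-free FN glomeruli
#' with all control glomeruli).
#'
#' @param manifest data frame with columns `disease` ("FN"/"control") and
#'   `label` ("foamy"/"not_foamy"), one row per glomerulus.
#' @return list with `n_fn`, `n_control`, `n_fn_positive`,
#'   `share_fn_positive`, `n_positive`, `n_negative`.
#' @export
cohort_summary <- function(manifest) {
  stopifnot(all(c("disease", "label") %in% names(manifest)))
  n_fn <- sum(manifest$disease == "FN")
  n_ctrl <- sum(manifest$disease == "control")
  n_fn_pos <- sum(manifest$disease == "FN" & manifest$label == "foamy")
  list(n_fn = n_fn, n_control = n_ctrl, n_fn_positive = n_fn_pos,
       share_fn_positive = if (n_fn > 0) n_fn_pos / n_fn else NA_real_,
       n_positive = sum(manifest$label == "foamy"),
       n_negative = sum(manifest$label == "not_foamy"))
}
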