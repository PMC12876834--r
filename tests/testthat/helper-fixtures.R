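# Shared fixtures, built in code and memoised per test session. Unit tests
# run on physically small glomerular regions (the generator is scale-free in
# its area fractions) to keep the suite fast; the acceptance tests exercise
# the full-size default world.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Same geometry as the default world (a 256 um box around the tuft, one
# 512 px tile at 0.5 um/px) but generated at a coarse 1.0 um/px source so the
# suite stays fast; the tiling path then exercises upsampling.
small_spec <- function(...) {
  cohort_spec(n_cases_pos = 5, n_cases_neg = 5, glomeruli_per_case = c(5, 7),
              region_um = 256, source_mpp = 1.0, seed = 404, ...)
}

# A small labeled tile set with ground-truth masks (30 tiles, 10 cases).
small_tiles <- function() {
  memo("small_tiles", {
    tiles <- list()
    tcfg <- tiling_config()
    generate_cohort(small_spec(), callback = function(cs) {
      for (g in cs$glomeruli)
        tiles <<- c(tiles, zebrascore:::tile_glomerulus(g, tcfg, 128L))
    })
    tiles
  })
}

small_folds <- function() {
  memo("small_folds", {
    tiles <- small_tiles()
    make_case_folds(vapply(tiles, `[[`, character(1), "case_id"),
                    k = 5, seed = 11)
  })
}

# Filled-circle mask, the standard convex test shape.
circle_mask <- function(side, cx, cy, r) {
  xc <- (seq_len(side)) - 0.5
  outer((xc - cy)^2, (xc - cx)^2, `+`) <= r^2
}

# Random blob mask: union of a few random discs.
random_blob_mask <- function(side, n_discs = 3) {
  m <- matrix(FALSE, side, side)
  for (i in seq_len(n_discs))
    m <- m | circle_mask(side, runif(1, side * 0.2, side * 0.8),
                         runif(1, side * 0.2, side * 0.8),
                         runif(1, side * 0.06, side * 0.2))
  m
}

# Brute-force 2x2 metrics used as the independent oracle.
oracle_confusion <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(accuracy = div(tp + tn, tp + fp + fn + tn),
       sens = div(tp, tp + fn), spec = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

# O(n^2) pair-counting AUC oracle (ties counted one half).
oracle_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
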