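# Independent oracles shared across test files.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Every clinimetric recomputed from the expanded vector of
# (reference, prediction) pairs by direct counting.
pairwise_metrics <- function(cm) {
  counts <- as.vector(t(cm))   # row-major: reference varies slowest
  ref <- rep(rep(0:2, each = 3), counts)
  prd <- rep(rep(0:2, times = 3), counts)
  po <- mean(ref == prd)
  pe <- sum(vapply(0:2, function(c) mean(ref == c) * mean(prd == c),
                   numeric(1)))
  per <- lapply(0:2, function(c) {
    tp <- sum(ref == c & prd == c); fn <- sum(ref == c & prd != c)
    fp <- sum(ref != c & prd == c); tn <- sum(ref != c & prd != c)
    sdiv <- function(a, b) if (b > 0) a / b else NA_real_
    list(sens = sdiv(tp, tp + fn), spec = sdiv(tn, tn + fp),
         ppv = sdiv(tp, tp + fp), npv = sdiv(tn, tn + fn))
  })
  list(accuracy = po, kappa = (po - pe) / (1 - pe),
       macro_recall = mean(vapply(per, `[[`, numeric(1), "sens")),
       per = per)
}

random_cm <- function() matrix(rpois(9, 8) + rbinom(9, 1, 0.5), 3, 3)

# Brute-force enumeration of the start times produced by sliding a 60 s
# window at the given stride over every gap-free consecutive minute pair,
# deduplicated (original window positions count once).
enumerate_slid_starts <- function(minutes, stride_s = 5) {
  starts <- minutes * 60
  for (m in minutes) {
    if ((m + 1) %in% minutes) {
      starts <- c(starts, m * 60 + seq(stride_s, 60 - stride_s, by = stride_s))
    }
  }
  sort(unique(starts))
}
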