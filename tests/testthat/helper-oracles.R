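# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the implementation paths
# they check.

# Exhaustive rule fit: every flag vector, per-sample classification by an
# explicit if-chain. Returns the maximal achievable training accuracy.
brute_best_accuracy <- function(values, labels) {
  labels <- as.factor(labels)
  med <- vapply(split(values, labels), median, numeric(1))
  ord <- order(med, seq_along(med))
  classes <- levels(labels)[ord]
  m <- sort(med)
  thr <- (m[-length(m)] + m[-1]) / 2
  nflag <- length(thr)
  best <- -1
  for (f in 0:(2^nflag - 1)) {
    flags <- as.logical(bitwAnd(bitwShiftR(f, (nflag - 1):0), 1L))
    # a sample's class index is one plus the number of thresholds it crosses
    # (flag TRUE: crossing requires v strictly above t_i)
    pred <- vapply(values, function(v) {
      cls <- 1L
      for (i in seq_along(thr)) {
        if (if (flags[i]) v > thr[i] else v >= thr[i]) cls <- cls + 1L
      }
      classes[cls]
    }, character(1))
    best <- max(best, mean(pred == as.character(labels)))
  }
  best
}

# O(m^2) Pareto filter built directly on the domination definition.
brute_pareto_mask <- function(acc, cplx) {
  m <- length(acc)
  vapply(seq_len(m), function(i) {
    !any(vapply(seq_len(m), function(j) {
      j != i && acc[j] >= acc[i] && cplx[j] <= cplx[i] &&
        (acc[j] > acc[i] || cplx[j] < cplx[i])
    }, logical(1)))
  }, logical(1))
}

# Tiny vocabulary over generic gene names.
tiny_blocks <- function(p = 6) building_blocks(paste0("g", seq_len(p)))

# Random ClassValueTable-style instance: values plus labels for n classes.
random_instance <- function(n_classes, n_samples) {
  labels <- factor(sample(paste0("c", seq_len(n_classes)), n_samples,
                          replace = TRUE))
  while (nlevels(droplevels(labels)) < n_classes) {
    labels <- factor(sample(paste0("c", seq_len(n_classes)), n_samples,
                            replace = TRUE))
  }
  list(values = round(rnorm(n_samples) * 3, 2), labels = labels)
}

# A dataset one feature of which separates the classes perfectly.
separable_dataset <- function(n_classes = 3, per_class = 8, p = 10, seed = 99) {
  set.seed(seed)
  n <- n_classes * per_class
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("g", seq_len(p))))
  labels <- factor(rep(paste0("c", seq_len(n_classes)), each = per_class))
  x[, "g1"] <- as.integer(labels) * 10 + rnorm(n, sd = 0.1)
  list(x = x, labels = labels)
}
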