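# Independent brute-force oracles. Each deliberately uses a different
# computational route than the package implementation.

# group-by-then-average stratified error
oracle_stratified <- function(y, yhat, metric) {
  vals <- c()
  for (lev in sort(unique(y))) {
    e <- yhat[y == lev] - lev
    vals <- c(vals, if (metric == "rmse") sqrt(mean(e^2)) else mean(abs(e)))
  }
  mean(vals)
}

# concordant-pair counting AUC (ties count 1/2)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# exhaustive pairwise Cliff's delta
oracle_cliffs <- function(a, b) {
  up <- 0; down <- 0
  for (x in a) for (y in b) {
    if (x > y) up <- up + 1
    if (x < y) down <- down + 1
  }
  (up - down) / (length(a) * length(b))
}

# all-midpoints exhaustive F1 threshold search
oracle_threshold <- function(yhat, labels) {
  u <- sort(unique(yhat))
  cands <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
             u[length(u)] + 1)
  f1s <- sapply(cands, function(t) {
    pred <- as.integer(yhat >= t)
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  list(threshold = cands[which.max(f1s)], f1 = max(f1s))
}

# per-region loop atlas summary
oracle_atlas_means <- function(vb, labels, mask, ids) {
  out <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    vox <- which(labels == ids[i] & mask)
    if (length(vox)) out[i] <- mean(vb[vox])
  }
  out
}

# one-way ANOVA F via per-column lm/aov
oracle_anova_f <- function(x, g) {
  summary(stats::aov(x ~ factor(g)))[[1]]$`F value`[1]
}
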