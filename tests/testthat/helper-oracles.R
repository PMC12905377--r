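# Independent oracles shared by unit and acceptance tests.

# brute-force silhouette, coded independently of the package implementation
brute_silhouette <- function(m, cl) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(m) - m[i, ])^2))
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(di[own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(di[cl == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# independent confusion-matrix metrics via table()
oracle_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  cm <- table(factor(truth, classes), factor(pred, classes))
  acc <- 100 * sum(diag(cm)) / sum(cm)
  f1 <- vapply(classes, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  list(accuracy = acc, f1_macro = mean(f1))
}
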