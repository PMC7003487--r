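# Independent oracles used across the suite; deliberately brute-force and
# kept free of any package internals they are checking.

# Mann-Whitney AUC by exhaustive pair enumeration (ties count 0.5).
auc_pair_oracle <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Trapezoidal area under an empirical ROC curve given as (fpr, tpr) points.
auc_trapezoid <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

# Pooled-variance two-sample t statistic, written out from the formula.
pooled_t_oracle <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  list(statistic = tstat, p = 2 * pt(-abs(tstat), df))
}

# Plain Newton/IRLS logistic regression, no penalty, no tricks.
irls_logistic_oracle <- function(X, y, maxit = 50, tol = 1e-12) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(as.numeric(X %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(X, W * X), crossprod(X, y - p))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Random strictly positive percent profiles on the 24-peak simplex.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    g <- matrix(rgamma(n * 24, shape = runif(n * 24, 0.5, 4)), nrow = n)
    m <- 100 * g / rowSums(g)
    colnames(m) <- glyconact::panel_peak_ids()
    cbind(data.frame(sample_id = sprintf("r%03d", seq_len(n))),
          as.data.frame(m))
  })
}

# Reference group-mean profiles as named percent vectors.
reference_mean_vectors <- function() {
  ref <- glyconact::reference_group_profiles()
  list(nrg = setNames(ref$mean_nrg, ref$peak_id),
       rg = setNames(ref$mean_rg, ref$peak_id))
}

# Minimal valid clinical frame for n samples.
toy_clinical <- function(grades, age = NULL) {
  n <- length(grades)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             age = if (is.null(age)) rep(c(50, 65), length.out = n) else age,
             sex = rep(c("male", "female"), length.out = n),
             site = rep(c("U", "M", "L"), length.out = n),
             histology = rep(c("Other", "Adenocarcinoma"), length.out = n),
             regimen = rep(c("XELOX", "DOS"), length.out = n),
             becker_grade = grades, stringsAsFactors = FALSE)
}
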