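# AdaBoost.R2 (Drucker, 1997) for regression, with depth-limited rpart
# trees as base learners and weighted-median aggregation. Each round fits a
# tree to a weight-proportional bootstrap resample, computes the linear loss
# L_i = |err_i| / max|err|, and down-weights well-predicted cases by
# beta^(1 - L_i) with beta = Lbar / (1 - Lbar); rounds with average loss
# >= 0.5 terminate boosting.

adaboost_r2_fit <- function(x, y, n_estimators = 100L, max_depth = 3L,
                            seed = 1L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  set.seed(seed)
  w <- rep(1 / n, n)
  trees <- list()
  log_inv_beta <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 5,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  dat <- cbind(.y = y, x)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE],
                        method = "anova", control = ctrl)
    pred <- predict(fit, x)
    err <- abs(pred - y)
    D <- max(err)
    if (D <= 0) {  # perfect member: it decides alone
      trees <- list(fit); log_inv_beta <- 1
      break
    }
    L <- err / D
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) {
      if (!length(trees)) { trees <- list(fit); log_inv_beta <- 1 }
      break
    }
    beta <- Lbar / (1 - Lbar)
    trees[[length(trees) + 1L]] <- fit
    log_inv_beta <- c(log_inv_beta, log(1 / beta))
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  structure(list(trees = trees, weights = log_inv_beta,
                 feature_names = colnames(x)),
            class = "adaboost_r2")
}

# Weighted median of the member predictions, per row (the R2 aggregation
# rule: smallest prediction whose cumulative member weight reaches half the
# total).
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  P <- vapply(object$trees, function(tr) predict(tr, newdata),
              numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  w <- object$weights
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(w[o])
    p[o][which(cw >= 0.5 * sum(w))[1]]
  })
}
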