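# Single-hidden-layer ReLU multilayer perceptron, trained by BFGS on the
# binary cross-entropy with a small L2 penalty. Kept deliberately minimal:
# the feature space here is 1-2 dimensional and n is small, so a 25-unit
# network trained full-batch with analytic gradients converges in well
# under a second.

mlp_fit <- function(x, y, hidden = 25L, decay = 1e-4, maxit = 300L,
                    seed = 0L) {
  x <- as.matrix(x)
  d <- ncol(x); n <- nrow(x); h <- hidden
  np <- d * h + h + h + 1L
  unpack <- function(theta) {
    list(
      W1 = matrix(theta[seq_len(d * h)], d, h),
      b1 = theta[d * h + seq_len(h)],
      w2 = theta[d * h + h + seq_len(h)],
      b2 = theta[np]
    )
  }
  fwd <- function(par) {
    a <- sweep(x %*% par$W1, 2L, par$b1, "+")
    hidden_act <- pmax(a, 0)
    z <- drop(hidden_act %*% par$w2) + par$b2
    list(h = hidden_act, z = z, p = stats::plogis(z))
  }
  loss <- function(theta) {
    par <- unpack(theta)
    f <- fwd(par)
    eps <- 1e-12
    -mean(y * log(f$p + eps) + (1 - y) * log(1 - f$p + eps)) +
      decay * sum(theta^2)
  }
  grad <- function(theta) {
    par <- unpack(theta)
    f <- fwd(par)
    dz <- (f$p - y) / n
    gw2 <- drop(crossprod(f$h, dz))
    gb2 <- sum(dz)
    dh <- (dz %*% t(par$w2)) * (f$h > 0)
    gW1 <- crossprod(x, dh)
    gb1 <- colSums(dh)
    c(as.numeric(gW1), gb1, gw2, gb2) + 2 * decay * theta
  }
  theta0 <- withr::with_seed(seed, runif(np, -0.7, 0.7) / sqrt(d + 1))
  fit <- stats::optim(theta0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  structure(list(theta = fit$par, unpack = unpack, d = d),
            class = "topocalc_mlp")
}

mlp_predict <- function(fit, newx) {
  newx <- as.matrix(newx)
  par <- fit$unpack(fit$theta)
  a <- sweep(newx %*% par$W1, 2L, par$b1, "+")
  stats::plogis(drop(pmax(a, 0) %*% par$w2) + par$b2)
}

# Fit one of the four classifier kinds on standardized training data and
# return pooled test-set labels and positive-class scores.
# labels are factors with levels c("benign", "malignant"); malignant is the
# positive class throughout.
fit_and_score <- function(kind, x_train, y_train, x_test, seed = 0L) {
  pos <- "malignant"
  switch(kind,
    nn = {
      fit <- mlp_fit(x_train, as.numeric(y_train == pos), seed = seed)
      score <- mlp_predict(fit, x_test)
      list(pred = factor(ifelse(score > 0.5, pos, "benign"),
                         levels = levels(y_train)),
           score = score)
    },
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = 1,
                        scale = FALSE)
      pr <- predict(fit, x_test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the colname
      first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
      score <- if (first == pos) dv[, 1L] else -dv[, 1L]
      list(pred = pr, score = as.numeric(score))
    },
    knn = {
      pr <- class::knn(x_train, x_test, y_train, k = 1L)
      # a discrete classifier: the 0/1 predicted label is the score
      list(pred = pr, score = as.numeric(pr == pos))
    },
    dt = {
      df_train <- data.frame(x_train, .label = y_train)
      fit <- rpart::rpart(.label ~ ., data = df_train, method = "class")
      df_test <- data.frame(x_test)
      names(df_test) <- names(df_train)[seq_len(ncol(x_test))]
      prob <- predict(fit, df_test, type = "prob")[, pos]
      list(pred = factor(ifelse(prob > 0.5, pos, "benign"),
                         levels = levels(y_train)),
           score = as.numeric(prob))
    },
    stop("unknown classifier kind: ", kind, call. = FALSE)
  )
}
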