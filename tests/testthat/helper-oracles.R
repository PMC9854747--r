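# Independent brute-force reference implementations, deliberately written as
# plain double loops so they share no code with the package internals.

oracle_appen <- function(x, m, r_abs) {
  n <- length(x)
  phi <- function(mm) {
    N <- n - mm + 1
    logs <- numeric(N)
    for (i in seq_len(N)) {
      count <- 0
      for (j in seq_len(N)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r_abs) count <- count + 1
      }
      logs[i] <- log(count / N)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r_abs) {
  n <- length(x)
  N <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r_abs) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r_abs) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

oracle_pen <- function(x, order, delay) {
  n_pat <- length(x) - (order - 1) * delay
  pats <- character(n_pat)
  for (i in seq_len(n_pat)) {
    idx <- i + (0:(order - 1)) * delay
    pats[i] <- paste(order(x[idx]), collapse = "-")
  }
  p <- as.numeric(table(pats)) / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

oracle_higuchi <- function(x, kmax) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm_vals <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx)
      total <- 0
      for (q in 2:nm) total <- total + abs(x[idx[q]] - x[idx[q - 1]])
      lm_vals[m] <- (total * (n - 1) / ((nm - 1) * k)) / k
    }
    lk[k] <- mean(lm_vals)
  }
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kmax))))[[2]]
}

# exhaustive winner scan in the standardized space of the model
oracle_winner <- function(model, x) {
  xs <- (x - model$center) / model$scale
  best <- 1
  bestd <- Inf
  for (k in seq_len(nrow(model$weights))) {
    d <- sum((xs - model$weights[k, ])^2)
    if (d < bestd) {
      bestd <- d
      best <- k
    }
  }
  best
}

oracle_quantization_error <- function(model, X) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    xs <- (X[i, ] - model$center) / model$scale
    dmin <- Inf
    for (k in seq_len(nrow(model$weights))) {
      d <- sqrt(sum((xs - model$weights[k, ])^2))
      if (d < dmin) dmin <- d
    }
    total <- total + dmin
  }
  total / nrow(X)
}

oracle_image_mse <- function(a, b) {
  total <- 0
  for (i in seq_len(dim(a)[1]))
    for (j in seq_len(dim(a)[2]))
      for (c in seq_len(dim(a)[3]))
        total <- total + (a[i, j, c] - b[i, j, c])^2
  total / prod(dim(a))
}

oracle_despike <- function(x, window, threshold_sds, protect_factor = 1.5) {
  med <- stats::runmed(x, window, endrule = "median")
  dev <- x - med
  scale <- 1.4826 * stats::median(abs(dev))
  threshold <- max(threshold_sds * scale,
                   protect_factor * stats::quantile(abs(dev), 0.99))
  out <- x
  for (i in seq_along(x)) {
    if (abs(dev[i]) > threshold) out[i] <- med[i]
  }
  out
}

# expand a confusion matrix (rows = true HIGH/MEDIUM/LOW) into label vectors
labels_from_confusion <- function(cm) {
  lv <- c("HIGH", "MEDIUM", "LOW")
  true <- character(0)
  pred <- character(0)
  for (i in 1:3) {
    for (j in 1:3) {
      true <- c(true, rep(lv[i], cm[i, j]))
      pred <- c(pred, rep(lv[j], cm[i, j]))
    }
  }
  list(true = true, pred = pred)
}
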