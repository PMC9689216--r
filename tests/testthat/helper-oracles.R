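# Independent oracles and small fixture builders shared across tests.

# brute-force evaluation of the score-matching sum, written directly from
# its definition (independent of the vectorized implementation)
sm_loss_bruteforce <- function(Y, Theta, eta, cap = Inf) {
  n <- nrow(Y); p <- ncol(Y)
  total <- 0
  for (i in seq_len(n)) {
    yi <- Y[i, ]
    for (j in seq_len(p)) {
      h <- min(yi[j], cap)
      hp <- if (yi[j] < cap) 1 else 0
      r <- sum(Theta[j, ] * yi) - eta[j]
      total <- total + 0.5 * h * r^2 - hp * r - h * Theta[j, j]
    }
  }
  total / n
}

# brute-force TF-IDF scoring: every (term, document) score enumerated
tfidf_bruteforce <- function(counts_list, agg = "max") {
  N <- length(counts_list)
  vocab <- sort(unique(unlist(lapply(counts_list, names))))
  df_t <- sapply(vocab, function(t)
    sum(vapply(counts_list, function(ct) t %in% names(ct), NA)))
  score <- sapply(vocab, function(t) {
    per_doc <- vapply(counts_list, function(ct) {
      f <- if (t %in% names(ct)) ct[[t]] else 0
      f * log(N / df_t[[t]])
    }, 0)
    switch(agg, max = max(per_doc), mean = mean(per_doc), sum = sum(per_doc))
  })
  data.frame(term = vocab, score = score)[order(-score, vocab), ]
}

# generic convex-programming oracle for the penalized joint objective:
# L-BFGS-B on a smoothed (pseudo-Huber) surrogate of the two nonsmooth
# penalty terms, with analytic gradients; eps makes the smoothing bias
# negligible at the comparison tolerance
oracle_joint_fit <- function(panel, lambda1, lambda2, cap = 3,
                             eps = 1e-7, maxit = 2000) {
  p <- panel$p
  M <- panel$M
  hw <- h_weight(cap)
  ut <- which(upper.tri(matrix(0, p, p)))
  K <- length(ut) + 2 * p
  unpack <- function(x) {
    lapply(seq_len(M), function(m) {
      xm <- x[(m - 1) * K + seq_len(K)]
      Th <- matrix(0, p, p)
      Th[ut] <- xm[seq_along(ut)]
      Th <- Th + t(Th)
      diag(Th) <- xm[length(ut) + seq_len(p)]
      list(Theta = Th, eta = xm[length(ut) + p + seq_len(p)])
    })
  }
  fn <- function(x) {
    ps <- unpack(x)
    val <- 0
    for (m in seq_len(M)) {
      val <- val + sm_loss(panel$matrices[[m]],
                           tgm_params(ps[[m]]$Theta, ps[[m]]$eta), hw)
      od <- ps[[m]]$Theta; diag(od) <- 0
      val <- val + lambda1 * sum(sqrt(od^2 + eps^2) - eps)
      if (m < M) {
        od2 <- ps[[m + 1]]$Theta; diag(od2) <- 0
        val <- val + lambda2 * (sqrt(sum((od - od2)^2) + eps^2) - eps)
      }
    }
    val
  }
  gr <- function(x) {
    ps <- unpack(x)
    g <- numeric(M * K)
    offd <- lapply(ps, function(pp) { o <- pp$Theta; diag(o) <- 0; o })
    for (m in seq_len(M)) {
      sg <- sm_loss_grad(panel$matrices[[m]],
                         tgm_params(ps[[m]]$Theta, ps[[m]]$eta), hw)
      gTh <- sg$grad_Theta
      # lasso smooth surrogate (both symmetric entries -> factor 2 on ut)
      gTh <- gTh + lambda1 * 2 * (offd[[m]] / sqrt(offd[[m]]^2 + eps^2))[] *
        (row(gTh) != col(gTh))
      if (m < M) {
        d <- offd[[m]] - offd[[m + 1]]
        nrm <- sqrt(sum(d^2) + eps^2)
        gTh <- gTh + lambda2 * 2 * d / nrm * (row(gTh) != col(gTh))
      }
      if (m > 1) {
        d <- offd[[m - 1]] - offd[[m]]
        nrm <- sqrt(sum(d^2) + eps^2)
        gTh <- gTh - lambda2 * 2 * d / nrm * (row(gTh) != col(gTh))
      }
      g[(m - 1) * K + seq_len(K)] <- c(gTh[ut], diag(sg$grad_Theta),
                                       sg$grad_eta)
    }
    g
  }
  x0 <- numeric(M * K)
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  ps <- unpack(opt$par)
  list(estimates = lapply(ps, function(pp) tgm_params(pp$Theta, pp$eta)),
       value = opt$value)
}

# edge-recovery F1 of a fitted phase against the generating truth
phase_f1 <- function(fit, scenario, phase_idx) {
  m <- fit$phases[[phase_idx]][1]
  est <- fit$estimates[[m]]$Theta; diag(est) <- 0
  tru <- scenario$theta_true[[scenario$phase_of[m]]]; diag(tru) <- 0
  tp <- sum(est != 0 & tru != 0) / 2
  fp <- sum(est != 0 & tru == 0) / 2
  fn <- sum(est == 0 & tru != 0) / 2
  2 * tp / (2 * tp + fp + fn)
}

# small keyword network from an explicit edge list
toy_network <- function(n, edges, labels = NULL) {
  Th <- diag(n)
  for (e in edges) {
    Th[e[1], e[2]] <- Th[e[2], e[1]] <- 0.5
  }
  if (!is.null(labels)) dimnames(Th) <- list(labels, labels)
  build_network(Th)
}

# three tiny hand-countable documents
fixture_records <- function() {
  data.frame(
    id = c("d1", "d2", "d3"),
    date = c("2015-01-10", "2015-02-10", "2015-03-10"),
    text = c("apple banana apple cherry",
             "banana banana date",
             "apple cherry cherry cherry"),
    stringsAsFactors = FALSE)
}
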