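`.with_seed` <- function(seed, expr) {
  force(seed)   # evaluate before snapshotting the RNG state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phase-structured ground-truth scenario
#'
#' Builds the ground truth for a synthetic panel: M ordered periods split
#' into `n_phases` contiguous phases of near-equal length, one sparse
#' symmetric positive-definite precision matrix `Theta` per phase
#' (off-diagonal support drawn at random, entries of magnitude `effect`
#' with random sign, diagonal set to the absolute row sum plus one, so the
#' matrix is strictly diagonally dominant and hence positive definite) and
#' one positive linear vector `eta` per phase.
#'
#' @param p dimension (number of keywords).
#' @param M number of periods.
#' @param n_phases number of phases (<= M).
#' @param edges_per_phase number of nonzero upper-triangle entries per
#'   phase's precision matrix.
#' @param effect absolute value of nonzero off-diagonal entries.
#' @param n_per_period per-period sample size (recycled to length M).
#' @param seed integer seed.
#' @return Object of class `tgm_scenario`: `p`, `M`, `phase_of` (length-M
#'   phase index), `change_points` (periods m with a new phase at m+1),
#'   `theta_true`, `eta_true` (per phase), `n_per_period`, `seed`.
#' @export
make_scenario <- function(p = 10, M = 12, n_phases = 3, edges_per_phase = p,
                          effect = 0.5, n_per_period = 300, seed = 1) {
  stopifnot(n_phases >= 1, n_phases <= M, effect > 0, p >= 2)
  if (edges_per_phase > p * (p - 1) / 2)
    stop("edges_per_phase exceeds p(p-1)/2 available pairs")
  phase_of <- rep(seq_len(n_phases),
                  times = diff(round(seq(0, M, length.out = n_phases + 1))))
  change_points <- which(diff(phase_of) != 0)
  .with_seed(seed, {
    theta_true <- vector("list", n_phases)
    eta_true <- vector("list", n_phases)
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    for (ph in seq_len(n_phases)) {
      Th <- matrix(0, p, p)
      if (edges_per_phase > 0) {
        sel <- pairs[sample.int(nrow(pairs), edges_per_phase), , drop = FALSE]
        vals <- effect * sample(c(-1, 1), edges_per_phase, replace = TRUE)
        Th[sel] <- vals
        Th[sel[, 2:1, drop = FALSE]] <- vals
      }
      diag(Th) <- rowSums(abs(Th)) + 1
      theta_true[[ph]] <- Th
      eta_true[[ph]] <- stats::runif(p, 0.5, 1.5)
    }
    structure(list(p = p, M = M, phase_of = phase_of,
                   change_points = change_points, theta_true = theta_true,
                   eta_true = eta_true,
                   n_per_period = rep_len(n_per_period, M), seed = seed),
              class = "tgm_scenario")
  })
}

# one draw from N(mean, sd^2) truncated to [0, Inf); numerically stable in
# the far-tail regime via Robert's translated-exponential rejection
.rtrunc_lower0 <- function(mean, sd) {
  alpha <- -mean / sd
  if (alpha < 4) {
    lo <- stats::pnorm(alpha)
    u <- stats::runif(1, lo, 1)
    z <- stats::qnorm(u)
    if (!is.finite(z)) z <- alpha
  } else {
    lam <- (alpha + sqrt(alpha^2 + 4)) / 2
    repeat {
      z <- alpha + stats::rexp(1, lam)
      if (stats::runif(1) <= exp(-(z - lam)^2 / 2)) break
    }
  }
  mean + sd * max(z, alpha)
}

#' Gibbs sampler for the truncated multivariate Gaussian
#'
#' Samples from the density proportional to
#' \eqn{\exp\{-\tfrac12 y^\top\Theta y + \eta^\top y\}} on the non-negative
#' orthant. The full conditional of coordinate j given the rest is a
#' univariate Gaussian with mean \eqn{(\eta_j - \sum_{l\ne j}\theta_{jl}
#' y_l)/\theta_{jj}} and variance \eqn{1/\theta_{jj}}, truncated to
#' \eqn{[0,\infty)}; a single chain is run with `burn` warm-up sweeps and
#' every `thin`-th sweep retained.
#'
#' @param theta symmetric positive-definite p x p precision matrix.
#' @param eta length-p linear vector.
#' @param n number of retained samples.
#' @param seed integer seed.
#' @param burn warm-up sweeps (default 500).
#' @param thin keep every `thin`-th sweep (default 2).
#' @return n x p non-negative matrix.
#' @export
sample_tn <- function(theta, eta, n, seed = 1, burn = 500, thin = 2) {
  theta <- as.matrix(theta)
  p <- nrow(theta)
  stopifnot(length(eta) == p, n >= 1, burn >= 0, thin >= 1)
  if (max(abs(theta - t(theta))) > 1e-10) stop("theta must be symmetric")
  ev <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ev)) stop("theta must be positive definite")
  sds <- 1 / sqrt(diag(theta))
  .with_seed(seed, {
    y <- pmax(drop(solve(theta, eta)), 0.1)
    out <- matrix(0, n, p)
    sweeps <- burn + n * thin
    k <- 0L
    for (it in seq_len(sweeps)) {
      for (j in seq_len(p)) {
        m <- (eta[j] - sum(theta[j, -j] * y[-j])) / theta[j, j]
        y[j] <- .rtrunc_lower0(m, sds[j])
      }
      if (it > burn && (it - burn) %% thin == 0) {
        k <- k + 1L
        out[k, ] <- y
      }
    }
    out
  })
}

#' Sample the panel defined by a scenario
#'
#' @param scenario a [make_scenario()] object.
#' @param start_quarter label of the first period, default "2015 Q1" style
#'   start date.
#' @return A [panel_data()] object with keywords `kw01..kwp` and quarter
#'   period labels.
#' @export
sample_scenario_panel <- function(scenario, start_quarter = "2015-01-01") {
  stopifnot(inherits(scenario, "tgm_scenario"))
  kw <- sprintf("kw%02d", seq_len(scenario$p))
  periods <- .quarter_seq(start_quarter,
                          as.Date(start_quarter) + 92 * (scenario$M - 1))
  mats <- lapply(seq_len(scenario$M), function(m) {
    ph <- scenario$phase_of[m]
    sample_tn(scenario$theta_true[[ph]], scenario$eta_true[[ph]],
              scenario$n_per_period[m], seed = scenario$seed + 1000L + m)
  })
  panel_data(mats, periods, kw)
}

#' Synthetic document corpus with planted panel structure
#'
#' For each period, one truncated-Gaussian vector is drawn per synthetic
#' report from that period's phase parameters; keyword counts are Poisson
#' with rate `count_scale` times the drawn value, and filler tokens pad
#' each report to `tokens_per_report`. This emulates the statistical shape
#' of a keyword panel (non-negative, right-skewed, phase-structured
#' dependence), not natural-language text.
#'
#' @param scenario a [make_scenario()] object.
#' @param reports_per_period synthetic reports per period.
#' @param tokens_per_report minimum tokens per report.
#' @param count_scale Poisson rate per unit of the latent value (default
#'   10, at which the latent values are recoverable from the counts with
#'   correlation above 0.9).
#' @param seed integer seed.
#' @param start_date first period start date.
#' @return List with `records` (data.frame id, date, text suitable for
#'   [make_documents()]), `keywords`, `periods`, and `latent` (per-period
#'   matrices of the generating truncated-Gaussian values).
#' @export
make_corpus <- function(scenario, reports_per_period = 50,
                        tokens_per_report = 200, count_scale = 10, seed = 1,
                        start_date = "2015-01-01") {
  stopifnot(inherits(scenario, "tgm_scenario"),
            reports_per_period >= 1, tokens_per_report >= 1)
  kw <- sprintf("kw%02d", seq_len(scenario$p))
  fillers <- sprintf("filler%02d", 1:8)
  periods <- .quarter_seq(start_date,
                          as.Date(start_date) + 92 * (scenario$M - 1))
  q_start <- seq(as.Date(start_date), by = "3 months",
                 length.out = scenario$M)
  .with_seed(seed, {
    latent <- vector("list", scenario$M)
    ids <- dates <- texts <- character(0)
    for (m in seq_len(scenario$M)) {
      ph <- scenario$phase_of[m]
      tn <- sample_tn(scenario$theta_true[[ph]], scenario$eta_true[[ph]],
                      reports_per_period,
                      seed = scenario$seed + 2000L + m)
      latent[[m]] <- tn
      for (i in seq_len(reports_per_period)) {
        counts <- stats::rpois(scenario$p, count_scale * tn[i, ])
        toks <- rep(kw, counts)
        pad <- max(tokens_per_report - length(toks), 0)
        toks <- sample(c(toks, sample(fillers, pad, replace = TRUE)))
        ids <- c(ids, sprintf("doc_%03d_%03d", m, i))
        dates <- c(dates, as.character(q_start[m] +
                                         sample.int(85, 1) - 1L))
        texts <- c(texts, paste(toks, collapse = " "))
      }
    }
    list(records = data.frame(id = ids, date = dates, text = texts,
                              stringsAsFactors = FALSE),
         keywords = kw, periods = periods, latent = latent)
  })
}

#' Draws from the discrete power law on {1, 2, ...}
#'
#' \eqn{P(k) = k^{-\gamma}/\zeta(\gamma)}; sampled by inverse CDF on a
#' truncated support whose tail mass is negligible.
#'
#' @param n number of draws.
#' @param gamma exponent (> 1).
#' @param seed integer seed.
#' @param kmax support truncation (default 1e5).
#' @return Integer vector of length n.
#' @export
sample_powerlaw <- function(n, gamma, seed = 1, kmax = 1e5) {
  stopifnot(gamma > 1, n >= 1)
  k <- seq_len(kmax)
  cdf <- cumsum(k^(-gamma))
  cdf <- cdf / cdf[kmax]
  .with_seed(seed, {
    u <- stats::runif(n)
    findInterval(u, cdf) + 1L
  })
}
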