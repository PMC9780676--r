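#' Rank-normalized split-Rhat and tail effective sample size
#'
#' Convergence statistics computed the modern way: chains are split in
#' half; draws are rank-normalized (normal scores of pooled ranks) before
#' the classic between/within variance ratio, and the reported Rhat is the
#' larger of the bulk statistic and the statistic of the folded
#' (median-absolute-deviation) draws, which is sensitive to scale
#' disagreement. Tail ESS is the smaller effective sample size of the 5%
#' and 95% quantile indicator sequences, the quantity that controls
#' credible-interval stability.
#'
#' @param x numeric matrix of draws, iterations x chains.
#' @return `splitRhat()`: the statistic (1 means converged; values above
#'   ~1.01 indicate disagreeing chains). `tailESS()`: effective sample
#'   size (`NA` for constant sequences).
#' @export
splitRhat <- function(x) {
  x <- .splitChains(as.matrix(x))
  max(.basicRhat(.rankNormalize(x)),
      .basicRhat(.rankNormalize(abs(sweep(x, 1:2, median(x))))))
}

#' @rdname splitRhat
#' @export
tailESS <- function(x) {
  x <- .splitChains(as.matrix(x))
  if (stats::sd(x) == 0) return(NA_real_)
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  min(.essMean(1 * (x <= q[1])), .essMean(1 * (x >= q[2])))
}

.splitChains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}

.rankNormalize <- function(x) {
  d <- dim(x)
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  dim(z) <- d
  z
}

.basicRhat <- function(x) {
  m <- ncol(x); n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt((n - 1) / n + B / (W * n))
}

# effective sample size of the mean across chains: chain-averaged
# autocorrelations combined by Geyer's initial positive, monotone sequence
.essMean <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  S <- m * n
  if (n < 4) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) .acov(x[, j]), numeric(n))
  acov <- matrix(acov, nrow = n)
  meanAcov <- rowMeans(acov)
  meanVar <- mean(acov[1, ]) * n / (n - 1)
  varPlus <- meanVar * (n - 1) / n +
    (if (m > 1) var(colMeans(x)) else 0)
  if (!is.finite(varPlus) || varPlus == 0) return(NA_real_)
  rho <- 1 - (meanVar - meanAcov) / varPlus
  rho[1] <- 1
  # pair sums P_k = rho_{2k} + rho_{2k+1}; keep while positive, then
  # enforce monotone decrease
  P <- numeric(0)
  k <- 0L
  repeat {
    i1 <- 2L * k + 1L; i2 <- 2L * k + 2L
    if (i2 > n) break
    p <- rho[i1] + rho[i2]
    if (!is.finite(p) || p <= 0) break
    P <- c(P, p)
    k <- k + 1L
  }
  if (!length(P)) return(S)
  P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / log10(S))
  S / tau
}

.acov <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  drop(stats::acf(v, lag.max = n - 1, type = "covariance",
                  plot = FALSE, demean = FALSE)$acf)
}

#' Convergence gate for an SEM posterior
#'
#' Computes rank-normalized split-Rhat and tail ESS for every monitored
#' parameter and applies the pass criteria: zero divergent transitions
#' (copied from the sampler metadata), all Rhat below `rhatLimit`, and all
#' tail ESS at or above `essFloor`.
#'
#' @param posterior a [SemPosterior] with at least 2 chains.
#' @param rhatLimit convergence threshold (default 1.01).
#' @param essFloor minimum acceptable tail ESS per parameter.
#' @return a [SemDiagnostics].
#' @export
diagnoseSem <- function(posterior, rhatLimit = 1.01, essFloor = 100) {
  stopifnot(is(posterior, "SemPosterior"))
  chains <- sort(unique(posterior@chain))
  if (length(chains) < 2)
    stop("Rhat is undefined for a single chain; run at least 2")
  params <- colnames(posterior@draws)
  perChain <- lapply(chains, function(ch)
    posterior@draws[posterior@chain == ch, , drop = FALSE])
  nIter <- min(vapply(perChain, nrow, integer(1)))
  tab <- data.frame(param = params, rhat = NA_real_, tailESS = NA_real_)
  for (j in seq_along(params)) {
    x <- vapply(perChain, function(m) m[seq_len(nIter), j], numeric(nIter))
    if (stats::sd(x) == 0) next      # constant parameter: nothing to judge
    tab$rhat[j] <- splitRhat(x)
    tab$tailESS[j] <- tailESS(x)
  }
  nDiv <- as.integer(posterior@info$nDivergent %||% 0L)
  ok <- nDiv == 0L &&
    all(tab$rhat < rhatLimit, na.rm = TRUE) &&
    all(tab$tailESS >= essFloor, na.rm = TRUE)
  new("SemDiagnostics", table = tab, nDivergent = nDiv,
      rhatLimit = rhatLimit, essFloor = essFloor, pass = ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname diagnoseSem
#' @param x a [SemDiagnostics].
#' @export
diagnosticsPass <- function(x) x@pass
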