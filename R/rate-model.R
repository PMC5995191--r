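#' Discrete-gamma category rates
#'
#' Discretizes a Gamma(alpha, alpha) rate distribution (mean 1) into `k`
#' equal-probability categories, each represented by the conditional mean of
#' its bin (the usual "mean of bin" discretization). The returned rates are
#' increasing and average exactly 1.
#'
#' @param alpha positive gamma shape parameter; smaller values mean stronger
#'   rate variation among sites.
#' @param k number of categories (>= 1).
#' @return Numeric vector of `k` increasing category rates with mean 1.
#' @examples
#' discretizeGamma(1.8, 4)
#' @export
discretizeGamma <- function(alpha, k) {
  .checkPositive(alpha, "alpha")
  k <- .checkCount(k, "k")
  if (k == 1L) return(1)
  breaks <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  # E[X; X in bin] for Gamma(a, a) is pgamma(ub, a+1, a) - pgamma(lb, a+1, a);
  # dividing by the bin probability 1/k gives the conditional mean.
  p <- pgamma(c(breaks, Inf), shape = alpha + 1, rate = alpha)
  rates <- k * diff(c(0, p))
  rates / mean(rates)
}

#' WAG substitution model
#'
#' Builds a [RateModel-class] from the WAG empirical amino-acid
#' exchangeabilities and stationary frequencies (taken from the model tables
#' shipped with \pkg{phangorn}), with discrete-gamma among-site rate
#' variation.
#'
#' @param alpha gamma shape parameter (default 1.8).
#' @param nCategories number of discrete gamma categories (default 4).
#' @return A validated [RateModel-class] object.
#' @examples
#' m <- wagModel()
#' categoryRates(m)
#' @export
wagModel <- function(alpha = 1.8, nCategories = 4) {
  wag <- get(".WAG", envir = asNamespace("phangorn"))
  S <- matrix(0, 20L, 20L, dimnames = list(AA_CODES, AA_CODES))
  S[lower.tri(S)] <- wag$Q
  S <- S + t(S)
  freqs <- as.numeric(wag$bf)
  names(freqs) <- AA_CODES
  rateModel(S, freqs, alpha = alpha, nCategories = nCategories)
}

#' @describeIn RateModel-class Construct a normalized reversible model from
#'   exchangeabilities and frequencies.
#' @param exchangeabilities symmetric non-negative 20x20 matrix.
#' @param frequencies stationary frequencies (length 20, positive).
#' @param alpha,nCategories discrete-gamma parameters.
#' @export
rateModel <- function(exchangeabilities, frequencies, alpha = 1.8,
                      nCategories = 4) {
  .checkPositive(alpha, "alpha")
  nCategories <- .checkCount(nCategories, "nCategories")
  frequencies <- frequencies / sum(frequencies)
  Q <- exchangeabilities * rep(frequencies, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(frequencies * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_CODES, AA_CODES)
  # Reversibility makes D^{1/2} Q D^{-1/2} symmetric; its eigensystem gives
  # numerically stable transition probabilities for any branch length.
  d <- sqrt(frequencies)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  eig <- list(values = e$values,
              left = (1 / d) * e$vectors,    # D^{-1/2} U
              right = t(e$vectors * d))      # U' D^{1/2}
  new("RateModel", exchangeabilities = exchangeabilities,
      frequencies = frequencies, alpha = alpha, nCategories = nCategories,
      Q = Q, categoryRates = discretizeGamma(alpha, nCategories), eig = eig)
}

#' @describeIn RateModel-class Transition probability matrix `exp(Q t r)`.
#' @param model a [RateModel-class] object.
#' @param t branch length (expected substitutions per average-rate site).
#' @param rate relative rate multiplier (e.g. a category rate).
#' @export
transitionMatrix <- function(model, t, rate = 1) {
  stopifnot(is(model, "RateModel"), t >= 0)
  if (t * rate == 0) {
    P <- diag(20L)
    dimnames(P) <- dimnames(model@Q)
    return(P)
  }
  e <- model@eig
  P <- e$left %*% (exp(e$values * t * rate) * e$right)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model@Q)
  P
}

#' @rdname RateModel-class
#' @export
setMethod("categoryRates", "RateModel", function(x) x@categoryRates)

#' @rdname RateModel-class
#' @export
setMethod("stationaryFrequencies", "RateModel", function(x) x@frequencies)
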