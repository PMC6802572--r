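#' Reversible substitution models
#'
#' Construct a continuous-time substitution model from a named
#' parameterisation. The instantaneous rate matrix is assembled as
#' `Q[i,j] = s[i,j] * pi[j]` for `i != j` from symmetric exchangeabilities
#' `s` and equilibrium frequencies `pi`, the diagonal is set so rows sum to
#' zero, and the matrix is rescaled so that the expected number of
#' substitutions per unit time at equilibrium, `-sum(pi * diag(Q))`, equals
#' one. Branch lengths are therefore always in expected substitutions per
#' site, comparable across models.
#'
#' Supported parameterisations:
#' \describe{
#'   \item{`"JC"`}{equal rates, equal frequencies (no parameters).}
#'   \item{`"HKY"`}{one transition/transversion ratio `kappa`; the
#'     exchangeability is `kappa` for the two transitions (A<->G, C<->T)
#'     and 1 for transversions.}
#'   \item{`"GTR"`}{six exchangeabilities in the order
#'     AC, AG, AT, CG, CT, GT.}
#'   \item{`"ARBITRARY"`}{a full `S x S` rate matrix with zero row sums,
#'     any state count (e.g. 61 for codons). It is normalised the same
#'     way; detailed balance is checked to decide whether the fast
#'     eigendecomposition route applies, not assumed.}
#' }
#'
#' @param name one of `"JC"`, `"HKY"`, `"GTR"`, `"ARBITRARY"`.
#' @param frequencies equilibrium frequency vector (a probability simplex);
#'   defaults to uniform for `"JC"`.
#' @param kappa transition/transversion ratio (HKY).
#' @param exchangeabilities numeric vector of `S*(S-1)/2` symmetric rates
#'   (GTR order AC, AG, AT, CG, CT, GT for nucleotides).
#' @param rate_matrix full rate matrix for `"ARBITRARY"`.
#' @return an object of class `pw_model` with elements `state_count`,
#'   `frequencies`, `exchangeabilities` (when applicable), `Q`
#'   (the normalised rate matrix) and `reversible`.
#' @examples
#' m <- build_model("HKY", kappa = 2, frequencies = c(0.3, 0.2, 0.2, 0.3))
#' rowSums(m$Q)                       # zero
#' -sum(m$frequencies * diag(m$Q))    # one substitution per unit time
#' @export
build_model <- function(name = c("JC", "HKY", "GTR", "ARBITRARY"),
                        frequencies = NULL, kappa = NULL,
                        exchangeabilities = NULL, rate_matrix = NULL) {
  name <- match.arg(name)

  if (name == "ARBITRARY") {
    if (is.null(rate_matrix) || !is.matrix(rate_matrix) ||
        nrow(rate_matrix) != ncol(rate_matrix))
      pw_stop("ARBITRARY model needs a square rate matrix")
    S <- nrow(rate_matrix)
    if (is.null(frequencies))
      pw_stop("ARBITRARY model needs equilibrium frequencies")
    pi <- check_frequencies(frequencies, S)
    if (any(rate_matrix[row(rate_matrix) != col(rate_matrix)] < 0))
      pw_stop("off-diagonal rates must be nonnegative")
    if (max(abs(rowSums(rate_matrix))) > 1e-8)
      pw_stop("ARBITRARY rate matrix must have zero row sums")
    Q <- normalize_rate_matrix(rate_matrix, pi)
    rev <- max(abs(pi * Q - t(pi * Q))) < 1e-9
    return(new_model(S, pi, NULL, Q, reversible = rev, name = name))
  }

  S <- 4L
  if (name == "JC") {
    if (is.null(frequencies)) frequencies <- rep(0.25, 4)
    s <- rep(1, 6)
  } else if (name == "HKY") {
    if (is.null(kappa)) pw_stop("HKY model needs kappa")
    if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0)
      pw_stop("kappa must be a single nonnegative number")
    # order AC, AG, AT, CG, CT, GT; transitions are AG and CT
    s <- c(1, kappa, 1, 1, kappa, 1)
  } else { # GTR
    if (is.null(exchangeabilities) || length(exchangeabilities) != 6)
      pw_stop("GTR model needs 6 exchangeabilities (AC, AG, AT, CG, CT, GT)")
    s <- as.numeric(exchangeabilities)
  }
  if (any(s < 0)) pw_stop("exchangeabilities must be nonnegative")
  if (is.null(frequencies)) pw_stop(name, " model needs frequencies")
  pi <- check_frequencies(frequencies, S)

  # symmetric exchangeability matrix in the conventional
  # AC, AG, AT, CG, CT, GT input order
  R <- matrix(0, S, S)
  idx <- cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
  R[idx] <- s
  R <- R + t(R)
  Q <- R * rep(pi, each = S)    # Q[i,j] = s[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- normalize_rate_matrix(Q, pi)
  new_model(S, pi, s, Q, reversible = TRUE, name = name)
}

new_model <- function(S, pi, s, Q, reversible, name) {
  structure(list(state_count = S, frequencies = pi, exchangeabilities = s,
                 Q = Q, reversible = reversible, name = name),
            class = "pw_model")
}

check_frequencies <- function(pi, S) {
  pi <- as.numeric(pi)
  if (length(pi) != S) pw_stop("frequencies must have length ", S)
  if (any(pi < 0)) pw_stop("frequencies must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-8) pw_stop("frequencies must sum to 1")
  pi
}

normalize_rate_matrix <- function(Q, pi) {
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) pw_stop("rate matrix has no flux; cannot normalise")
  Q / mu
}

#' @export
print.pw_model <- function(x, ...) {
  cat(sprintf("<pw_model %s, %d states, %s>\n", x$name, x$state_count,
              if (x$reversible) "reversible" else "non-reversible"))
  invisible(x)
}

#' Eigendecomposition of a reversible rate matrix
#'
#' Decomposes `Q = E diag(lambda) E^-1` through the symmetric similarity
#' transform `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is symmetric exactly
#' when the model satisfies detailed balance, guaranteeing a real spectrum:
#' one zero eigenvalue and the rest negative. Non-reversible models cannot
#' use this route; the returned system is flagged `unavailable` and
#' downstream transition-probability code falls back to the matrix
#' exponential.
#'
#' @param model a [build_model()] result.
#' @return an object of class `pw_eigen` with `values`, `vectors`,
#'   `inverse_vectors`, `state_count`, `frequencies`, `Q`, `unavailable`.
#' @export
eigendecompose <- function(model) {
  stopifnot(inherits(model, "pw_model"))
  pi <- model$frequencies
  if (any(pi <= 0))
    pw_stop("eigendecomposition needs strictly positive frequencies")
  if (!model$reversible) {
    return(structure(list(values = NULL, vectors = NULL,
                          inverse_vectors = NULL,
                          state_count = model$state_count,
                          frequencies = pi, Q = model$Q,
                          unavailable = TRUE),
                     class = "pw_eigen"))
  }
  sq <- sqrt(pi)
  A <- (sq * model$Q) %*% diag(1 / sq, model$state_count)  # diag(sq) Q diag(1/sq)
  A <- (A + t(A)) / 2                                      # kill round-off asymmetry
  es <- eigen(A, symmetric = TRUE)
  E <- diag(1 / sq, model$state_count) %*% es$vectors
  Einv <- t(es$vectors) %*% diag(sq, model$state_count)
  structure(list(values = es$values, vectors = E, inverse_vectors = Einv,
                 state_count = model$state_count, frequencies = pi,
                 Q = model$Q, unavailable = FALSE),
            class = "pw_eigen")
}

#' Discretized-gamma rate categories
#'
#' Splits a mean-one gamma distribution with shape `alpha` into
#' `category_count` equal-probability intervals and uses the conditional
#' mean of each interval as its representative relative rate (the standard
#' discrete-gamma construction of among-site rate variation). The means are
#' computed through the incomplete-gamma function and renormalised so the
#' weighted mean rate is exactly one. A `"median"` variant (interval
#' medians, rescaled to mean one) is available behind the `method` flag.
#'
#' @param alpha gamma shape (> 0); small values mean strong rate
#'   heterogeneity, large values approach rate homogeneity.
#' @param category_count number of categories (>= 1).
#' @param method `"mean"` (default) or `"median"`.
#' @return an object of class `pw_rates`: `rates` (nondecreasing, mean one
#'   under `weights`), `weights` (equal, summing to one), `shape`.
#' @examples
#' discretize_gamma(0.5, 4)
#' @export
discretize_gamma <- function(alpha, category_count = 4L,
                             method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    pw_stop("alpha must be a single positive number")
  C <- as.integer(category_count)
  if (is.na(C) || C < 1) pw_stop("category_count must be >= 1")
  w <- rep(1 / C, C)
  if (C == 1L) {
    return(new_rates(1, w, alpha))
  }
  if (method == "mean") {
    # E[X | quantile interval] for X ~ Gamma(shape = alpha, rate = alpha):
    # mass of Gamma(alpha + 1, alpha) between the interval bounds, times C.
    cuts <- qgamma(seq(0, 1, length.out = C + 1), shape = alpha, rate = alpha)
    mass <- pgamma(cuts, shape = alpha + 1, rate = alpha)
    r <- C * diff(mass)
  } else {
    r <- qgamma((2 * seq_len(C) - 1) / (2 * C), shape = alpha, rate = alpha)
  }
  r <- r / sum(r * w)
  new_rates(r, w, alpha)
}

new_rates <- function(r, w, shape = NULL) {
  structure(list(rates = as.numeric(r), weights = as.numeric(w),
                 shape = shape),
            class = "pw_rates")
}

#' Fixed rate categories
#'
#' Wraps explicit relative rates and weights (renormalised so the weights
#' sum to one and the mean rate is one) for use where gamma-derived
#' categories are not wanted.
#' @param rates,weights numeric vectors of equal length.
#' @export
rate_categories <- function(rates, weights = NULL) {
  r <- as.numeric(rates)
  if (is.null(weights)) weights <- rep(1 / length(r), length(r))
  w <- as.numeric(weights)
  if (length(r) != length(w)) pw_stop("rates and weights differ in length")
  if (any(r < 0) || any(w < 0)) pw_stop("rates and weights must be nonnegative")
  w <- w / sum(w)
  r <- r / sum(r * w)
  o <- order(r)
  new_rates(r[o], w[o])
}

#' Transition probability matrices per edge and rate category
#'
#' Computes `P(t, c) = E diag(exp(lambda_k * r_c * t)) E^-1` for every edge
#' length and rate category and, when asked, the first and second
#' derivatives with respect to `t` (the eigenvalues picking up factors
#' `lambda_k r_c` and `(lambda_k r_c)^2`). Tiny negative round-off entries
#' are clamped to zero. When the eigensystem is flagged unavailable
#' (non-reversible model) the probabilities come from the dense matrix
#' exponential and the derivatives from `Q P` and `Q Q P` products.
#'
#' @param eigen a [eigendecompose()] result.
#' @param rates a [discretize_gamma()] / [rate_categories()] result.
#' @param edge_lengths nonnegative branch lengths.
#' @param want_derivatives also compute `dP/dt` and `d2P/dt2`.
#' @return a list with one element per edge; each element has `P` (an
#'   `S x S x C` array) and, when requested, `d1` and `d2`.
#' @export
compute_transition_matrices <- function(eigen, rates, edge_lengths,
                                        want_derivatives = FALSE) {
  stopifnot(inherits(eigen, "pw_eigen"), inherits(rates, "pw_rates"))
  t <- as.numeric(edge_lengths)
  if (any(!is.finite(t)) || any(t < 0))
    pw_stop("branch lengths must be finite and nonnegative")
  S <- eigen$state_count
  C <- length(rates$rates)

  if (isTRUE(eigen$unavailable))
    return(tm_via_expm(eigen$Q, rates, t, S, C, want_derivatives))

  E <- eigen$vectors
  Einv <- eigen$inverse_vectors
  lam <- eigen$values
  lapply(t, function(ti) {
    P <- array(0, c(S, S, C))
    d1 <- if (want_derivatives) array(0, c(S, S, C)) else NULL
    d2 <- if (want_derivatives) array(0, c(S, S, C)) else NULL
    for (c in seq_len(C)) {
      lr <- lam * rates$rates[c]
      e <- exp(lr * ti)
      Pc <- E %*% (e * Einv)
      Pc[Pc < 0] <- 0
      P[, , c] <- Pc
      if (want_derivatives) {
        d1[, , c] <- E %*% ((lr * e) * Einv)
        d2[, , c] <- E %*% ((lr * lr * e) * Einv)
      }
    }
    list(P = P, d1 = d1, d2 = d2)
  })
}

# matrix-exponential fallback for non-reversible rate matrices
tm_via_expm <- function(Q, rates, t, S, C, want_derivatives) {
  lapply(t, function(ti) {
    P <- array(0, c(S, S, C))
    d1 <- if (want_derivatives) array(0, c(S, S, C)) else NULL
    d2 <- if (want_derivatives) array(0, c(S, S, C)) else NULL
    for (c in seq_len(C)) {
      Qr <- Q * rates$rates[c]
      Pc <- as.matrix(Matrix::expm(Qr * ti))
      Pc[Pc < 0] <- 0
      P[, , c] <- Pc
      if (want_derivatives) {
        d1[, , c] <- Qr %*% Pc
        d2[, , c] <- Qr %*% Qr %*% Pc
      }
    }
    list(P = P, d1 = d1, d2 = d2)
  })
}

#' Read model parameters from a plain key/value config file
#'
#' Accepts a YAML file with keys `model` (jc/hky/gtr), `kappa`,
#' `exchangeabilities`, `frequencies`, `alpha`, `categories`.
#' @param path config file path.
#' @return list with `model` (a `pw_model`) and `rates` (a `pw_rates`).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  name <- toupper(cfg$model %||% "JC")
  model <- build_model(name,
                       frequencies = cfg$frequencies,
                       kappa = cfg$kappa,
                       exchangeabilities = cfg$exchangeabilities)
  rates <- if (!is.null(cfg$alpha))
    discretize_gamma(cfg$alpha, cfg$categories %||% 4L)
  else
    rate_categories(1)
  list(model = model, rates = rates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
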