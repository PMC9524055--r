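# Trainable location-word classifier: the first step of the two-step
# geolocation algorithm. A ridge-penalised logistic scorer over character
# n-grams, fitted by IRLS solved in the observation (dual) space so that it
# stays well defined down to one example per class.

#' Classifier hyper-parameters
#'
#' @param ngram Integer range of character n-gram lengths extracted from each
#'   token (tokens are padded with `^`/`$` boundary markers).
#' @param lambda Ridge penalty, `> 0`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   linear predictor.
#' @param seed Kept for interface stability; the fit itself is deterministic.
#' @return A list of parameters for [train_candidate_classifier()].
#' @export
classifier_params <- function(ngram = c(2L, 4L), lambda = 1, max_iter = 50L,
                              tol = 1e-8, seed = 1L) {
  stopifnot(length(ngram) == 2L, ngram[1] >= 1L, ngram[2] >= ngram[1],
            lambda > 0)
  list(ngram = as.integer(ngram), lambda = lambda,
       max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed))
}

char_ngrams <- function(token, lo, hi) {
  token <- paste0("^", token, "$")
  n <- nchar(token)
  out <- character(0)
  for (k in lo:hi) {
    if (n >= k) out <- c(out, substring(token, 1:(n - k + 1), k:n))
  }
  unique(out)
}

ngram_matrix <- function(tokens, vocab, lo, hi) {
  p <- length(vocab) + 1L # final column: intercept feature
  X <- matrix(0, nrow = length(tokens), ncol = p)
  for (i in seq_along(tokens)) {
    g <- char_ngrams(tokens[i], lo, hi)
    X[i, match(intersect(g, vocab), vocab)] <- 1
  }
  X[, p] <- 1
  X
}

#' Train the location-word classifier
#'
#' Fits a ridge-penalised logistic regression on character n-gram indicators,
#' with gazetteer-derived location words as positives and common (stop and
#' domain) words as negatives. The normal equations are solved per IRLS step
#' in the observation space, so the fit is exact, deterministic, and defined
#' for classes of any size (including a single word).
#'
#' @param location_words,common_words Character vectors; non-empty and
#'   disjoint after casefolding.
#' @param params A [classifier_params()] list.
#' @return An object of class `location_classifier`. Score new tokens with
#'   [score_tokens()] or `predict()`; scores are probabilities in `[0, 1]`.
#' @export
#' @examples
#' clf <- train_candidate_classifier(
#'   c("paris", "france", "madrid"),
#'   c("outbreak", "cases", "the")
#' )
#' score_tokens(clf, c("france", "cases"))
train_candidate_classifier <- function(location_words, common_words,
                                       params = classifier_params()) {
  location_words <- unique(stringr::str_to_lower(location_words[nzchar(location_words)]))
  common_words <- unique(stringr::str_to_lower(common_words[nzchar(common_words)]))
  if (length(location_words) == 0 || length(common_words) == 0) {
    abort("both training classes must be non-empty")
  }
  overlap <- intersect(location_words, common_words)
  if (length(overlap)) {
    abort(paste0(
      "training classes must be disjoint after casefolding; shared: ",
      paste(head(overlap, 5), collapse = ", ")
    ))
  }
  tokens <- c(location_words, common_words)
  y <- c(rep(1, length(location_words)), rep(0, length(common_words)))
  vocab <- unique(unlist(lapply(tokens, char_ngrams,
    lo = params$ngram[1], hi = params$ngram[2]
  )))
  X <- ngram_matrix(tokens, vocab, params$ngram[1], params$ngram[2])
  K <- tcrossprod(X)
  n <- nrow(X)
  eta <- rep(0, n)
  alpha <- rep(0, n)
  for (it in seq_len(params$max_iter)) {
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    alpha <- solve(K + params$lambda * diag(1 / w, n), z)
    eta_new <- as.numeric(K %*% alpha)
    if (max(abs(eta_new - eta)) < params$tol) {
      eta <- eta_new
      break
    }
    eta <- eta_new
  }
  beta <- as.numeric(crossprod(X, alpha))
  structure(
    list(
      vocab = vocab, beta = beta, params = params,
      n_location = length(location_words), n_common = length(common_words)
    ),
    class = "location_classifier"
  )
}

#' Score tokens with a trained classifier
#'
#' @param classifier A `location_classifier`.
#' @param tokens Character vector of tokens (casefolded internally).
#' @return Numeric vector of location scores in `[0, 1]`; a token sharing no
#'   n-gram with the training vocabulary scores at the intercept.
#' @export
score_tokens <- function(classifier, tokens) {
  stopifnot(inherits(classifier, "location_classifier"))
  if (length(tokens) == 0) return(numeric(0))
  tokens <- stringr::str_to_lower(tokens)
  X <- ngram_matrix(tokens, classifier$vocab,
    classifier$params$ngram[1], classifier$params$ngram[2]
  )
  eta <- as.numeric(X %*% classifier$beta)
  1 / (1 + exp(-eta))
}

#' @export
predict.location_classifier <- function(object, newdata, ...) {
  score_tokens(object, newdata)
}

#' @export
print.location_classifier <- function(x, ...) {
  cat(sprintf(
    "<location_classifier> %d location + %d common words, %d n-gram features\n",
    x$n_location, x$n_common, length(x$vocab)
  ))
  invisible(x)
}

#' Tidy a location-word classifier
#'
#' @param x A `location_classifier`.
#' @param ... Unused.
#' @return `tidy()`: one row per n-gram feature with its logistic weight
#'   (positive weights favour locations). `glance()`: a one-row model
#'   summary.
#' @export
tidy.location_classifier <- function(x, ...) {
  tibble(ngram = c(x$vocab, "(intercept)"), weight = x$beta) %>%
    arrange(desc(abs(.data$weight)))
}

#' @rdname tidy.location_classifier
#' @export
glance.location_classifier <- function(x, ...) {
  tibble(
    n_location = x$n_location, n_common = x$n_common,
    n_features = length(x$vocab), lambda = x$params$lambda
  )
}
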